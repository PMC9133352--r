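#' Parametric pulsatile inlet waveform
#'
#' Builds a two-harmonic inlet velocity waveform over one cardiac cycle,
#' a smooth stand-in for a Doppler-derived flow curve. The systolic peak
#' sits at `t_peak` and the curve stays strictly positive for the default
#' harmonic amplitudes.
#'
#' @param period Cycle length in seconds (default 0.8).
#' @param timestep Sampling interval in seconds (default 0.01); `period /
#'   timestep` must be a whole number, giving 80 frames at the defaults.
#' @param u_mean Mean inlet speed in m/s.
#' @param a1,a2 Relative amplitudes of the first and second harmonic.
#' @param t_peak Time of the systolic peak in seconds.
#'
#' @return An object of class `flow_waveform`: a list with `period`,
#'   `timestep`, `times` and `velocities` (one speed per frame, m/s).
#' @examples
#' wf <- flow_waveform()
#' length(wf$velocities)  # 80
#' @export
flow_waveform <- function(period = 0.8, timestep = 0.01, u_mean = 0.35,
                          a1 = 0.45, a2 = 0.20, t_peak = 0.12) {
  if (period <= 0 || timestep <= 0)
    stop("invalid-parameter: period and timestep must be positive")
  n <- period / timestep
  if (abs(n - round(n)) > 1e-9 || round(n) < 2)
    stop("invalid-parameter: period / timestep must be a positive integer >= 2")
  n <- as.integer(round(n))
  times <- (seq_len(n) - 1L) * timestep
  phase <- 2 * pi * (times - t_peak) / period
  shape <- 1 + a1 * cos(phase) + a2 * cos(2 * phase)
  if (any(shape <= 0))
    stop("invalid-parameter: harmonic amplitudes yield non-positive velocity")
  # rescale so the frame mean is exactly u_mean
  v <- u_mean * shape / mean(shape)
  structure(list(period = period, timestep = timestep,
                 times = times, velocities = v),
            class = "flow_waveform")
}

#' Constant (non-pulsatile) waveform, mainly for degenerate-case tests
#' @inheritParams flow_waveform
#' @return A `flow_waveform` whose velocities are all `u_mean`.
#' @export
flat_waveform <- function(period = 0.8, timestep = 0.01, u_mean = 0.35) {
  flow_waveform(period, timestep, u_mean, a1 = 0, a2 = 0)
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform: %d frames over %.3g s, mean %.3g m/s, peak %.3g m/s\n",
              length(x$velocities), x$period, mean(x$velocities),
              max(x$velocities)))
  invisible(x)
}

n_frames <- function(waveform) length(waveform$velocities)

#' Index of the systolic frame (maximum inlet velocity)
#' @param waveform A `flow_waveform`.
#' @return Integer frame index.
#' @export
systolic_frame <- function(waveform) which.max(waveform$velocities)
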