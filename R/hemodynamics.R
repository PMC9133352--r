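#' @title Cycle-integrated wall-shear-stress channels
#' @description
#' `compute_tawss()` returns the time-averaged WSS magnitude
#' \eqn{(1/T)\int_0^T |\tau(t)|\,dt} and `compute_osi()` the oscillatory
#' shear index \eqn{\tfrac12(1 - |\int \tau\,dt| / \int |\tau|\,dt)} for
#' each surface point. Integrals use the periodic trapezoidal rule on the
#' uniform frame grid (the cycle is closed by wrapping to frame 0), which
#' reduces to the frame mean and is spectrally accurate for smooth
#' periodic signals.
#'
#' @param wss_series Either an array `n_points x n_frames x 3` of WSS
#'   vectors (Pa) or, for a single point, an `n_frames x 3` matrix.
#' @param waveform The [flow_waveform()] that produced the series; used to
#'   validate the frame count.
#' @return Numeric vector, one value per point. OSI lies in `[0, 0.5]`
#'   and is defined as 0 at points where WSS vanishes for the whole cycle.
#' @examples
#' wf <- flow_waveform()
#' s <- matrix(rep(c(1, 0, 0), each = 80), 80, 3)   # steady unidirectional
#' compute_tawss(s, wf)  # 1
#' compute_osi(s, wf)    # 0
#' @export
compute_tawss <- function(wss_series, waveform) {
  s <- .as_series(wss_series, waveform)
  n <- dim(s)[1]; nt <- dim(s)[2]
  mags <- sqrt(matrix(s[, , 1], n, nt)^2 + matrix(s[, , 2], n, nt)^2 +
                 matrix(s[, , 3], n, nt)^2)
  rowMeans(mags)
}

#' @rdname compute_tawss
#' @export
compute_osi <- function(wss_series, waveform) {
  s <- .as_series(wss_series, waveform)
  n <- dim(s)[1]; nt <- dim(s)[2]
  mean_vec <- cbind(rowMeans(matrix(s[, , 1], n, nt)),
                    rowMeans(matrix(s[, , 2], n, nt)),
                    rowMeans(matrix(s[, , 3], n, nt)))
  num <- sqrt(rowSums(mean_vec^2))
  den <- compute_tawss(s, waveform)
  osi <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(osi, 0), 0.5)
}

.as_series <- function(wss_series, waveform) {
  if (is.matrix(wss_series)) {
    m <- wss_series
    if (ncol(m) != 3)
      stop("contract error: single-point series must be n_frames x 3")
    wss_series <- array(0, dim = c(1L, nrow(m), 3L))
    wss_series[1, , ] <- m
  }
  d <- dim(wss_series)
  if (length(d) != 3 || d[3] != 3)
    stop("contract error: wss_series must be n_points x n_frames x 3")
  if (d[2] < 2)
    stop("contract error: a single timestep cannot span a cardiac cycle")
  if (!missing(waveform) && !is.null(waveform) && d[2] != n_frames(waveform))
    stop("contract error: wss_series frame count does not match the waveform")
  wss_series
}

#' Derive TAWSS, OSI and systolic-WSS channels of a cloud
#'
#' Fills the `tawss`, `osi` and `wss_sys` per-point channels of a
#' hemodynamic cloud from its stored WSS time series. The systolic frame
#' is the frame of maximum inlet velocity.
#'
#' @param cloud A `hemo_cloud` (see [simulate_hemo_fields()]).
#' @return The cloud with derived channels filled.
#' @export
derive_channels <- function(cloud) {
  sys <- systolic_frame(cloud$waveform)
  w <- cloud$wss_series
  cloud$tawss <- compute_tawss(w, cloud$waveform)
  cloud$osi <- compute_osi(w, cloud$waveform)
  cloud$wss_sys <- sqrt(w[, sys, 1]^2 + w[, sys, 2]^2 + w[, sys, 3]^2)
  cloud
}

#' Low-shear area fraction
#'
#' Area-weighted fraction of the sac surface whose TAWSS falls below a
#' fraction of the parent-artery mean WSS.
#'
#' @param cloud A derived `hemo_cloud`.
#' @param parent_mean_wss Parent-artery reference TAWSS (Pa), > 0.
#' @param threshold_frac Threshold as a fraction of the reference
#'   (default 0.10).
#' @return Fraction in `[0, 1]`.
#' @export
compute_lsa <- function(cloud, parent_mean_wss, threshold_frac = 0.10) {
  if (parent_mean_wss <= 0)
    stop("contract error: parent_mean_wss must be positive")
  w <- cloud$geometry$point_areas
  sum(w[cloud$tawss < threshold_frac * parent_mean_wss]) / sum(w)
}

#' High-OSI area fraction
#'
#' Area-weighted fraction of the sac surface with OSI above a threshold.
#'
#' @param cloud A derived `hemo_cloud`.
#' @param osi_threshold OSI cut-off (default 0.2).
#' @return Fraction in `[0, 1]`.
#' @export
compute_hoa <- function(cloud, osi_threshold = 0.2) {
  if (is.null(cloud$osi)) stop("contract error: OSI channel not derived")
  w <- cloud$geometry$point_areas
  sum(w[cloud$osi > osi_threshold]) / sum(w)
}

#' Trans-aneurysmal energy loss
#'
#' Difference in total (static + kinetic) energy flux between the inlet
#' and the outlets: \eqn{EL = \sum_{in}(P + \rho u^2/2) Q - \sum_{out}(P +
#' \rho u^2/2) Q}, in watts. Flow conservation is enforced to 1%.
#'
#' @param inlet_state List with `pressure` (Pa), `velocity` (m/s), `flow`
#'   (m^3/s).
#' @param outlet_states A list of such states (or a single state).
#' @param density Blood density, kg/m^3 (default 1060).
#' @return Energy loss in W.
#' @examples
#' compute_energy_loss(list(pressure = 200, velocity = 0.5, flow = 5e-6),
#'                     list(list(pressure = 100, velocity = 0.5, flow = 5e-6)))
#' @export
compute_energy_loss <- function(inlet_state, outlet_states, density = 1060) {
  if (!is.null(outlet_states$pressure)) outlet_states <- list(outlet_states)
  q_in <- inlet_state$flow
  q_out <- sum(vapply(outlet_states, `[[`, numeric(1), "flow"))
  if (abs(q_in - q_out) > 0.01 * max(abs(q_in), 1e-300))
    stop("contract error: inlet and outlet flows do not balance within 1%")
  eflux <- function(st) (st$pressure + 0.5 * density * st$velocity^2) * st$flow
  eflux(inlet_state) - sum(vapply(outlet_states, eflux, numeric(1)))
}

#' The 18 scalar hemodynamic parameters of one subject
#'
#' Summarises a derived hemodynamic cloud into the fixed 18-parameter
#' roster: max/avg/min of systolic WSS, TAWSS, OSI, pressure and velocity
#' (averages are area-weighted; max/min are order statistics over sac
#' points), plus the high-OSI area fraction, the low-shear area fraction
#' and the energy loss.
#'
#' @param cloud A derived `hemo_cloud`.
#' @param parent_mean_wss Parent-artery reference TAWSS (Pa); defaults to
#'   the cloud's own `parent_mean_wss` field.
#' @param lsa_frac,hoa_threshold Thresholds for LSA and HOA.
#' @param density Blood density (kg/m^3) for the energy loss.
#' @return An object of class `hemo_vector`: a named numeric vector of
#'   length 18.
#' @export
summarize_hemodynamics <- function(cloud, parent_mean_wss = NULL,
                                   lsa_frac = 0.10, hoa_threshold = 0.2,
                                   density = 1060) {
  if (is.null(cloud$tawss) || is.null(cloud$osi) || is.null(cloud$wss_sys))
    stop("contract error: derived channels missing; call derive_channels()")
  if (is.null(parent_mean_wss)) parent_mean_wss <- cloud$parent_mean_wss
  if (is.null(parent_mean_wss))
    stop("contract error: parent_mean_wss not supplied and not in cloud")
  w <- cloud$geometry$point_areas
  stat3 <- function(x) c(max = max(x), avg = sum(w * x) / sum(w), min = min(x))
  el <- compute_energy_loss(cloud$inlet_state, cloud$outlet_states, density)
  v <- c(
    wss = stat3(cloud$wss_sys),
    tawss = stat3(cloud$tawss),
    osi = stat3(cloud$osi),
    pressure = stat3(cloud$pressure),
    velocity = stat3(cloud$velocity),
    hoa = compute_hoa(cloud, hoa_threshold),
    lsa = compute_lsa(cloud, parent_mean_wss, lsa_frac),
    energy_loss = el
  )
  names(v) <- c("wss_max", "wss_avg", "wss_min",
                "tawss_max", "tawss_avg", "tawss_min",
                "osi_max", "osi_avg", "osi_min",
                "pressure_max", "pressure_avg", "pressure_min",
                "velocity_max", "velocity_avg", "velocity_min",
                "hoa", "lsa", "energy_loss")
  structure(v, class = c("hemo_vector", "numeric"))
}

#' Hemodynamic parameter table for a whole cohort
#'
#' @param cohort List of derived hemodynamic clouds.
#' @param ... Passed to [summarize_hemodynamics()].
#' @return A data.frame with `subject_id`, `label` and 18 named columns.
#' @export
cohort_hemodynamics <- function(cohort, ...) {
  rows <- lapply(cohort, function(cl) {
    hv <- summarize_hemodynamics(cl, ...)
    cbind(data.frame(subject_id = cl$subject_id, label = cl$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(hv))))
  })
  do.call(rbind, rows)
}
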