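#' Impingement-zone mask
#'
#' Points whose systolic WSS magnitude exceeds `frac` of the sac maximum
#' (strict `>`, with a `>=`-at-max fallback so a uniform field still
#' yields its argmax points), unioned with the surface footprint of the
#' inflow jet: all points within `jet_radius_frac` of the sac height from
#' the maximum-velocity point.
#'
#' @param cloud A derived `hemo_cloud`.
#' @param frac WSS threshold fraction in (0, 1), default 0.8.
#' @param jet_radius_frac Jet footprint radius as a fraction of sac
#'   height (default 0.1). Set to 0 to disable the union.
#' @return Logical mask over surface points.
#' @export
find_impingement_zone <- function(cloud, frac = 0.8, jet_radius_frac = 0.1) {
  if (is.null(cloud$wss_sys))
    stop("contract error: systolic WSS channel not derived")
  if (frac <= 0 || frac >= 1)
    stop("invalid-parameter: frac must be in (0, 1)")
  w <- cloud$wss_sys
  mask <- w > frac * max(w)
  if (!any(mask)) mask <- w >= max(w)
  if (jet_radius_frac > 0) {
    pts <- cloud$geometry$surface_points
    g <- cloud$geometry
    height <- g$radius - g$neck_z
    jmax <- which.max(cloud$velocity)
    d <- sqrt(rowSums((pts - matrix(pts[jmax, ], nrow(pts), 3,
                                    byrow = TRUE))^2))
    mask <- mask | (d <= jet_radius_frac * height)
  }
  mask
}

#' Inflow-jet mask
#'
#' Points whose near-wall velocity exceeds `vel_frac` of the sac maximum
#' (strict `>`, `>=`-at-max fallback on uniform fields).
#'
#' @param cloud A derived `hemo_cloud`.
#' @param vel_frac Velocity threshold fraction in (0, 1), default 0.8.
#' @return Logical mask over surface points.
#' @export
find_inflow_jet <- function(cloud, vel_frac = 0.8) {
  if (is.null(cloud$velocity))
    stop("contract error: velocity channel missing")
  if (vel_frac <= 0 || vel_frac >= 1)
    stop("invalid-parameter: vel_frac must be in (0, 1)")
  v <- cloud$velocity
  mask <- v > vel_frac * max(v)
  if (!any(mask)) mask <- v >= max(v)
  mask
}

#' Sample the N x 8 region point matrix
#'
#' Draws `n` points uniformly from the union of the impingement and jet
#' masks (without replacement when the region is large enough, with
#' replacement otherwise, keeping N fixed for the network), and assembles
#' the 8 channels in the fixed column order
#' `(x, y, z, wss_sys, osi, pressure, velocity, tawss)`.
#'
#' @param cloud A derived `hemo_cloud`.
#' @param masks A list with elements `impingement` and `jet` (logical
#'   masks), e.g. from [find_impingement_zone()] / [find_inflow_jet()];
#'   or a single logical mask used as the union.
#' @param n Number of rows to sample (default 5000).
#' @param seed Integer seed.
#' @return An object of class `region_points`: list with `points`
#'   (n x 8 matrix), `source_mask` (per-row provenance: `"impingement"`,
#'   `"jet"` or `"both"`), `index` (sampled surface-point indices) and
#'   `subject_id`.
#' @export
sample_region_points <- function(cloud, masks, n = 5000, seed = 1) {
  if (n < 1) stop("invalid-parameter: n must be >= 1")
  if (is.list(masks)) {
    imp <- masks$impingement
    jet <- masks$jet
    union_mask <- imp | jet
  } else {
    imp <- masks; jet <- masks
    union_mask <- masks
  }
  idx_pool <- which(union_mask)
  if (length(idx_pool) == 0)
    stop(sprintf("region error: empty impingement/jet union for subject %s",
                 cloud$subject_id))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  idx <- if (length(idx_pool) >= n) sample(idx_pool, n)
         else sample(idx_pool, n, replace = TRUE)
  pts <- cloud$geometry$surface_points[idx, , drop = FALSE]
  mat <- cbind(pts,
               cloud$wss_sys[idx], cloud$osi[idx], cloud$pressure[idx],
               cloud$velocity[idx], cloud$tawss[idx])
  colnames(mat) <- region_channel_names()
  src <- ifelse(imp[idx] & jet[idx], "both",
                ifelse(imp[idx], "impingement", "jet"))
  structure(list(points = mat, source_mask = src, index = idx,
                 subject_id = cloud$subject_id),
            class = "region_points")
}

#' Fixed channel order of the region point matrix
#' @return Character vector of the 8 column names.
#' @export
region_channel_names <- function() {
  c("x", "y", "z", "wss_sys", "osi", "pressure", "velocity", "tawss")
}

#' @export
print.region_points <- function(x, ...) {
  cat(sprintf("region_points %s: %d x %d (%s)\n", x$subject_id,
              nrow(x$points), ncol(x$points),
              paste(names(table(x$source_mask)), collapse = "/")))
  invisible(x)
}

#' Extract the region point set of one subject in one call
#'
#' @param cloud A derived `hemo_cloud`.
#' @param n Sample size (default 5000).
#' @param frac,jet_radius_frac,vel_frac Threshold parameters, see
#'   [find_impingement_zone()] and [find_inflow_jet()].
#' @param seed Integer seed.
#' @return A `region_points` object.
#' @export
extract_regions <- function(cloud, n = 5000, frac = 0.8,
                            jet_radius_frac = 0.1, vel_frac = 0.8,
                            seed = 1) {
  masks <- list(impingement = find_impingement_zone(cloud, frac,
                                                    jet_radius_frac),
                jet = find_inflow_jet(cloud, vel_frac))
  sample_region_points(cloud, masks, n = n, seed = seed)
}

#' Region point sets for a whole cohort
#'
#' @param cohort An `ia_cohort` of derived clouds.
#' @param n Points per subject.
#' @param seed Master seed (per-subject seeds derive from it).
#' @param ... Passed to [extract_regions()].
#' @return A list of `region_points`, one per subject.
#' @export
cohort_regions <- function(cohort, n = 5000, seed = 1, ...) {
  lapply(seq_along(cohort), function(i)
    extract_regions(cohort[[i]], n = n,
                    seed = as.integer(seed %% 100000L) * 10000L + i, ...))
}
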