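#' Sample a parametric aneurysm-sac surface
#'
#' Generates a point-sampled spherical-cap sac: the portion of a sphere of
#' the given `radius` above the neck plane implied by `neck_width`. For
#' `neck_width = 2 * radius` the sac is a hemisphere; narrower necks give
#' over-hemispherical domes of height `radius + sqrt(radius^2 -
#' (neck_width/2)^2)`. `shape_flag = "irregular"` superimposes random
#' smooth radial lobes (daughter-sac-like bumps) on the dome.
#'
#' Points are drawn area-uniformly on the cap (uniform height, uniform
#' azimuth), plus an explicit ring of points on the neck curve and the
#' dome apex, so `neck_ring` and `dome_tip` are exact. Per-point area
#' weights split the analytic cap area evenly and, for irregular sacs, are
#' rescaled by the squared local radial stretch.
#'
#' @param radius Sphere radius in mm.
#' @param neck_width Neck (ostium) diameter in mm, in `(0, 2*radius]`.
#' @param parent_diameter Parent-vessel diameter in mm.
#' @param shape_flag `"smooth"` or `"irregular"`.
#' @param location_flag `"sidewall"` or `"bifurcation"`.
#' @param n_points Total number of surface points (>= 50).
#' @param n_neck Number of points placed exactly on the neck curve.
#' @param seed Integer seed; output is a pure function of seed + arguments.
#'
#' @return An object of class `sac_geometry`: list with `surface_points`
#'   (n x 3, mm), `point_areas` (mm^2), `point_normals` (unit outward),
#'   `neck_ring` (indices), `dome_tip` (index), `parent_diameter`,
#'   `radius`, `neck_width`, `neck_z` (neck-plane height in the sac frame),
#'   `shape_flag`, `location_flag`.
#' @examples
#' g <- make_sac_geometry(3, 6, 4, n_points = 500, seed = 1)
#' sum(g$point_areas)        # ~ 2*pi*3^2 (hemisphere)
#' @export
make_sac_geometry <- function(radius, neck_width, parent_diameter,
                              shape_flag = c("smooth", "irregular"),
                              location_flag = c("sidewall", "bifurcation"),
                              n_points = 2000, n_neck = 64, seed = 1) {
  shape_flag <- match.arg(shape_flag)
  location_flag <- match.arg(location_flag)
  if (radius <= 0 || neck_width <= 0 || parent_diameter <= 0)
    stop("invalid-parameter: dimensions must be positive")
  if (neck_width > 2 * radius + 1e-12)
    stop("invalid-parameter: neck_width must not exceed 2 * radius")
  if (n_points < 50)
    stop("invalid-parameter: n_points must be at least 50")

  # neck plane z = z0; cap is the sphere above it (dome over-hemispherical
  # when the neck is narrower than the equator)
  z0 <- -sqrt(max(radius^2 - (neck_width / 2)^2, 0))
  height <- radius - z0
  cap_area <- 2 * pi * radius * height

  n_dome <- n_points - n_neck - 1L
  if (n_dome < 10)
    stop("invalid-parameter: n_points too small for the requested neck ring")

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  # area-uniform sampling on the zone z in (z0, radius): z uniform
  z <- stats::runif(n_dome, min = z0, max = radius)
  phi <- stats::runif(n_dome, min = 0, max = 2 * pi)
  rho <- sqrt(pmax(radius^2 - z^2, 0))
  dome <- cbind(rho * cos(phi), rho * sin(phi), z)

  ring_phi <- seq(0, 2 * pi, length.out = n_neck + 1L)[-(n_neck + 1L)]
  ring_rho <- neck_width / 2
  ring <- cbind(ring_rho * cos(ring_phi), ring_rho * sin(ring_phi),
                rep(z0, n_neck))
  tip <- matrix(c(0, 0, radius), nrow = 1)

  pts <- rbind(dome, ring, tip)
  dimnames(pts) <- NULL
  normals <- pts / radius            # sphere centred at the origin
  stretch <- rep(1, nrow(pts))

  if (shape_flag == "irregular") {
    n_lobes <- sample(2:3, 1)
    # lobe centres on the upper dome (z > radius/3)
    cz <- stats::runif(n_lobes, min = radius / 3, max = 0.95 * radius)
    cphi <- stats::runif(n_lobes, min = 0, max = 2 * pi)
    crho <- sqrt(pmax(radius^2 - cz^2, 0))
    centres <- cbind(crho * cos(cphi), crho * sin(cphi), cz)
    amp <- stats::runif(n_lobes, min = 0.10, max = 0.22)
    width <- stats::runif(n_lobes, min = 0.25, max = 0.45) * radius
    # taper to zero towards the neck so the ring stays fixed
    taper <- pmax((pts[, 3] - z0) / height, 0)
    for (j in seq_len(n_lobes)) {
      d2 <- rowSums((pts - matrix(centres[j, ], nrow(pts), 3,
                                  byrow = TRUE))^2)
      stretch <- stretch + amp[j] * exp(-d2 / (2 * width[j]^2)) * taper
    }
    idx <- seq_len(nrow(pts) - 1L - n_neck)           # dome points only
    keep <- c(idx, nrow(pts))                          # and the tip
    pts[keep, ] <- pts[keep, ] * stretch[keep]
    # radial bumps keep the outward direction approximately radial
  }

  areas <- rep(cap_area / nrow(pts), nrow(pts)) * stretch^2

  structure(list(
    surface_points = pts,
    point_areas = areas,
    point_normals = normals,
    neck_ring = seq.int(n_dome + 1L, n_dome + n_neck),
    dome_tip = nrow(pts),
    parent_diameter = parent_diameter,
    radius = radius,
    neck_width = neck_width,
    neck_z = z0,
    shape_flag = shape_flag,
    location_flag = location_flag
  ), class = "sac_geometry")
}

#' @export
print.sac_geometry <- function(x, ...) {
  cat(sprintf(
    "sac_geometry: %d points, radius %.2f mm, neck %.2f mm, %s %s\n",
    nrow(x$surface_points), x$radius, x$neck_width, x$shape_flag,
    x$location_flag))
  invisible(x)
}

# RNG bookkeeping so generators do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
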