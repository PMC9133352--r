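#' Morphological variables of an aneurysm sac
#'
#' Computes the ten standard morphological descriptors from a point-sampled
#' sac surface:
#' neck width (largest distance across the neck curve), height (largest
#' distance from the least-squares neck plane to the dome), parent-vessel
#' diameter, size ratio SR = height / vessel diameter, aspect ratio
#' AR = height / neck width, surface area (sum of point area weights),
#' volume (divergence theorem over the closed surface, with the neck
#' opening capped by a flat disk), the surface-to-volume ratio S/V, and the
#' two categorical flags (shape: 0 smooth / 1 irregular; location: 0
#' sidewall / 1 bifurcation).
#'
#' @param geometry A [make_sac_geometry()] object (or any list with the
#'   same fields).
#' @param height_method `"plane"` (perpendicular distance from the
#'   least-squares neck plane, the default) or `"max_distance"` (largest
#'   distance from the neck centroid to any surface point).
#'
#' @return An object of class `morpho_vector`: a named list of the 10
#'   variables.
#' @examples
#' g <- make_sac_geometry(3, 6, 4, n_points = 1000, seed = 1)
#' m <- compute_morphology(g)
#' m$aspect_ratio  # ~ 0.5 for a hemisphere
#' @export
compute_morphology <- function(geometry,
                               height_method = c("plane", "max_distance")) {
  height_method <- match.arg(height_method)
  pts <- geometry$surface_points
  ring_idx <- geometry$neck_ring
  if (length(ring_idx) < 3)
    stop("geometry error: neck_ring must contain at least 3 points")
  ring <- pts[ring_idx, , drop = FALSE]

  centroid <- colMeans(ring)
  centred <- sweep(ring, 2, centroid)
  sv <- svd(centred)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("geometry error: degenerate neck ring (points are collinear)")
  normal <- sv$v[, 3]
  # orient the plane normal towards the dome
  signed <- as.numeric(sweep(pts, 2, centroid) %*% normal)
  if (sum(signed > 0) < sum(signed < 0)) {
    normal <- -normal
    signed <- -signed
  }

  neck_width <- max(stats::dist(ring))
  height <- switch(height_method,
    plane = max(signed),
    max_distance = sqrt(max(rowSums(sweep(pts, 2, centroid)^2)))
  )
  if (height <= 0) stop("geometry error: sac has no extent above the neck plane")

  surface_area <- sum(geometry$point_areas)

  # divergence theorem: V = (1/3) oint (x - c) . n dA over the closed
  # surface, taking the ring centroid as origin so the estimate is exactly
  # translation-invariant despite the discrete (not exactly closed) flux;
  # the sac samples contribute pointwise, the neck opening as one flat disk
  rel <- sweep(pts, 2, centroid)
  flux_sac <- sum(rowSums(rel * geometry$point_normals) *
                    geometry$point_areas)
  volume <- flux_sac / 3   # the disk term vanishes about its own centroid
  if (volume <= 0) stop("geometry error: non-positive enclosed volume")

  structure(list(
    neck_width = neck_width,
    height = height,
    vessel_diameter = geometry$parent_diameter,
    size_ratio = height / geometry$parent_diameter,
    aspect_ratio = height / neck_width,
    surface_area = surface_area,
    volume = volume,
    s_over_v = surface_area / volume,
    shape_flag = as.integer(identical(geometry$shape_flag, "irregular")),
    location_flag = as.integer(identical(geometry$location_flag, "bifurcation"))
  ), class = "morpho_vector")
}

#' @export
print.morpho_vector <- function(x, ...) {
  cat("morpho_vector:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.data.frame.morpho_vector <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Morphology table for a whole cohort
#'
#' @param cohort A list of hemodynamic clouds (see [generate_cohort()]).
#' @param ... Passed to [compute_morphology()].
#' @return A data.frame with `subject_id`, `label` and the 10 variables.
#' @export
cohort_morphology <- function(cohort, ...) {
  rows <- lapply(cohort, function(cl) {
    cbind(data.frame(subject_id = cl$subject_id, label = cl$label,
                     stringsAsFactors = FALSE),
          as.data.frame(compute_morphology(cl$geometry, ...)))
  })
  do.call(rbind, rows)
}
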