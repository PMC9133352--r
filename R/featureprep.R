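#' Fold-safe z-score normalization
#'
#' Fits per-column centring/scaling statistics on `fit_rows` only and
#' applies them to the whole table, so held-out rows are transformed with
#' training statistics. Columns that are constant on the fitting rows are
#' mapped to zero (scale floored at 1) with a warning.
#'
#' @param x Numeric matrix or data.frame of features.
#' @param fit_rows Row indices used to fit the statistics (default: all).
#' @return An object of class `feature_scaler`: list with `scaled` (the
#'   transformed table), `center`, `scale`.
#' @export
normalize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  if (length(fit_rows) == 0) stop("contract error: fit_rows is empty")
  ctr <- colMeans(x[fit_rows, , drop = FALSE])
  scl <- apply(x[fit_rows, , drop = FALSE], 2, stats::sd)
  if (any(is.na(scl))) scl[is.na(scl)] <- 0
  const <- scl < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant column(s) mapped to zero", sum(const)))
    scl[const] <- 1
  }
  out <- structure(list(center = ctr, scale = scl), class = "feature_scaler")
  out$scaled <- predict(out, x)
  out
}

#' @export
predict.feature_scaler <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
}

#' Recursive feature elimination with a linear-margin model
#'
#' Iteratively fits a linear-kernel SVM and removes the features with the
#' smallest absolute weight until `n_keep` remain. `step` controls how
#' many features fall per iteration: an integer >= 1 removes that many, a
#' fraction in (0, 1) removes that fraction of the currently surviving
#' features (at least one), never overshooting `n_keep`.
#'
#' @param x Numeric feature matrix (pre-normalized; columns named).
#' @param y 0/1 labels.
#' @param n_keep Number of features to retain (< ncol(x)).
#' @param step Elimination granularity (default 1: classic one-at-a-time).
#' @param cost SVM cost parameter.
#' @return Character vector of kept column names, in original order.
#' @export
rfe_select <- function(x, y, n_keep, step = 1, cost = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  if (n_keep >= ncol(x))
    stop("contract error: n_keep must be smaller than the number of columns")
  if (n_keep < 1) stop("contract error: n_keep must be >= 1")
  keep <- colnames(x)
  yf <- factor(y, levels = sort(unique(y)))
  while (length(keep) > n_keep) {
    fit <- e1071::svm(x[, keep, drop = FALSE], yf, kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    imp <- abs(w)
    n_drop <- if (step < 1) max(1L, floor(step * length(keep))) else
      as.integer(step)
    n_drop <- min(n_drop, length(keep) - n_keep)
    drop_idx <- order(imp, seq_along(imp))[seq_len(n_drop)]
    keep <- keep[-drop_idx]
  }
  colnames(x)[colnames(x) %in% keep]
}

#' Kernel PCA reduction with a reusable transform
#'
#' Fits kernel PCA on the fitting rows and projects any rows (including
#' held-out ones) onto the leading components. The default kernel is RBF
#' with the median-heuristic bandwidth (sigma = 1 / (2 m^2), m the median
#' pairwise Euclidean distance among fitting rows); `kernel = "linear"`
#' recovers classical PCA scores up to per-component sign.
#'
#' @param x Numeric feature matrix.
#' @param n_components Number of components (< number of fitting rows).
#' @param kernel `"rbf"` or `"linear"`.
#' @param sigma Optional RBF bandwidth (kernlab parametrization
#'   `exp(-sigma * |x - y|^2)`); median heuristic when `NULL`.
#' @param fit_rows Rows used to fit the kernel map (default: all).
#' @return An object of class `kpca_transform`: list with `scores` (all
#'   rows projected), the fitted `kpca` object and the kernel settings.
#' @export
kpca_reduce <- function(x, n_components, kernel = c("rbf", "linear"),
                        sigma = NULL, fit_rows = seq_len(nrow(x))) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  xf <- x[fit_rows, , drop = FALSE]
  if (n_components >= length(fit_rows))
    stop("contract error: n_components must be below the number of fitting rows")
  if (kernel == "rbf") {
    if (is.null(sigma)) {
      m <- stats::median(stats::dist(xf))
      sigma <- if (m > 0) 1 / (2 * m^2) else 1
    }
    kern <- kernlab::rbfdot(sigma = sigma)
  } else {
    kern <- kernlab::vanilladot()
  }
  fit <- kernlab::kpca(xf, kernel = kern, features = n_components)
  out <- structure(list(fit = fit, kernel = kernel, sigma = sigma,
                        n_components = n_components,
                        n_fit = length(fit_rows)),
                   class = "kpca_transform")
  out$scores <- predict(out, x)
  out
}

#' @export
predict.kpca_transform <- function(object, newdata, ...) {
  # rescale to the classical PCA score convention (kernlab returns
  # sqrt(n)-inflated projections)
  sc <- kernlab::predict(object$fit, as.matrix(newdata)) /
    sqrt(object$n_fit)
  colnames(sc) <- sprintf("kpc_%02d", seq_len(ncol(sc)))
  sc
}

#' Default feature-pipeline configuration
#'
#' The 1,024 cloud features are z-normalized, screened to `rfe_keep`
#' columns by [rfe_select()] (with coarse `rfe_step` for tractability on
#' the wide block), then reduced to `kpca_components` kernel-PCA scores.
#' The 28 base features are normalized only.
#'
#' @param rfe_keep Cloud features surviving RFE (default 64).
#' @param rfe_step RFE elimination granularity for the cloud block
#'   (default 0.5: halve per iteration).
#' @param kpca_components Kernel-PCA components kept (default 16).
#' @param kpca_kernel `"rbf"` (default) or `"linear"`.
#' @return A `featureprep_config` list.
#' @export
featureprep_config <- function(rfe_keep = 64L, rfe_step = 0.5,
                               kpca_components = 16L,
                               kpca_kernel = "rbf") {
  structure(list(rfe_keep = as.integer(rfe_keep), rfe_step = rfe_step,
                 kpca_components = as.integer(kpca_components),
                 kpca_kernel = kpca_kernel),
            class = "featureprep_config")
}

#' Column roster of the 28 base features
#' @return Character vector: 10 morphological + 18 hemodynamic names.
#' @export
base_feature_names <- function() {
  c("neck_width", "height", "vessel_diameter", "size_ratio",
    "aspect_ratio", "surface_area", "volume", "s_over_v", "shape_flag",
    "location_flag",
    "wss_max", "wss_avg", "wss_min", "tawss_max", "tawss_avg", "tawss_min",
    "osi_max", "osi_avg", "osi_min", "pressure_max", "pressure_avg",
    "pressure_min", "velocity_max", "velocity_avg", "velocity_min",
    "hoa", "lsa", "energy_loss")
}

# merge morpho + hemo tables into the raw 28-column base matrix, aligned
# and validated by subject_id
.merge_base <- function(morpho, hemo) {
  if (!all(c("subject_id", "label") %in% names(morpho)) ||
      !all(c("subject_id", "label") %in% names(hemo)))
    stop("contract error: morpho/hemo tables need subject_id and label")
  missing_m <- setdiff(hemo$subject_id, morpho$subject_id)
  missing_h <- setdiff(morpho$subject_id, hemo$subject_id)
  if (length(missing_m) || length(missing_h))
    stop(sprintf("alignment error: subject(s) %s missing from %s table",
                 paste(c(missing_m, missing_h), collapse = ", "),
                 if (length(missing_m)) "morphology" else "hemodynamics"))
  hemo <- hemo[match(morpho$subject_id, hemo$subject_id), ]
  base <- cbind(morpho[, setdiff(names(morpho), c("subject_id", "label"))],
                hemo[, setdiff(names(hemo), c("subject_id", "label"))])
  base <- as.matrix(base[, base_feature_names()])
  rownames(base) <- morpho$subject_id
  list(base = base,
       labels = as.integer(morpho$label == "ruptured"),
       subject_id = morpho$subject_id)
}

#' Assemble feature groups A and B
#'
#' Group A holds the 28 base features (10 morphological + 18
#' hemodynamic), z-normalized on `fit_rows`. Group B appends the cloud
#' feature block processed by normalize -> RFE -> kernel PCA, all fitted
#' on `fit_rows` only.
#'
#' @param morpho Output of [cohort_morphology()] (or the same CSV read
#'   back).
#' @param hemo Output of [cohort_hemodynamics()].
#' @param cloud Matrix of 1,024 cloud features per subject
#'   ([extract_features()]), or `NULL` for group A alone.
#' @param config A [featureprep_config()].
#' @param fit_rows Rows on which every transform is fitted (default: all;
#'   the CV harness passes training-fold rows).
#' @return A list with `A` and (when `cloud` is given) `B`, each an
#'   object of class `feature_table` (`features`, `labels`,
#'   `subject_id`, `group_tag`).
#' @export
assemble_groups <- function(morpho, hemo, cloud = NULL,
                            config = featureprep_config(),
                            fit_rows = NULL) {
  mb <- .merge_base(morpho, hemo)
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(mb$base))
  ft <- function(features, tag)
    structure(list(features = features, labels = mb$labels,
                   subject_id = mb$subject_id, group_tag = tag),
              class = "feature_table")
  sc <- normalize_features(mb$base, fit_rows)
  out <- list(A = ft(sc$scaled, "A"))
  if (!is.null(cloud)) {
    cloud <- as.matrix(cloud)
    if (nrow(cloud) != nrow(mb$base))
      stop("alignment error: cloud feature rows do not match the cohort")
    if (!is.null(rownames(cloud)) &&
        !identical(rownames(cloud), mb$subject_id)) {
      if (!setequal(rownames(cloud), mb$subject_id))
        stop(sprintf("alignment error: subject(s) %s missing from cloud table",
                     paste(setdiff(mb$subject_id, rownames(cloud)),
                           collapse = ", ")))
      cloud <- cloud[mb$subject_id, , drop = FALSE]
    }
    csc <- normalize_features(cloud, fit_rows)
    kept <- rfe_select(csc$scaled[fit_rows, , drop = FALSE],
                       mb$labels[fit_rows], n_keep = config$rfe_keep,
                       step = config$rfe_step)
    kp <- kpca_reduce(csc$scaled[, kept, drop = FALSE],
                      n_components = config$kpca_components,
                      kernel = config$kpca_kernel, fit_rows = fit_rows)
    out$B <- ft(cbind(sc$scaled, kp$scores), "B")
  }
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table group %s: %d subjects x %d features\n",
              x$group_tag, nrow(x$features), ncol(x$features)))
  invisible(x)
}
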