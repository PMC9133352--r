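#' Classifier specification
#'
#' Fixed-hyperparameter specifications for the five classifiers compared
#' in the study harness: random forest (`RF`), k-nearest neighbours
#' (`KNN`), gradient-boosted trees (`XGB`), RBF support vector machine
#' (`SVM`) and ridge-penalized logistic regression (`LR`). Hyperparameters
#' stay fixed across all repetitions of a run; any default can be
#' overridden through `params`.
#'
#' @param name One of `"RF"`, `"KNN"`, `"XGB"`, `"SVM"`, `"LR"`.
#' @param params Named list of hyperparameter overrides.
#' @param seed Seed used by stochastic learners.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name = c("RF", "KNN", "XGB", "SVM", "LR"),
                       params = list(), seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    RF = list(ntree = 300L),
    KNN = list(k = 5L),
    XGB = list(nrounds = 60L, max_depth = 3L, eta = 0.1,
               subsample = 1, nthread = 1L),
    SVM = list(cost = 10, gamma = NULL,   # NULL gamma -> 1/ncol
               class_weights = NULL),
    LR = list(lambda = 0.05, alpha = 0)
  )
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

#' The default five-classifier roster
#' @param seed Seed shared by the specs.
#' @return Named list of [model_spec()]s.
#' @export
default_models <- function(seed = 1L) {
  nm <- c("RF", "KNN", "XGB", "SVM", "LR")
  stats::setNames(lapply(nm, model_spec, seed = seed), nm)
}

# fit on (xtr, ytr), return scores in [0, 1] for xte (monotone in the
# estimated probability of the positive class)
.fit_predict <- function(spec, xtr, ytr, xte) {
  p <- spec$params
  yf <- factor(ytr, levels = c(0, 1))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  switch(spec$name,
    RF = {
      fit <- randomForest::randomForest(xtr, yf, ntree = p$ntree)
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    KNN = {
      pr <- class::knn(xtr, xte, yf, k = p$k, prob = TRUE)
      frac <- attr(pr, "prob")
      ifelse(pr == "1", frac, 1 - frac)
    },
    XGB = {
      dtr <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = p$nthread)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = p$max_depth, eta = p$eta,
                      subsample = p$subsample, nthread = p$nthread,
                      seed = spec$seed),
        data = dtr, nrounds = p$nrounds, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(xte, nthread = p$nthread))
    },
    SVM = {
      gamma <- if (is.null(p$gamma)) 1 / ncol(xtr) else p$gamma
      cw <- NULL
      if (identical(p$class_weights, "balanced")) {
        tab <- table(yf)
        cw <- as.numeric(length(yf) / (2 * tab))
        names(cw) <- names(tab)
      }
      fit <- e1071::svm(xtr, yf, kernel = "radial", cost = p$cost,
                        gamma = gamma, scale = FALSE,
                        class.weights = cw)
      dvm <- attr(stats::predict(fit, xte, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # the column name "a/b" says positive values favour class a
      if (!startsWith(colnames(dvm)[1], "1/")) dv <- -dv
      stats::plogis(dv)
    },
    LR = {
      fit <- glmnet::glmnet(xtr, yf, family = "binomial",
                            alpha = p$alpha, lambda = p$lambda)
      as.numeric(stats::predict(fit, xte, type = "response"))
    }
  )
}

#' Threshold and ranking metrics of one score vector
#'
#' Sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) with ruptured
#' (label 1) as the positive class; accuracy = (TP+TN)/n; AUC by the
#' rank-sum statistic with midranks for ties.
#'
#' @param scores Numeric scores (higher = more rupture-like).
#' @param labels 0/1 vector, both classes present.
#' @param threshold Score cut-off for the confusion matrix (default 0.5).
#' @return Named numeric vector `accuracy`, `auc`, `sensitivity`,
#'   `specificity`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("contract error: scores and labels must be aligned")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("contract error: both classes must be present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  r <- rank(scores)                      # midranks for ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  c(accuracy = (tp + tn) / length(labels), auc = auc,
    sensitivity = tp / n_pos, specificity = tn / n_neg)
}

#' Normal-approximation 95% interval over repetition AUCs
#'
#' @param per_repetition_aucs Numeric vector, length >= 2.
#' @return Named vector `mean`, `lower`, `upper` (mean +/- 1.96 sd/sqrt(n)).
#' @export
auc_interval <- function(per_repetition_aucs) {
  n <- length(per_repetition_aucs)
  if (n < 2) stop("contract error: need at least 2 repetitions")
  m <- mean(per_repetition_aucs)
  hw <- 1.96 * stats::sd(per_repetition_aucs) / sqrt(n)
  c(mean = m, lower = m - hw, upper = m + hw)
}

# stratified fold assignment: shuffle within class, deal round-robin
.stratified_folds <- function(labels, k) {
  n_min <- min(table(labels))
  if (k > n_min)
    stop(sprintf(
      "stratified folding error: k = %d exceeds the minority-class count %d; use a smaller k",
      k, n_min))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' A dataset bundle for cross-validated evaluation
#'
#' Carries the raw ingredients so that every transform (normalization,
#' RFE, kernel PCA, and in full mode the extractor itself) can be refit
#' inside each training fold.
#'
#' @param morpho,hemo Descriptor tables ([cohort_morphology()],
#'   [cohort_hemodynamics()]).
#' @param regions Optional list of `region_points` (enables group B).
#' @param prep A [featureprep_config()].
#' @param net A [cloudnet_config()] used when the extractor is refit per
#'   fold.
#' @return A `cv_dataset` object.
#' @export
cv_dataset <- function(morpho, hemo, regions = NULL,
                       prep = featureprep_config(),
                       net = cloudnet_config()) {
  mb <- .merge_base(morpho, hemo)
  structure(list(morpho = morpho, hemo = hemo, regions = regions,
                 labels = mb$labels, subject_id = mb$subject_id,
                 prep = prep, net = net),
            class = "cv_dataset")
}

#' Repeated stratified k-fold evaluation of one classifier
#'
#' Repeats stratified k-fold cross-validation `n_repeats` times with
#' reshuffled folds, scoring one classifier on one feature group. All
#' preprocessing is fold-contained: base features are normalized with
#' training-fold statistics, and for group B the cloud block is
#' normalized, RFE-screened and KPCA-reduced per training fold. With
#' `extractor = "fold"` (the default) the point-set network itself is
#' retrained on the training folds of every split so the evaluation
#' features of test subjects never see their labels; `"single"` fits it
#' once on all subjects (optimistically biased, kept for comparison);
#' `"none"` evaluates group A.
#'
#' Per repetition, fold test scores are pooled and summarized once
#' (accuracy, AUC, sensitivity, specificity).
#'
#' @param dataset A [cv_dataset()].
#' @param model A [model_spec()].
#' @param n_repeats Number of CV repetitions (the study design uses 100).
#' @param k Folds (default 10).
#' @param seed Master seed; per-repetition seeds derive from it.
#' @param group `"A"` or `"B"`.
#' @param extractor Extractor hygiene for group B, see above.
#' @return A `cv_report`: list with `per_repetition` (data.frame of the 4
#'   metrics per repetition), `fold_records` (one row per repetition x
#'   fold with the fold-level metrics), `mean_metrics`, `auc_ci`,
#'   `n_repeats`, `k`, `model`, `group`, `seed`.
#' @export
run_repeated_cv <- function(dataset, model, n_repeats = 5, k = 10,
                            seed = 1,
                            group = c("A", "B"),
                            extractor = c("fold", "single", "none")) {
  group <- match.arg(group)
  extractor <- match.arg(extractor)
  if (group == "A") extractor <- "none"
  core <- .run_cv_core(dataset, stats::setNames(list(model), model$name),
                       groups = group, n_repeats = n_repeats, k = k,
                       seed = seed, extractor = extractor)
  core[[model$name]][[group]]
}

# shared engine: one pass over repetitions and folds; the fold-contained
# transforms (and the per-fold extractor) are fitted once per fold and
# reused by every classifier
.run_cv_core <- function(dataset, models, groups, n_repeats, k, seed,
                         extractor) {
  if ("B" %in% groups && is.null(dataset$regions))
    stop("contract error: group B requested but the dataset has no regions")
  labels <- dataset$labels
  n <- length(labels)

  single_weights <- NULL
  if ("B" %in% groups && extractor == "single") {
    cfg <- dataset$net; cfg$seed <- as.integer(seed)
    single_weights <- train_extractor(dataset$regions, labels, cfg)
  }

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)

  metr <- lapply(models, function(m)
    lapply(stats::setNames(groups, groups), function(g)
      vector("list", n_repeats)))
  frec <- lapply(models, function(m)
    lapply(stats::setNames(groups, groups), function(g) list()))
  for (r in seq_len(n_repeats)) {
    rep_seed <- as.integer((seed * 131 + r * 7) %% 2147483)
    set.seed(rep_seed)
    folds <- .stratified_folds(labels, k)
    scores <- lapply(models, function(m)
      lapply(stats::setNames(groups, groups), function(g)
        rep(NA_real_, n)))
    for (f in seq_len(k)) {
      te <- which(folds == f); tr <- which(folds != f)
      fold_seed <- as.integer((rep_seed * 100 + f) %% 2147483)
      feats <- .fold_features(dataset, tr, groups, extractor,
                              single_weights, fold_seed)
      for (nm in names(models)) {
        sp <- models[[nm]]; sp$seed <- fold_seed
        for (g in groups) {
          x <- feats[[g]]
          sc <- .fit_predict(sp, x[tr, , drop = FALSE], labels[tr],
                             x[te, , drop = FALSE])
          scores[[nm]][[g]][te] <- sc
          fm <- compute_metrics(sc, labels[te])
          frec[[nm]][[g]][[length(frec[[nm]][[g]]) + 1L]] <-
            data.frame(repetition = r, fold = f, n_test = length(te),
                       as.list(fm))
        }
      }
    }
    for (nm in names(models)) for (g in groups)
      metr[[nm]][[g]][[r]] <- compute_metrics(scores[[nm]][[g]], labels)
  }

  lapply(stats::setNames(names(models), names(models)), function(nm)
    lapply(stats::setNames(groups, groups), function(g) {
      per_rep <- as.data.frame(do.call(rbind, metr[[nm]][[g]]))
      structure(list(per_repetition = per_rep,
                     fold_records = do.call(rbind, frec[[nm]][[g]]),
                     mean_metrics = colMeans(per_rep),
                     auc_ci = if (n_repeats >= 2) auc_interval(per_rep$auc)
                              else NULL,
                     n_repeats = n_repeats, k = k,
                     model = nm, group = g, seed = seed),
                class = "cv_report")
    }))
}

# fold-contained feature construction: fit everything on rows `tr`;
# returns a named list over the requested groups
.fold_features <- function(dataset, tr, groups, extractor, single_weights,
                           fold_seed) {
  cloud <- NULL
  if ("B" %in% groups) {
    weights <- if (extractor == "single") single_weights else {
      cfg <- dataset$net
      cfg$seed <- as.integer(fold_seed %% 2147483)
      train_extractor(dataset$regions[tr], dataset$labels[tr], cfg)
    }
    cloud <- extract_features(dataset$regions, weights)
  }
  grp <- suppressWarnings(
    assemble_groups(dataset$morpho, dataset$hemo, cloud = cloud,
                    config = dataset$prep, fit_rows = tr))
  out <- list()
  if ("A" %in% groups) out$A <- grp$A$features
  if ("B" %in% groups) out$B <- grp$B$features
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report %s/group %s: %d x %d-fold\n", x$model, x$group,
              x$n_repeats, x$k))
  print(round(x$mean_metrics, 4))
  invisible(x)
}

#' Paired comparison of two feature groups
#'
#' Two-sided Wilcoxon signed-rank test on per-repetition metric
#' differences (B minus A), paired by repetition. The exact null
#' distribution is used for n <= 25 when no zero or tied differences
#' occur, the normal approximation with continuity correction otherwise.
#' All-zero differences are flagged degenerate with p = 1.
#'
#' @param reportA,reportB `cv_report`s with equal repetition counts and
#'   matching seeds.
#' @param metric Metric column to compare (default `"auc"`).
#' @return List with `statistic`, `p_value`, `direction` (+1 if B > A on
#'   average), `mean_difference`, `metric`, `degenerate`.
#' @export
compare_groups <- function(reportA, reportB, metric = "auc") {
  a <- reportA$per_repetition[[metric]]
  b <- reportB$per_repetition[[metric]]
  if (length(a) != length(b))
    stop("contract error: repetition counts differ between reports")
  if (!identical(reportA$seed, reportB$seed))
    warning("reports built from different master seeds; pairing may be invalid")
  d <- b - a
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, direction = 0,
                mean_difference = 0, metric = metric, degenerate = TRUE))
  }
  exact <- length(d) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                            exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = sign(mean(d)), mean_difference = mean(d),
       metric = metric, degenerate = FALSE)
}

#' Full five-classifier, two-group experiment
#'
#' Runs [run_repeated_cv()] for every classifier on feature groups A and
#' B and pairs them with [compare_groups()], producing the study-shaped
#' summary: one row per model x group with AUC, its 95% CI, accuracy,
#' sensitivity and specificity.
#'
#' @param dataset A [cv_dataset()] with regions (group B enabled).
#' @param models List of [model_spec()]s (default: the five-model roster).
#' @param n_repeats,k,seed CV settings, as in [run_repeated_cv()].
#' @param extractor Extractor hygiene for group B.
#' @return An `ia_experiment`: list with `metrics` (10-row data.frame),
#'   `tests` (per-model paired AUC and accuracy tests), `reports` (all
#'   `cv_report`s), and the settings.
#' @export
run_experiment <- function(dataset, models = default_models(),
                           n_repeats = 5, k = 10, seed = 1,
                           extractor = c("fold", "single")) {
  extractor <- match.arg(extractor)
  core <- .run_cv_core(dataset, models, groups = c("A", "B"),
                       n_repeats = n_repeats, k = k, seed = seed,
                       extractor = extractor)
  reports <- list()
  rows <- list()
  tests <- list()
  for (nm in names(models)) {
    ra <- core[[nm]]$A
    rb <- core[[nm]]$B
    reports[[paste0(nm, "_A")]] <- ra
    reports[[paste0(nm, "_B")]] <- rb
    row <- function(r) data.frame(
      algorithm = nm, feature_group = r$group,
      auc = r$mean_metrics[["auc"]],
      auc_ci_lower = if (is.null(r$auc_ci)) NA_real_ else
        r$auc_ci[["lower"]],
      auc_ci_upper = if (is.null(r$auc_ci)) NA_real_ else
        r$auc_ci[["upper"]],
      accuracy = r$mean_metrics[["accuracy"]],
      sensitivity = r$mean_metrics[["sensitivity"]],
      specificity = r$mean_metrics[["specificity"]],
      stringsAsFactors = FALSE)
    rows[[paste0(nm, "_A")]] <- row(ra)
    rows[[paste0(nm, "_B")]] <- row(rb)
    tests[[nm]] <- data.frame(
      algorithm = nm,
      auc_p = compare_groups(ra, rb, "auc")$p_value,
      accuracy_p = compare_groups(ra, rb, "accuracy")$p_value,
      auc_direction = compare_groups(ra, rb, "auc")$direction,
      stringsAsFactors = FALSE)
  }
  structure(list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
                 tests = do.call(rbind, c(tests, make.row.names = FALSE)),
                 reports = reports,
                 n_repeats = n_repeats, k = k, seed = seed,
                 extractor = extractor),
            class = "ia_experiment")
}

#' @export
print.ia_experiment <- function(x, ...) {
  cat(sprintf("ia_experiment: %d repeats x %d-fold, extractor '%s'\n",
              x$n_repeats, x$k, x$extractor))
  print(transform(x$metrics,
                  auc = round(auc, 3), accuracy = round(accuracy, 3),
                  sensitivity = round(sensitivity, 3),
                  specificity = round(specificity, 3),
                  auc_ci_lower = round(auc_ci_lower, 3),
                  auc_ci_upper = round(auc_ci_upper, 3)))
  cat("paired tests (B vs A):\n")
  print(x$tests)
  invisible(x)
}
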