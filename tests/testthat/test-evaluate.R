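test_that("threshold metrics follow their definitions", {
  # TP=3 FN=1 TN=9 FP=1
  labels <- c(rep(1, 4), rep(0, 10))
  scores <- c(0.9, 0.8, 0.7, 0.2, rep(0.1, 9), 0.6)
  m <- compute_metrics(scores, labels)
  expect_equal(m[["sensitivity"]], 0.75)
  expect_equal(m[["specificity"]], 0.9)
  expect_equal(m[["accuracy"]], 12 / 14)
  # metric identity
  expect_equal(m[["accuracy"]],
               (m[["sensitivity"]] * 4 + m[["specificity"]] * 10) / 14)
  expect_error(compute_metrics(scores, rep(1, 14)), "both classes")
})

test_that("the rank AUC handles ties, perfection and monotone maps", {
  expect_equal(compute_metrics(rep(0.3, 6), c(1, 1, 0, 0, 0, 1))[["auc"]],
               0.5)
  expect_equal(compute_metrics(c(0.9, 0.8, 0.1, 0.2),
                               c(1, 1, 0, 0))[["auc"]], 1)
  set.seed(3)
  scores <- round(runif(50), 2)   # rounded to force some ties
  labels <- rbinom(50, 1, 0.4)
  auc <- compute_metrics(scores, labels)[["auc"]]
  expect_equal(auc, auc_pairs(scores, labels), tolerance = 1e-12)
  mono <- compute_metrics(stats::qlogis((scores + 0.01) / 1.02),
                          labels)[["auc"]]
  expect_equal(mono, auc, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  proc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(auc, proc, tolerance = 1e-12)
})

test_that("the repetition AUC interval is a normal approximation", {
  expect_equal(unname(auc_interval(rep(0.9, 5))), c(0.9, 0.9, 0.9))
  ci <- auc_interval(c(0.9, 1.0))
  expect_equal(ci[["mean"]], 0.95)
  expect_equal(ci[["upper"]] - ci[["mean"]],
               1.96 * stats::sd(c(0.9, 1)) / sqrt(2), tolerance = 1e-12)
  expect_true(ci[["lower"]] <= ci[["mean"]] &&
                ci[["mean"]] <= ci[["upper"]])
  expect_error(auc_interval(0.9), "2 repetitions")
})

test_that("paired group comparison matches exact enumeration", {
  mk <- function(aucs, seed = 1)
    structure(list(per_repetition = data.frame(auc = aucs,
                                               accuracy = aucs),
                   seed = seed), class = "cv_report")
  # all-positive differences, n = 6: two-sided p = 2/2^6
  a <- mk(rep(0.7, 6)); b <- mk(0.7 + c(1, 2, 3, 4, 5, 6) / 100)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$p_value, 1 / 32, tolerance = 1e-12)
  expect_equal(cmp$direction, 1)
  # swapping negates the direction, p unchanged
  rev <- compare_groups(b, a)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
  expect_equal(rev$direction, -1)
  # degenerate: identical reports
  deg <- compare_groups(a, a)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # oracle: full 2^n enumeration across random cases
  set.seed(12)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), 3)
    d[d == 0] <- 0.11
    while (any(duplicated(abs(d)))) d <- d + seq_along(d) * 1e-4
    cmp <- compare_groups(mk(rep(0.5, n)), mk(0.5 + d))
    expect_equal(cmp$p_value, wilcoxon_enum_p(d), tolerance = 1e-9)
  }
})

test_that("stratified folding rejects infeasible k", {
  coh <- suppressWarnings(generate_cohort(20, 0.2, "none", seed = 2,
                                          n_points = 80, n_neck = 24))
  ds <- cv_dataset(cohort_morphology(coh), cohort_hemodynamics(coh))
  expect_error(run_repeated_cv(ds, model_spec("RF"), n_repeats = 1,
                               k = 10, seed = 1, group = "A"),
               "smaller k")
})

make_toy_dataset <- function(n = 40, sep = 10, seed = 5) {
  coh <- generate_cohort(n, 0.5, "none", seed = seed, n_points = 80,
                         n_neck = 24)
  morpho <- cohort_morphology(coh)
  hemo <- cohort_hemodynamics(coh)
  if (sep > 0) {
    lab <- morpho$label == "ruptured"
    for (cn in c("wss_avg", "wss_max", "tawss_avg", "pressure_avg"))
      hemo[[cn]] <- hemo[[cn]] + sep * stats::sd(hemo[[cn]]) * lab
    for (cn in c("velocity_avg", "osi_avg"))
      hemo[[cn]] <- hemo[[cn]] - sep * stats::sd(hemo[[cn]]) * lab
  }
  cv_dataset(morpho, hemo)
}

test_that("perfectly separated classes score perfectly in every repetition", {
  ds <- make_toy_dataset(sep = 25)
  for (nm in c("RF", "SVM", "LR")) {
    r <- run_repeated_cv(ds, model_spec(nm), n_repeats = 2, k = 5,
                         seed = 3, group = "A")
    expect_equal(unname(r$per_repetition$auc), rep(1, 2), label = nm)
    expect_equal(unname(r$per_repetition$accuracy), rep(1, 2), label = nm)
  }
})

test_that("label-free data scores at chance", {
  ds <- make_toy_dataset(sep = 0, seed = 9)
  r <- run_repeated_cv(ds, model_spec("LR"), n_repeats = 5, k = 5,
                       seed = 2, group = "A")
  expect_gt(mean(r$per_repetition$auc), 0.3)
  expect_lt(mean(r$per_repetition$auc), 0.7)
})

test_that("repeated CV is deterministic and correctly shaped", {
  ds <- make_toy_dataset(sep = 3)
  r1 <- run_repeated_cv(ds, model_spec("XGB"), n_repeats = 3, k = 5,
                        seed = 7, group = "A")
  r2 <- run_repeated_cv(ds, model_spec("XGB"), n_repeats = 3, k = 5,
                        seed = 7, group = "A")
  expect_identical(r1$per_repetition, r2$per_repetition)
  expect_equal(nrow(r1$per_repetition), 3)
  expect_equal(nrow(r1$fold_records), 3 * 5)   # repetitions x folds
  expect_true(all(r1$fold_records$n_test >= 1))
  expect_true(all(r1$per_repetition$accuracy >= 0 &
                    r1$per_repetition$accuracy <= 1))
  expect_true(all(r1$per_repetition$auc >= 0 &
                    r1$per_repetition$auc <= 1))
})
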