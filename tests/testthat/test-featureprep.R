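test_that("normalization is fold-contained z-scoring", {
  set.seed(1)
  x <- matrix(rnorm(40, mean = 5, sd = 3), 10, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  sc <- normalize_features(x, fit_rows = 1:6)
  expect_equal(unname(colMeans(sc$scaled[1:6, ])), rep(0, 4),
               tolerance = 1e-9)
  expect_equal(unname(apply(sc$scaled[1:6, ], 2, sd)), rep(1, 4),
               tolerance = 1e-9)
  # held-out rows use training statistics, not their own
  own <- scale(x[7:10, ])
  expect_false(isTRUE(all.equal(sc$scaled[7:10, ], unclass(own),
                                check.attributes = FALSE)))
  expect_equal(predict(sc, x), sc$scaled)
  xc <- cbind(x, const = 7)
  expect_warning(scc <- normalize_features(xc, 1:6), "constant")
  expect_equal(unname(scc$scaled[, "const"]), rep(0, 10))
})

test_that("RFE keeps informative columns and drops redundancy", {
  set.seed(5)
  n <- 60
  y <- rep(0:1, each = n / 2)
  # one elimination step drops exactly one (least important) column
  x <- cbind(sig = y + rnorm(n, sd = 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n))
  kept <- rfe_select(scale(x), y, n_keep = 2)
  expect_length(kept, 2)
  expect_true("sig" %in% kept)
  # planted 3 informative among 20 noise columns
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    xs <- cbind(matrix(rnorm(n * 20), n), a = y + rnorm(n, sd = 0.4),
                b = -y + rnorm(n, sd = 0.4), c = 2 * y + rnorm(n, sd = 0.4))
    colnames(xs) <- c(paste0("n", 1:20), "a", "b", "c")
    kept <- rfe_select(scale(xs), y, n_keep = 5)
    if (all(c("a", "b", "c") %in% kept)) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # a duplicated column pair splits its weight, so the twins lose to an
  # equally informative singleton and cannot both survive
  set.seed(9)
  xd <- cbind(s1 = y + rnorm(n, sd = 0.3),
              s2 = y + rnorm(n, sd = 0.3),
              n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  xd <- cbind(xd, s1dup = xd[, "s1"])
  kept <- rfe_select(scale(xd), y, n_keep = 2)
  expect_lte(sum(c("s1", "s1dup") %in% kept), 1)
  expect_error(rfe_select(scale(x), y, n_keep = 3), "smaller")
})

test_that("fractional RFE steps reach the same small subsets faster", {
  set.seed(17)
  n <- 50
  y <- rep(0:1, each = 25)
  x <- cbind(sig = 2 * y + rnorm(n, sd = 0.4),
             matrix(rnorm(n * 15), n))
  colnames(x) <- c("sig", paste0("n", 1:15))
  kept <- rfe_select(scale(x), y, n_keep = 4, step = 0.5)
  expect_length(kept, 4)
  expect_true("sig" %in% kept)
})

test_that("linear-kernel KPCA recovers classical PCA scores", {
  set.seed(2)
  x <- matrix(rnorm(30 * 5), 30, 5)
  kp <- kpca_reduce(x, n_components = 3, kernel = "linear")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, 1:3]
  for (j in 1:3) {
    agree <- min(max(abs(kp$scores[, j] - pc[, j])),
                 max(abs(kp$scores[, j] + pc[, j])))
    expect_lt(agree, 1e-6)
  }
  # collinear points have no second direction of variance
  x2 <- cbind(1:6, 2 * (1:6)) + 0
  kp2 <- suppressWarnings(   # collinear fixture: near-zero eigenvalue
    kpca_reduce(x2, n_components = 2, kernel = "linear"))
  expect_lt(stats::var(kp2$scores[, 2]) / stats::var(kp2$scores[, 1]),
            1e-6)
})

test_that("kernel centering zeroes the Gram column sums", {
  # direct double-centering on a toy 4x4 kernel, the operation KPCA
  # relies on, cross-checked against an explicit eigen decomposition
  set.seed(4)
  x <- matrix(rnorm(8), 4, 2)
  K <- exp(-as.matrix(stats::dist(x))^2)
  one <- matrix(1 / 4, 4, 4)
  Kc <- K - one %*% K - K %*% one + one %*% K %*% one
  expect_equal(unname(colSums(Kc)), rep(0, 4), tolerance = 1e-12)
  # RBF KPCA scores match the centered-Gram eigenvectors up to sign
  sig <- 0.7
  kp <- kpca_reduce(x, n_components = 2, kernel = "rbf", sigma = sig)
  K2 <- exp(-sig * as.matrix(stats::dist(x))^2)
  K2c <- K2 - one %*% K2 - K2 %*% one + one %*% K2 %*% one
  ev <- eigen(K2c, symmetric = TRUE)
  manual <- K2c %*% (ev$vectors[, 1:2] %*%
                       diag(1 / sqrt(ev$values[1:2])))
  for (j in 1:2) {
    agree <- min(max(abs(kp$scores[, j] - manual[, j])),
                 max(abs(kp$scores[, j] + manual[, j])))
    expect_lt(agree, 1e-6)
  }
})

test_that("KPCA transforms apply to held-out rows", {
  set.seed(6)
  x <- matrix(rnorm(40 * 4), 40, 4)
  kp <- kpca_reduce(x, n_components = 3, fit_rows = 1:30)
  expect_equal(dim(kp$scores), c(40L, 3L))
  expect_equal(predict(kp, x[31:40, , drop = FALSE]),
               kp$scores[31:40, ], tolerance = 1e-10)
  expect_error(kpca_reduce(x, n_components = 40), "below")
})

test_that("assembled groups have the documented column structure", {
  coh <- suppressWarnings(generate_cohort(16, 0.5, "both", seed = 4,
                                          n_points = 120, n_neck = 24))
  morpho <- cohort_morphology(coh)
  hemo <- cohort_hemodynamics(coh)
  set.seed(8)
  cloud <- matrix(rnorm(16 * 1024), 16, 1024,
                  dimnames = list(morpho$subject_id,
                                  sprintf("cf_%04d", 1:1024)))
  cfg <- featureprep_config(rfe_keep = 16, kpca_components = 4)
  grp <- suppressWarnings(assemble_groups(morpho, hemo, cloud, cfg))
  expect_equal(ncol(grp$A$features), 28)
  expect_equal(ncol(grp$B$features), 28 + 4)
  expect_identical(grp$A$labels, grp$B$labels)
  # idempotent and order-stable
  grp2 <- suppressWarnings(assemble_groups(morpho, hemo, cloud, cfg))
  expect_identical(grp$B$features, grp2$B$features)
  # misalignment is reported with the subject name
  expect_error(assemble_groups(morpho[-3, ], hemo),
               morpho$subject_id[3])
})
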