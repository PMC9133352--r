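test_that("the pooled feature is permutation- and duplication-invariant", {
  w <- cn_init_weights(cloudnet_config(seed = 5))
  set.seed(3)
  m <- matrix(rnorm(60 * 8), 60, 8)
  f <- forward_features(m, w)
  expect_length(f, 1024)
  expect_true(all(is.finite(f)))
  for (i in 1:20) {
    fp <- forward_features(m[sample(nrow(m)), ], w)
    expect_lt(max(abs(fp - f)), 1e-6)
  }
  fd <- forward_features(rbind(m, m), w)
  expect_lt(max(abs(fd - f)), 1e-6)
})

test_that("a singleton cloud pools to its own embedding", {
  w <- cn_init_weights(cloudnet_config(seed = 2))
  one <- matrix(rnorm(8), 1, 8)
  f1 <- forward_features(one, w)
  f4 <- forward_features(one[rep(1, 4), ], w)
  expect_equal(f4, f1, tolerance = 1e-12)
})

test_that("intermediate widths follow the 8 -> 64 -> 1024 lift", {
  w <- cn_init_weights(cloudnet_config(seed = 1))
  X <- matrix(rnorm(10 * 8), 10, 8)
  fw <- aneucloud:::cn_forward(w$params, X, 1L, 10L, with_head = TRUE,
                               cache = TRUE)
  expect_equal(ncol(fw$cache$X), 8)
  expect_equal(dim(fw$cache$T1[[1]]), c(8, 8))
  expect_equal(ncol(fw$cache$Z2), 64)
  expect_equal(dim(fw$cache$T2[[1]]), c(64, 64))
  expect_equal(ncol(fw$cache$Z6), 1024)
  expect_equal(ncol(fw$G), 1024)
  expect_equal(ncol(fw$logits), 2)
})

test_that("both T-nets start at the identity transform", {
  w <- cn_init_weights(cloudnet_config(seed = 4))
  X <- matrix(rnorm(12 * 8), 12, 8)
  fw <- aneucloud:::cn_forward(w$params, X, 1L, 12L, cache = TRUE)
  expect_equal(fw$cache$T1[[1]], diag(8), tolerance = 1e-12)
  expect_equal(fw$cache$T2[[1]], diag(64), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cfg <- cloudnet_config(tnet1_hidden = 6, mlp1 = c(12, 64),
                         tnet2_hidden = 6, mlp2 = c(12, 6, 1024),
                         head = c(6, 4), seed = 3)
  params <- aneucloud:::cn_init_params(cfg)
  set.seed(42)
  S <- 3L; N <- 5L
  X <- matrix(rnorm(S * N * 8), S * N, 8)
  y <- c(0L, 1L, 1L)
  lg <- aneucloud:::cn_loss_grad(params, X, y, S, N, cfg$reg_weight)
  lossfn <- function(p)
    aneucloud:::cn_loss_grad(p, X, y, S, N, cfg$reg_weight)$loss
  eps <- 1e-6
  set.seed(7)
  for (nm in names(params)) {
    i <- sample(length(params[[nm]]), 1)
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    fd <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
    an <- lg$grads[[nm]][i]
    expect_lt(abs(fd - an) / (abs(fd) + abs(an) + 1e-8), 1e-5,
              label = nm)
  }
})

test_that("training is deterministic, label-aware and decreases the loss", {
  set.seed(10)
  regs <- lapply(1:12, function(i) matrix(rnorm(32 * 8), 32, 8))
  # plant a separable signature: positives have a shifted channel
  for (i in 7:12) regs[[i]][, 4] <- regs[[i]][, 4] + 3
  y <- rep(0:1, each = 6)
  cfg <- cloudnet_config(epochs = 8, batch_size = 6, lr = 2e-3, seed = 11)
  w1 <- train_extractor(regs, y, cfg)
  w2 <- train_extractor(regs, y, cfg)
  expect_equal(utils::tail(w1$loss_history, 1),
               utils::tail(w2$loss_history, 1), tolerance = 1e-6)
  expect_lt(utils::tail(w1$loss_history, 1), w1$loss_history[1])
  expect_error(train_extractor(regs, rep(0L, 12), cfg), "single class")
  expect_error(forward_features(matrix(1, 3, 5), w1), "8")
})

test_that("feature extraction is reproducible and non-degenerate", {
  set.seed(20)
  regs <- lapply(1:8, function(i) {
    m <- matrix(rnorm(24 * 8), 24, 8)
    if (i > 4) m[, 1] <- m[, 1] + 2
    m
  })
  y <- rep(0:1, each = 4)
  w <- train_extractor(regs, y,
                       cloudnet_config(epochs = 4, batch_size = 4,
                                       lr = 2e-3, seed = 3))
  ft1 <- extract_features(regs, w)
  ft2 <- extract_features(regs, w)
  expect_identical(ft1, ft2)
  expect_equal(dim(ft1), c(8L, 1024L))
  expect_gt(max(apply(ft1, 2, stats::sd)), 0)
})

test_that("checkpoints round-trip through the JSON format", {
  set.seed(30)
  regs <- lapply(1:6, function(i) matrix(rnorm(16 * 8), 16, 8))
  y <- rep(0:1, 3)
  w <- train_extractor(regs, y,
                       cloudnet_config(epochs = 2, batch_size = 6,
                                       seed = 8))
  f <- withr::local_tempfile(fileext = ".json")
  write_cloudnet(w, f)
  back <- read_cloudnet(f)
  expect_equal(forward_features(regs[[1]], back),
               forward_features(regs[[1]], w), tolerance = 1e-12)
  expect_error(read_cloudnet(withr::local_tempfile(lines = "{}",
                                                   fileext = ".json")),
               "checkpoint")
})
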