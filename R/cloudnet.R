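#' Configuration of the point-set feature extractor
#'
#' A compact, permutation-invariant point-set network in the PointNet
#' mould: an input transform (T-net) predicting an 8 x 8 affine applied to
#' each point's channel vector, a shared MLP lifting 8 -> 64 -> 64, a
#' feature transform (second T-net, 64 x 64), a second shared MLP lifting
#' 64 -> 128 -> 1024, and a channel-wise max-pool over points that yields
#' the 1,024-dimensional hemodynamic cloud feature. A detachable
#' 512-256-2 softmax head supervises training on rupture labels; the
#' feature transform carries an orthogonality penalty.
#'
#' @param in_channels Number of input channels; fixed at 8.
#' @param tnet1_hidden,tnet2_hidden Hidden widths of the two T-nets.
#' @param mlp1 Widths of the first shared MLP (length 2, ending in 64).
#' @param mlp2 Widths of the second shared MLP (length 3, ending in 1024).
#' @param head Widths of the two hidden classifier-head layers.
#' @param epochs,batch_size,lr Adam training schedule.
#' @param reg_weight Orthogonality penalty weight on the feature
#'   transform (default 1e-3).
#' @param seed Seed for initialization and batching.
#' @return A `cloudnet_config` list.
#' @export
cloudnet_config <- function(in_channels = 8L, tnet1_hidden = 32L,
                            mlp1 = c(64L, 64L), tnet2_hidden = 64L,
                            mlp2 = c(64L, 128L, 1024L),
                            head = c(512L, 256L),
                            epochs = 30L, batch_size = 16L, lr = 1e-3,
                            reg_weight = 1e-3, seed = 1L) {
  if (in_channels != 8L)
    stop("contract error: in_channels is fixed at 8")
  if (length(mlp1) != 2L || utils::tail(mlp1, 1) != 64L)
    stop("contract error: mlp1 must have two layers ending at width 64")
  if (length(mlp2) != 3L || utils::tail(mlp2, 1) != 1024L)
    stop("contract error: mlp2 must have three layers ending at width 1024")
  structure(list(in_channels = 8L, tnet1_hidden = as.integer(tnet1_hidden),
                 mlp1 = as.integer(mlp1), tnet2_hidden = as.integer(tnet2_hidden),
                 mlp2 = as.integer(mlp2), head = as.integer(head),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 reg_weight = reg_weight, seed = as.integer(seed)),
            class = "cloudnet_config")
}

# ---- parameter initialization --------------------------------------------

.he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         fan_in, fan_out)
}

cn_init_params <- function(config) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)
  c8 <- config$in_channels; h1 <- config$tnet1_hidden
  m1 <- config$mlp1; h2 <- config$tnet2_hidden; m2 <- config$mlp2
  hd <- config$head
  list(
    # input T-net: shared fc -> max-pool -> fc predicting the 8x8 matrix;
    # output layer zero-initialized with identity bias (identity at init)
    t1A = .he_init(c8, h1), t1a = rep(0, h1),
    t1W = matrix(0, h1, c8 * c8), t1b = as.vector(diag(c8)),
    m1W1 = .he_init(c8, m1[1]), m1b1 = rep(0, m1[1]),
    m1W2 = .he_init(m1[1], m1[2]), m1b2 = rep(0, m1[2]),
    t2A = .he_init(m1[2], h2), t2a = rep(0, h2),
    t2W = matrix(0, h2, m1[2]^2), t2b = as.vector(diag(m1[2])),
    m2W1 = .he_init(m1[2], m2[1]), m2b1 = rep(0, m2[1]),
    m2W2 = .he_init(m2[1], m2[2]), m2b2 = rep(0, m2[2]),
    m2W3 = .he_init(m2[2], m2[3]), m2b3 = rep(0, m2[3]),
    hW1 = .he_init(m2[3], hd[1]), hb1 = rep(0, hd[1]),
    hW2 = .he_init(hd[1], hd[2]), hb2 = rep(0, hd[2]),
    hW3 = .he_init(hd[2], 2L), hb3 = rep(0, 2L)
  )
}

# ---- primitive ops --------------------------------------------------------

.affb <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

# channel-wise max over each subject's block of N rows;
# returns pooled S x C matrix and the global row index of each max
.pool_max <- function(Z, S, N) {
  C <- ncol(Z)
  P <- matrix(0, S, C)
  idx <- matrix(0L, S, C)
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * N + 1L):(s * N)
    block <- Z[rows, , drop = FALSE]
    j <- max.col(t(block), ties.method = "first")   # argmax per column
    idx[s, ] <- rows[j]
    P[s, ] <- block[cbind(j, seq_len(C))]
  }
  list(P = P, idx = idx)
}

.scatter_pool <- function(dP, idx, n_rows) {
  C <- ncol(dP)
  out <- matrix(0, n_rows, C)
  out[cbind(as.vector(idx), rep(seq_len(C), each = nrow(dP)))] <-
    as.vector(dP)
  out
}

# per-subject right-multiplication by a predicted square matrix
.apply_transform <- function(Z, Tmats, S, N) {
  out <- Z
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * N + 1L):(s * N)
    out[rows, ] <- Z[rows, , drop = FALSE] %*% Tmats[[s]]
  }
  out
}

# ---- forward --------------------------------------------------------------

# X: (S*N) x 8 stacked subject-major, already channel-standardized
cn_forward <- function(params, X, S, N, with_head = TRUE, cache = FALSE) {
  c8 <- ncol(X)
  H1 <- pmax(.affb(X, params$t1A, params$t1a), 0)
  p1 <- .pool_max(H1, S, N)
  M1 <- .affb(p1$P, params$t1W, params$t1b)
  T1 <- lapply(seq_len(S), function(s) matrix(M1[s, ], c8, c8))
  X2 <- .apply_transform(X, T1, S, N)

  Z1 <- pmax(.affb(X2, params$m1W1, params$m1b1), 0)
  Z2 <- pmax(.affb(Z1, params$m1W2, params$m1b2), 0)

  H2 <- pmax(.affb(Z2, params$t2A, params$t2a), 0)
  p2 <- .pool_max(H2, S, N)
  M2 <- .affb(p2$P, params$t2W, params$t2b)
  d2 <- ncol(Z2)
  T2 <- lapply(seq_len(S), function(s) matrix(M2[s, ], d2, d2))
  Z3 <- .apply_transform(Z2, T2, S, N)

  Z4 <- pmax(.affb(Z3, params$m2W1, params$m2b1), 0)
  Z5 <- pmax(.affb(Z4, params$m2W2, params$m2b2), 0)
  Z6 <- pmax(.affb(Z5, params$m2W3, params$m2b3), 0)
  pg <- .pool_max(Z6, S, N)
  G <- pg$P

  out <- list(G = G)
  if (with_head) {
    Hh1 <- pmax(.affb(G, params$hW1, params$hb1), 0)
    Hh2 <- pmax(.affb(Hh1, params$hW2, params$hb2), 0)
    out$logits <- .affb(Hh2, params$hW3, params$hb3)
  }
  if (cache) {
    out$cache <- list(X = X, G = G, H1 = H1, p1 = p1, T1 = T1, X2 = X2,
                      Z1 = Z1, Z2 = Z2, H2 = H2, p2 = p2, T2 = T2,
                      Z3 = Z3, Z4 = Z4, Z5 = Z5, Z6 = Z6, pg = pg,
                      Hh1 = if (with_head) Hh1 else NULL,
                      Hh2 = if (with_head) Hh2 else NULL)
  }
  out
}

# ---- loss + gradients -----------------------------------------------------

cn_loss_grad <- function(params, X, y, S, N, reg_weight) {
  fw <- cn_forward(params, X, S, N, with_head = TRUE, cache = TRUE)
  ch <- fw$cache
  logits <- fw$logits
  lmax <- apply(logits, 1, max)
  ex <- exp(logits - lmax)
  probs <- ex / rowSums(ex)
  Y <- cbind(1 - y, y)
  ce <- -mean(log(pmax(probs[cbind(seq_len(S), y + 1L)], 1e-12)))

  d2 <- ncol(ch$Z2)
  I2 <- diag(d2)
  reg <- 0
  dT2reg <- vector("list", S)
  for (s in seq_len(S)) {
    R <- I2 - ch$T2[[s]] %*% t(ch$T2[[s]])
    reg <- reg + sum(R^2)
    dT2reg[[s]] <- -4 * (R %*% ch$T2[[s]])
  }
  loss <- ce + reg_weight * reg / S

  g <- list()
  dlog <- (probs - Y) / S
  g$hW3 <- t(ch$Hh2) %*% dlog; g$hb3 <- colSums(dlog)
  dH2h <- (dlog %*% t(params$hW3)) * (ch$Hh2 > 0)
  g$hW2 <- t(ch$Hh1) %*% dH2h; g$hb2 <- colSums(dH2h)
  dH1h <- (dH2h %*% t(params$hW2)) * (ch$Hh1 > 0)
  g$hW1 <- t(ch$G) %*% dH1h; g$hb1 <- colSums(dH1h)
  dG <- dH1h %*% t(params$hW1)

  nrows <- nrow(X)
  dZ6 <- .scatter_pool(dG, ch$pg$idx, nrows) * (ch$Z6 > 0)
  g$m2W3 <- t(ch$Z5) %*% dZ6; g$m2b3 <- colSums(dZ6)
  dZ5 <- (dZ6 %*% t(params$m2W3)) * (ch$Z5 > 0)
  g$m2W2 <- t(ch$Z4) %*% dZ5; g$m2b2 <- colSums(dZ5)
  dZ4 <- (dZ5 %*% t(params$m2W2)) * (ch$Z4 > 0)
  g$m2W1 <- t(ch$Z3) %*% dZ4; g$m2b1 <- colSums(dZ4)
  dZ3 <- dZ4 %*% t(params$m2W1)

  # through the feature transform: direct path + predicted-matrix path
  dZ2 <- matrix(0, nrows, d2)
  dM2 <- matrix(0, S, d2 * d2)
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * N + 1L):(s * N)
    Ts <- ch$T2[[s]]
    dZ3s <- dZ3[rows, , drop = FALSE]
    dZ2[rows, ] <- dZ3s %*% t(Ts)
    dTs <- t(ch$Z2[rows, , drop = FALSE]) %*% dZ3s +
      (reg_weight / S) * dT2reg[[s]]
    dM2[s, ] <- as.vector(dTs)
  }
  g$t2W <- t(ch$p2$P) %*% dM2; g$t2b <- colSums(dM2)
  dP2 <- dM2 %*% t(params$t2W)
  dH2 <- .scatter_pool(dP2, ch$p2$idx, nrows) * (ch$H2 > 0)
  g$t2A <- t(ch$Z2) %*% dH2; g$t2a <- colSums(dH2)
  dZ2 <- dZ2 + dH2 %*% t(params$t2A)

  dZ2 <- dZ2 * (ch$Z2 > 0)
  g$m1W2 <- t(ch$Z1) %*% dZ2; g$m1b2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(params$m1W2)) * (ch$Z1 > 0)
  g$m1W1 <- t(ch$X2) %*% dZ1; g$m1b1 <- colSums(dZ1)
  dX2 <- dZ1 %*% t(params$m1W1)

  c8 <- ncol(X)
  dM1 <- matrix(0, S, c8 * c8)
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * N + 1L):(s * N)
    dM1[s, ] <- as.vector(t(X[rows, , drop = FALSE]) %*%
                            dX2[rows, , drop = FALSE])
  }
  g$t1W <- t(ch$p1$P) %*% dM1; g$t1b <- colSums(dM1)
  dP1 <- dM1 %*% t(params$t1W)
  dH1 <- .scatter_pool(dP1, ch$p1$idx, nrows) * (ch$H1 > 0)
  g$t1A <- t(ch$X) %*% dH1; g$t1a <- colSums(dH1)

  list(loss = loss, ce = ce, grads = g)
}

# ---- training -------------------------------------------------------------

.stack_regions <- function(regions) {
  mats <- lapply(regions, function(r) {
    m <- if (inherits(r, "region_points")) r$points else r
    if (ncol(m) != 8L)
      stop("contract error: region point matrix must have 8 channels")
    m
  })
  N <- unique(vapply(mats, nrow, 1L))
  if (length(N) != 1L)
    stop("contract error: all subjects must have the same region sample size")
  list(X = do.call(rbind, mats), S = length(mats), N = N)
}

#' Train the point-set feature extractor
#'
#' Trains the network of [cloudnet_config()] with a two-class softmax head
#' on rupture labels (cross-entropy, Adam, mini-batches over subjects),
#' with an orthogonality penalty on the feature transform. Input channels
#' are z-standardized with statistics of the training subjects; the
#' statistics are stored in the returned weights and re-applied at
#' extraction time.
#'
#' @param regions List of `region_points` (or N x 8 matrices), one per
#'   subject, all with the same N.
#' @param labels 0/1 vector (1 = ruptured), both classes present.
#' @param config A [cloudnet_config()].
#' @return An object of class `cloudnet`: list with `params`,
#'   `channel_center`, `channel_scale`, `config` and `loss_history`
#'   (per-epoch mean training loss).
#' @export
train_extractor <- function(regions, labels, config = cloudnet_config()) {
  st <- .stack_regions(regions)
  y <- as.integer(labels)
  if (length(y) != st$S)
    stop("contract error: one label per subject required")
  if (length(unique(y)) < 2L)
    stop("contract error: training labels contain a single class")

  ctr <- colMeans(st$X)
  scl <- apply(st$X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xall <- sweep(sweep(st$X, 2, ctr), 2, scl, "/")

  params <- cn_init_params(config)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(config$epochs)

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed + 7919L)

  N <- st$N
  for (ep in seq_len(config$epochs)) {
    ord <- sample(st$S)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      rows <- as.vector(vapply(bt, function(s)
        ((s - 1L) * N + 1L):(s * N), integer(N)))
      lg <- cn_loss_grad(params, Xall[rows, , drop = FALSE], y[bt],
                         length(bt), N, config$reg_weight)
      ep_loss <- ep_loss + lg$loss * length(bt)
      step <- step + 1L
      for (nm in names(lg$grads)) {
        gr <- lg$grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_hist[ep] <- ep_loss / st$S
  }

  structure(list(params = params, channel_center = ctr,
                 channel_scale = scl, config = config,
                 loss_history = loss_hist),
            class = "cloudnet")
}

#' @export
print.cloudnet <- function(x, ...) {
  cat(sprintf("cloudnet: %d epochs trained, final loss %.4f\n",
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Hemodynamic cloud feature of one subject
#'
#' Runs the shared per-point transforms and the channel-wise max-pool,
#' returning the 1,024-dimensional feature. The output is invariant to
#' any permutation or duplication of the input rows.
#'
#' @param points A `region_points` object or an N x 8 matrix.
#' @param weights A trained [train_extractor()] object (an untrained
#'   `cloudnet` built from [cn_init_weights()] also works).
#' @return Named numeric vector of length 1,024 (`cf_0001` ...).
#' @export
forward_features <- function(points, weights) {
  m <- if (inherits(points, "region_points")) points$points else points
  if (!is.matrix(m) || ncol(m) != 8L)
    stop("contract error: points must be an N x 8 matrix")
  X <- sweep(sweep(m, 2, weights$channel_center), 2,
             weights$channel_scale, "/")
  fw <- cn_forward(weights$params, X, 1L, nrow(X), with_head = FALSE)
  v <- as.numeric(fw$G[1, ])
  names(v) <- sprintf("cf_%04d", seq_along(v))
  v
}

#' Untrained (identity-transform) weights, e.g. for property checks
#'
#' @param config A [cloudnet_config()].
#' @return A `cloudnet` with freshly initialized parameters and pass-through
#'   channel standardization.
#' @export
cn_init_weights <- function(config = cloudnet_config()) {
  structure(list(params = cn_init_params(config),
                 channel_center = rep(0, 8), channel_scale = rep(1, 8),
                 config = config, loss_history = numeric(0)),
            class = "cloudnet")
}

#' Cloud-feature table for a set of subjects
#'
#' @param regions List of `region_points` (or N x 8 matrices).
#' @param weights A trained `cloudnet`.
#' @return Matrix with one 1,024-column row per subject; row names are
#'   subject ids where available.
#' @export
extract_features <- function(regions, weights) {
  rows <- lapply(regions, forward_features, weights = weights)
  out <- do.call(rbind, rows)
  ids <- vapply(regions, function(r)
    if (inherits(r, "region_points")) r$subject_id else NA_character_, "")
  if (!anyNA(ids)) rownames(out) <- ids
  out
}

#' Save / load extractor weights as a single versioned JSON checkpoint
#'
#' @param weights A `cloudnet`.
#' @param path Checkpoint file path.
#' @return The path (writer, invisibly) or a `cloudnet` (reader).
#' @export
write_cloudnet <- function(weights, path) {
  obj <- list(format = "aneucloud-cloudnet", version = 1L,
              config = unclass(weights$config),
              channel_center = weights$channel_center,
              channel_scale = weights$channel_scale,
              loss_history = weights$loss_history,
              params = lapply(weights$params, function(p)
                list(dim = if (is.matrix(p)) dim(p) else length(p),
                     data = as.vector(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cloudnet
#' @export
read_cloudnet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "aneucloud-cloudnet"))
    stop("contract error: not an aneucloud checkpoint")
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  cfg <- do.call(cloudnet_config, obj$config[c(
    "in_channels", "tnet1_hidden", "mlp1", "tnet2_hidden", "mlp2", "head",
    "epochs", "batch_size", "lr", "reg_weight", "seed")])
  structure(list(params = params,
                 channel_center = as.numeric(obj$channel_center),
                 channel_scale = as.numeric(obj$channel_scale),
                 config = cfg,
                 loss_history = as.numeric(obj$loss_history)),
            class = "cloudnet")
}

#' Head predictions of the trained extractor
#'
#' @param weights A trained `cloudnet`.
#' @param regions List of `region_points` (or N x 8 matrices).
#' @return Vector of predicted rupture probabilities.
#' @export
cn_predict <- function(weights, regions) {
  st <- .stack_regions(regions)
  X <- sweep(sweep(st$X, 2, weights$channel_center), 2,
             weights$channel_scale, "/")
  fw <- cn_forward(weights$params, X, st$S, st$N, with_head = TRUE)
  lmax <- apply(fw$logits, 1, max)
  ex <- exp(fw$logits - lmax)
  (ex / rowSums(ex))[, 2]
}
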