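# shared fixtures and independent oracles, all built in code

tiny_geometry <- function(radius = 3, neck = 5, parent = 4,
                          n_points = 200, seed = 1, ...) {
  make_sac_geometry(radius, neck, parent, n_points = n_points,
                    seed = seed, n_neck = 32, ...)
}

tiny_cloud <- function(label = "ruptured", mode = "spatial", seed = 1,
                       n_points = 200, noise_sd = 0.08,
                       waveform = flow_waveform(), ...) {
  g <- tiny_geometry(n_points = n_points, seed = seed)
  simulate_hemo_fields(g, waveform, label = label, signal_mode = mode,
                       noise_sd = noise_sd, seed = seed + 1000,
                       subject_id = sprintf("T%03d", seed), ...)
}

# hand-assembled minimal cloud whose channels are set directly, for
# threshold-rule tests
fake_cloud <- function(wss_sys, velocity = NULL, tawss = NULL,
                       osi = NULL, areas = NULL) {
  n <- length(wss_sys)
  if (is.null(velocity)) velocity <- rep(1, n)
  if (is.null(tawss)) tawss <- wss_sys
  if (is.null(osi)) osi <- rep(0.1, n)
  if (is.null(areas)) areas <- rep(1, n)
  pts <- cbind(seq_len(n), 0, seq_len(n))   # distinct coordinates
  structure(list(
    geometry = structure(list(surface_points = pts, point_areas = areas,
                              point_normals = cbind(0, 0, rep(1, n)),
                              neck_ring = 1:2, dome_tip = n,
                              parent_diameter = 4, radius = 3,
                              neck_width = 4, neck_z = -1,
                              shape_flag = "smooth",
                              location_flag = "sidewall"),
                         class = "sac_geometry"),
    wss_sys = wss_sys, velocity = velocity, tawss = tawss, osi = osi,
    pressure = rep(100, n), label = "ruptured", subject_id = "FAKE"),
    class = "hemo_cloud")
}

# piecewise-constant WSS series: one row per segment, times in frames
series_from_segments <- function(vectors, n_frames_each) {
  nt <- sum(n_frames_each)
  s <- array(0, dim = c(1, nt, 3))
  at <- 1
  for (i in seq_along(n_frames_each)) {
    idx <- at:(at + n_frames_each[i] - 1)
    s[1, idx, 1] <- vectors[[i]][1]
    s[1, idx, 2] <- vectors[[i]][2]
    s[1, idx, 3] <- vectors[[i]][3]
    at <- at + n_frames_each[i]
  }
  s
}

# oracle: exact two-sided Wilcoxon signed-rank p by full enumeration of
# the 2^n sign assignments (no zeros, assumes untied |d| unless midranks)
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean_v <- n * (n + 1) / 4
  # two-sided: as extreme in either direction
  p <- mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-9)
  p
}

# oracle: AUC by brute-force pair counting with half-credit ties
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# spherical-cap closed forms (independent of package internals)
cap_height <- function(r, w) r + sqrt(r^2 - (w / 2)^2)
cap_area <- function(r, w) 2 * pi * r * cap_height(r, w)
cap_volume <- function(r, w) {
  h <- cap_height(r, w)
  pi * h^2 / 3 * (3 * r - h)
}
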