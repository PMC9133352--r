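wf <- flow_waveform()

test_that("TAWSS and OSI reproduce closed-form cases", {
  s <- series_from_segments(list(c(1, 0, 0)), 80)
  expect_equal(compute_tawss(s, wf), 1)
  expect_equal(compute_osi(s, wf), 0)
  # half-cycle reversal: magnitude constant, direction fully reversed
  s2 <- series_from_segments(list(c(1, 0, 0), c(-1, 0, 0)), c(40, 40))
  expect_equal(compute_tawss(s2, wf), 1)
  expect_equal(compute_osi(s2, wf), 0.5)
  # orthogonal half-cycles
  s3 <- series_from_segments(list(c(1, 0, 0), c(0, 1, 0)), c(40, 40))
  expect_equal(compute_osi(s3, wf), 0.5 * (1 - sqrt(2) / 2),
               tolerance = 1e-12)
  # piecewise magnitudes 1 then 2 over 0.4 s each
  s4 <- series_from_segments(list(c(1, 0, 0), c(0, 2, 0)), c(40, 40))
  expect_equal(compute_tawss(s4, wf), 1.5, tolerance = 1e-12)
})

test_that("cycle integrals agree with a fine quadrature oracle on smooth series", {
  f <- list(x = function(t) 2 + sin(2 * pi * t / 0.8),
            y = function(t) cos(2 * pi * t / 0.8),
            z = function(t) 0.3 * sin(4 * pi * t / 0.8))
  tt <- wf$times
  s <- array(0, c(1, 80, 3))
  s[1, , 1] <- f$x(tt); s[1, , 2] <- f$y(tt); s[1, , 3] <- f$z(tt)
  mag <- function(t) sqrt(f$x(t)^2 + f$y(t)^2 + f$z(t)^2)
  oracle_tawss <- stats::integrate(mag, 0, 0.8,
                                   subdivisions = 2000L,
                                   rel.tol = 1e-10)$value / 0.8
  expect_equal(compute_tawss(s, wf), oracle_tawss, tolerance = 1e-3)
  mean_vec <- vapply(f, function(fc)
    stats::integrate(fc, 0, 0.8, subdivisions = 2000L,
                     rel.tol = 1e-10)$value / 0.8, numeric(1))
  oracle_osi <- 0.5 * (1 - sqrt(sum(mean_vec^2)) / oracle_tawss)
  expect_equal(compute_osi(s, wf), oracle_osi, tolerance = 1e-3)
})

test_that("degenerate series are handled by contract", {
  expect_equal(compute_osi(series_from_segments(list(c(0, 0, 0)), 80), wf), 0)
  one_step <- array(1, c(1, 1, 3))
  expect_error(compute_tawss(one_step, wf), "single timestep")
  wrong <- array(1, c(1, 40, 3))
  expect_error(compute_tawss(wrong, wf), "does not match")
})

test_that("LSA and HOA are area-weighted threshold fractions", {
  cl <- fake_cloud(wss_sys = c(1, 1, 1, 1), tawss = c(1, 1, 1, 1))
  expect_equal(compute_lsa(cl, parent_mean_wss = 5), 0)   # thr 0.5 < 1
  cl$tawss <- rep(0.01, 4)
  expect_equal(compute_lsa(cl, parent_mean_wss = 5), 1)
  # half the total area below threshold by construction (areas 1 and 3)
  cl2 <- fake_cloud(wss_sys = rep(1, 4), tawss = c(0.1, 0.1, 2, 2),
                    areas = c(1, 1, 1, 1))
  expect_equal(compute_lsa(cl2, parent_mean_wss = 5), 0.5)
  cl3 <- fake_cloud(wss_sys = rep(1, 2), osi = c(0.4, 0.1),
                    areas = c(1, 3))
  expect_equal(compute_hoa(cl3, osi_threshold = 0.2), 0.25)
  expect_equal(compute_hoa(cl3, osi_threshold = 0.45), 0)
  expect_equal(compute_hoa(cl3, osi_threshold = 0.05), 1)
  expect_error(compute_lsa(cl3, parent_mean_wss = 0), "positive")
})

test_that("energy loss follows the energy-flux balance", {
  st <- function(p, u, q) list(pressure = p, velocity = u, flow = q)
  expect_equal(compute_energy_loss(st(200, 0.5, 5e-6),
                                   st(200, 0.5, 5e-6)), 0)
  expect_equal(compute_energy_loss(st(200, 0.5, 5e-6),
                                   st(100, 0.5, 5e-6)), 5e-4)
  # two outlets splitting the flow equally with equal states
  two <- compute_energy_loss(st(200, 0.5, 5e-6),
                             list(st(100, 0.5, 2.5e-6),
                                  st(100, 0.5, 2.5e-6)))
  expect_equal(two, 5e-4)
  expect_error(compute_energy_loss(st(200, 0.5, 5e-6),
                                   st(100, 0.5, 4e-6)),
               "do not balance")
})

test_that("the summary vector has exactly 18 ordered parameters", {
  cl <- tiny_cloud(seed = 4)
  hv <- summarize_hemodynamics(cl)
  expect_length(hv, 18)
  expect_identical(names(hv), base_feature_names()[11:28])
  for (q in c("wss", "tawss", "osi", "pressure", "velocity")) {
    expect_lte(hv[[paste0(q, "_min")]], hv[[paste0(q, "_avg")]])
    expect_lte(hv[[paste0(q, "_avg")]], hv[[paste0(q, "_max")]])
  }
  expect_true(hv[["hoa"]] >= 0 && hv[["hoa"]] <= 1)
  expect_true(hv[["lsa"]] >= 0 && hv[["lsa"]] <= 1)
  expect_lte(hv[["osi_max"]], 0.5)
})

test_that("summaries respect uniform fields, planted extremes and area weights", {
  base <- fake_cloud(wss_sys = rep(2, 4), tawss = rep(2, 4),
                     osi = rep(0.1, 4))
  base$parent_mean_wss <- 3
  base$inlet_state <- list(pressure = 200, velocity = 0.5, flow = 5e-6)
  base$outlet_states <- list(list(pressure = 150, velocity = 0.5,
                                  flow = 5e-6))
  hv <- summarize_hemodynamics(base)
  expect_equal(hv[["wss_max"]], hv[["wss_avg"]])
  expect_equal(hv[["wss_avg"]], hv[["wss_min"]])
  hot <- base
  hot$wss_sys <- c(2, 2, 2, 9)
  hh <- summarize_hemodynamics(hot)
  expect_equal(hh[["wss_max"]], 9)
  expect_equal(hh[["wss_min"]], hv[["wss_min"]])
  # area-weighted mean: areas 1:3 with values 4, 0 -> 1.0
  two <- base
  two$wss_sys <- c(4, 0, 0, 0)
  two$geometry$point_areas <- c(1, 1, 1, 1)
  two$wss_sys <- c(4, 4, 0, 0); two$geometry$point_areas <- c(0.5, 0.5, 3, 0)
  tv <- summarize_hemodynamics(two)
  expect_equal(tv[["wss_avg"]], 1.0)
})

test_that("summaries are invariant to point reordering", {
  cl <- tiny_cloud(seed = 8, n_points = 150)
  hv <- summarize_hemodynamics(cl)
  set.seed(1)
  perm <- sample(length(cl$wss_sys))
  cl2 <- cl
  cl2$geometry$surface_points <- cl$geometry$surface_points[perm, ]
  cl2$geometry$point_areas <- cl$geometry$point_areas[perm]
  cl2$wss_sys <- cl$wss_sys[perm]; cl2$tawss <- cl$tawss[perm]
  cl2$osi <- cl$osi[perm]; cl2$pressure <- cl$pressure[perm]
  cl2$velocity <- cl$velocity[perm]
  expect_equal(summarize_hemodynamics(cl2), hv, tolerance = 1e-12)
})

test_that("derived channels obey their bounds across generated clouds", {
  for (sd in 1:5) {
    cl <- tiny_cloud(seed = sd, n_points = 120,
                     mode = c("both", "none")[1 + sd %% 2])
    expect_true(all(cl$osi >= 0 & cl$osi <= 0.5))
    expect_true(all(cl$tawss >= 0))
    expect_true(all(cl$wss_sys >= 0))
    # TAWSS never exceeds the peak instantaneous magnitude
    mags <- sqrt(cl$wss_series[, , 1]^2 + cl$wss_series[, , 2]^2 +
                   cl$wss_series[, , 3]^2)
    expect_true(all(cl$tawss <= apply(mags, 1, max) + 1e-12))
  }
})
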