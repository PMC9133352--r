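test_that("field simulation is deterministic given seed and inputs", {
  g <- tiny_geometry(n_points = 120)
  wf <- flow_waveform()
  c1 <- simulate_hemo_fields(g, wf, "ruptured", "both", seed = 5)
  c2 <- simulate_hemo_fields(g, wf, "ruptured", "both", seed = 5)
  expect_identical(c1$wss_series, c2$wss_series)
  expect_identical(c1$pressure, c2$pressure)
  c3 <- simulate_hemo_fields(g, wf, "ruptured", "both", seed = 6)
  expect_false(identical(c1$wss_series, c3$wss_series))
})

test_that("a flat waveform with zero noise gives exactly zero OSI", {
  g <- tiny_geometry(n_points = 100)
  cl <- simulate_hemo_fields(g, flat_waveform(), "ruptured", "spatial",
                             noise_sd = 0, seed = 2)
  expect_equal(max(cl$osi), 0)
})

test_that("classes are exchangeable in 'none' mode", {
  coh <- generate_cohort(60, 0.5, "none", seed = 13, n_points = 150)
  wss_avg <- vapply(coh, function(cl)
    sum(cl$geometry$point_areas * cl$wss_sys) /
      sum(cl$geometry$point_areas), numeric(1))
  lab <- cohort_labels(coh)
  p <- stats::t.test(wss_avg[lab == 1], wss_avg[lab == 0])$p.value
  expect_gt(p, 0.01)
})

test_that("'summary' mode shifts scalar descriptor means", {
  coh <- generate_cohort(60, 0.5, "summary", seed = 3, n_points = 150)
  hem <- cohort_hemodynamics(coh)
  expect_gt(mean(hem$wss_avg[hem$label == "ruptured"]),
            mean(hem$wss_avg[hem$label == "unruptured"]))
  expect_gt(mean(hem$velocity_avg[hem$label == "ruptured"]),
            mean(hem$velocity_avg[hem$label == "unruptured"]))
})

test_that("'spatial' mode matches class means of the mean-level descriptors", {
  noise_sd <- 0.08
  coh <- generate_cohort(100, 0.5, "spatial", seed = 7, n_points = 300)
  hem <- cohort_hemodynamics(coh)
  lab <- hem$label
  for (cn in c("wss_avg", "osi_avg")) {
    d <- abs(mean(hem[[cn]][lab == "ruptured"]) -
               mean(hem[[cn]][lab == "unruptured"]))
    expect_lt(d, 0.5 * noise_sd)
  }
})

test_that("cohort composition follows the rupture fraction", {
  coh <- generate_cohort(148, 39 / 148, "none", seed = 1, n_points = 60,
                         n_neck = 24)
  lab <- vapply(coh, `[[`, "", "label")
  expect_equal(sum(lab == "ruptured"), 39)
  expect_equal(sum(lab == "unruptured"), 109)
  coh2 <- generate_cohort(60, 0.5, "none", seed = 1, n_points = 60,
                          n_neck = 24)
  expect_equal(sum(cohort_labels(coh2)), 30)
  expect_warning(generate_cohort(10, 0.5, "none", seed = 1,
                                 n_points = 60, n_neck = 24),
                 "fewer than 20")
  expect_error(generate_cohort(40, 0, "none"), "invalid-parameter")
})

test_that("identical seeds give byte-identical serialized cohorts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- suppressWarnings(generate_cohort(3, 1 / 3, "both", seed = 9,
                                         n_points = 80, n_neck = 24))
  c2 <- suppressWarnings(generate_cohort(3, 1 / 3, "both", seed = 9,
                                         n_points = 80, n_neck = 24))
  write_cohort_manifest(c1, d1)
  write_cohort_manifest(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(make_sac_geometry(3, 4, 4, n_points = 100, seed = 1))
  invisible(tiny_cloud(seed = 2, n_points = 80))
  expect_identical(.Random.seed, before)
})
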