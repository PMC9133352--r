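#' Full-run configuration
#'
#' Bundles every knob of the end-to-end pipeline: cohort generation,
#' region thresholds, network schedule, feature-pipeline counts and CV
#' settings. The whole object is serializable to JSON and a snapshot is
#' embedded in every run's output directory.
#'
#' @param seed Master seed for the run.
#' @param n_subjects,rupture_fraction,signal_mode,n_points,noise_sd
#'   Cohort parameters, see [generate_cohort()].
#' @param region_n,wss_frac,vel_frac,jet_radius_frac Region sampling
#'   parameters, see [extract_regions()].
#' @param net A [cloudnet_config()].
#' @param prep A [featureprep_config()].
#' @param n_repeats,k CV settings.
#' @param extractor `"fold"` (leakage-controlled, default) or `"single"`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 60L,
                       rupture_fraction = 39 / 148,
                       signal_mode = "spatial", n_points = 500L,
                       noise_sd = 0.08,
                       region_n = 128L, wss_frac = 0.8, vel_frac = 0.8,
                       jet_radius_frac = 0.1,
                       net = cloudnet_config(epochs = 10L,
                                             batch_size = 18L, lr = 2e-3),
                       prep = featureprep_config(),
                       n_repeats = 5L, k = 10L,
                       extractor = "fold") {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 rupture_fraction = rupture_fraction,
                 signal_mode = signal_mode, n_points = as.integer(n_points),
                 noise_sd = noise_sd, region_n = as.integer(region_n),
                 wss_frac = wss_frac, vel_frac = vel_frac,
                 jet_radius_frac = jet_radius_frac, net = net, prep = prep,
                 n_repeats = as.integer(n_repeats), k = as.integer(k),
                 extractor = extractor),
            class = "run_config")
}

#' Small demonstration preset
#'
#' A desk-scale configuration: spatial-signal cohort, compact network and
#' short schedule, meant to finish in minutes on one CPU while still
#' emitting the full 10-row report.
#'
#' @param seed Master seed.
#' @param n_subjects,n_repeats,k,region_n Size knobs (small defaults).
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L, n_subjects = 24L, n_repeats = 2L,
                        k = 4L, region_n = 64L) {
  run_config(seed = seed, n_subjects = n_subjects,
             rupture_fraction = 1 / 3, n_points = 300L,
             region_n = region_n,
             net = cloudnet_config(epochs = 3L, batch_size = 12L,
                                   lr = 3e-3),
             prep = featureprep_config(rfe_keep = 32L,
                                       kpca_components = 8L),
             n_repeats = n_repeats, k = k)
}

#' Run the whole pipeline and write a report bundle
#'
#' Chains generate -> morphology/hemodynamics -> regions -> (per-fold
#' extractor + feature assembly) -> repeated-CV evaluation, and writes
#' plain-file artifacts to `out_dir`: `morpho.csv`, `hemo.csv`,
#' `metrics.csv` (one row per algorithm x feature group),
#' `pairwise_tests.csv`, `config.json` and `run.log`. Artifacts present
#' from a previous run with the same config snapshot are reused unless
#' `overwrite = TRUE`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param overwrite Recompute even when matching artifacts exist.
#' @return The [run_experiment()] result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  snapshot <- jsonlite::toJSON(.strip_classes(config),
                               auto_unbox = TRUE, digits = NA)
  stale <- !(file.exists(cfg_path) &&
               identical(as.character(snapshot),
                         paste(readLines(cfg_path), collapse = "")))
  if (stale || overwrite) writeLines(as.character(snapshot), cfg_path)

  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat(sprintf("run started %s\n", format(Sys.time())), file = logf)
  logline("seed=%d n_subjects=%d signal_mode=%s n_points=%d noise_sd=%g",
          config$seed, config$n_subjects, config$signal_mode,
          config$n_points, config$noise_sd)
  logline("region_n=%d wss_frac=%g vel_frac=%g jet_radius_frac=%g",
          config$region_n, config$wss_frac, config$vel_frac,
          config$jet_radius_frac)
  logline("net: epochs=%d batch=%d lr=%g reg=%g",
          config$net$epochs, config$net$batch_size, config$net$lr,
          config$net$reg_weight)
  logline("prep: rfe_keep=%d rfe_step=%g kpca=%d (%s)",
          config$prep$rfe_keep, config$prep$rfe_step,
          config$prep$kpca_components, config$prep$kpca_kernel)
  logline("cv: n_repeats=%d k=%d extractor=%s",
          config$n_repeats, config$k, config$extractor)

  cohort <- generate_cohort(config$n_subjects, config$rupture_fraction,
                            config$signal_mode, seed = config$seed,
                            n_points = config$n_points,
                            noise_sd = config$noise_sd)
  morpho_path <- file.path(out_dir, "morpho.csv")
  hemo_path <- file.path(out_dir, "hemo.csv")
  reuse <- !stale && !overwrite && file.exists(morpho_path) &&
    file.exists(hemo_path)
  morpho <- if (reuse) utils::read.csv(morpho_path) else
    cohort_morphology(cohort)
  hemo <- if (reuse) utils::read.csv(hemo_path) else
    cohort_hemodynamics(cohort)
  if (!reuse) {
    utils::write.csv(morpho, morpho_path, row.names = FALSE)
    utils::write.csv(hemo, hemo_path, row.names = FALSE)
  }
  logline("descriptors computed for %d subjects", nrow(morpho))

  regions <- cohort_regions(cohort, n = config$region_n,
                            seed = config$seed, frac = config$wss_frac,
                            jet_radius_frac = config$jet_radius_frac,
                            vel_frac = config$vel_frac)
  dataset <- cv_dataset(morpho, hemo, regions, prep = config$prep,
                        net = config$net)
  exp <- run_experiment(dataset, default_models(seed = config$seed),
                        n_repeats = config$n_repeats, k = config$k,
                        seed = config$seed, extractor = config$extractor)
  .write_metrics_csv(exp$metrics, file.path(out_dir, "metrics.csv"))
  utils::write.csv(exp$tests, file.path(out_dir, "pairwise_tests.csv"),
                   row.names = FALSE)
  logline("report written: %d metric rows", nrow(exp$metrics))
  invisible(exp)
}

.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

# fixed-precision writer so identical runs are byte-identical
.write_metrics_csv <- function(metrics, path) {
  num <- vapply(metrics, is.numeric, TRUE)
  out <- metrics
  out[num] <- lapply(metrics[num], function(x) sprintf("%.10f", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Run the demonstration experiment
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides passed to [demo_config()].
#' @return The experiment object, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, ...) {
  run_pipeline(demo_config(seed = seed, ...), out_dir)
}
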