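## End-to-end orchestration: a single serializable run configuration, the
## cohort writer/reader, and the full simulate -> preprocess -> pretrain ->
## sweep -> stats pipeline.

#' Default run configuration
#'
#' Every tunable of the pipeline in one nested, serializable document:
#' paradigm timing, simulator population and seeds, optical constants,
#' preprocessing (cutoff, windowing, class mode, decimation), network
#' choice, training protocol (budgets, split, freezing, group sizes) and
#' the statistical stage. A run is a pure function of (config, master
#' seed).
#'
#' @param master_seed Master seed recorded in the config.
#' @return A `run_config` list.
#' @export
default_run_config <- function(master_seed = 1L) {
  structure(list(
    paradigm = list(sessions = 3, series_per_session = 3,
                    sampling_rate = 10, instruction_s = 2, task_s = 40,
                    rest_s = 20, trials_per_series = 20),
    simulator = list(n_subjects = 26, n_channels = 36,
                     population = default_population(),
                     master_seed = as.integer(master_seed)),
    mbll = unclass(default_mbll_config()),
    preprocess = list(cutoff_hz = 0.2, filter_order = 4,
                      window_s = 10, step_s = 5,
                      class_mode = "3class", decimate = 10),
    model = list(network = "reduced"),
    training = list(budgets = seq(10, 60, by = 10),
                    pretrain_epochs = 20, lr = 1e-3, batch_size = 32,
                    n_source = 16, n_control = 5, n_baseline = 5,
                    assignment = "disjoint",
                    freeze_plan = "last-two-dense",
                    split = list(kind = "holdout_70_30", k = 10,
                                 unit = "series")),
    stats = list(alpha = 0.05, test_budget = 60)
  ), class = "run_config")
}

#' Write / read a run configuration (JSON or YAML)
#'
#' @param config A `run_config`.
#' @param path Destination path; the extension picks the format
#'   (`.json` or `.yaml`/`.yml`).
#' @export
write_run_config <- function(config, path) {
  doc <- rapply(unclass(config), f = function(x) x, how = "replace")
  doc$mbll$extinction <- list(
    values = as.vector(config$mbll$extinction),
    dim = dim(config$mbll$extinction),
    dimnames = dimnames(config$mbll$extinction))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  ext <- doc$mbll$extinction
  doc$mbll$extinction <- matrix(unlist(ext$values), nrow = unlist(ext$dim)[1],
                                dimnames = ext$dimnames)
  doc$simulator$population <- lapply(doc$simulator$population, unlist)
  doc$training$budgets <- as.numeric(unlist(doc$training$budgets))
  for (k in c("paradigm", "preprocess", "stats")) doc[[k]] <- lapply(doc[[k]], unlist)
  doc$mbll$wavelengths_nm <- unlist(doc$mbll$wavelengths_nm)
  doc$mbll$dpf <- unlist(doc$mbll$dpf)
  structure(doc, class = "run_config")
}

#' @noRd
schedule_from_config <- function(config) {
  p <- config$paradigm
  build_schedule(sessions = p$sessions,
                 series_per_session = p$series_per_session,
                 sampling_rate = p$sampling_rate,
                 instruction_s = p$instruction_s, task_s = p$task_s,
                 rest_s = p$rest_s, trials_per_series = p$trials_per_series)
}

#' @noRd
mbll_from_config <- function(config) {
  default_mbll_config(wavelengths_nm = config$mbll$wavelengths_nm,
                      extinction = config$mbll$extinction,
                      distance_mm = config$mbll$distance_mm,
                      dpf = config$mbll$dpf)
}

#' Simulate a cohort from a run configuration
#' @param config A `run_config`.
#' @return An `fnirs_cohort`.
#' @export
cohort_from_config <- function(config) {
  make_cohort(n_subjects = config$simulator$n_subjects,
              schedule = schedule_from_config(config),
              n_channels = config$simulator$n_channels,
              population = config$simulator$population,
              mbll = mbll_from_config(config),
              master_seed = config$simulator$master_seed)
}

#' Preprocess a cohort into per-subject epoch sets
#'
#' MBLL inversion, zero-phase low-pass, sliding-window epoching (and
#' optional decimation) for every subject, using the configuration's
#' preprocessing block.
#'
#' @param cohort An `fnirs_cohort`.
#' @param config A `run_config`.
#' @return List of `epoch_set`s in cohort order.
#' @export
prepare_cohort_epochs <- function(cohort, config = default_run_config()) {
  pp <- config$preprocess
  mbll <- mbll_from_config(config)
  lapply(cohort$subjects, function(s) {
    hemo <- mbll_invert(s$optical, mbll)
    hemo <- lowpass_filter(hemo, cutoff_hz = pp$cutoff_hz,
                           order = pp$filter_order)
    segment_epochs(hemo, window_s = pp$window_s, step_s = pp$step_s,
                   class_mode = pp$class_mode, decimate = pp$decimate)
  })
}

#' @noRd
spec_from_config <- function(config) {
  pp <- config$preprocess
  wlen <- round(pp$window_s * config$paradigm$sampling_rate)
  n_samp <- length(seq(1, wlen, by = pp$decimate))
  n_classes <- if (identical(pp$class_mode, "4class")) 4L else 3L
  shape <- c(config$simulator$n_channels, n_samp, 2L)
  if (identical(config$model$network, "full")) {
    default_cnn_spec(shape, n_classes)
  } else {
    reduced_cnn_spec(shape, n_classes)
  }
}

#' Run the full experiment
#'
#' Simulate the cohort, preprocess it, pretrain on the source subjects,
#' sweep both groups over the epoch budgets, and compare the resulting
#' tables statistically. The report is a pure function of the
#' configuration (including its master seed).
#'
#' @param config A `run_config`.
#' @return List: the two [accuracy_table()]s, the [compare_groups()]
#'   report, per-budget group means (learning-curve data), the subject
#'   assignment and the config echo.
#' @export
run_full_experiment <- function(config = default_run_config()) {
  cohort <- cohort_from_config(config)
  epoch_sets <- prepare_cohort_epochs(cohort, config)
  spec <- spec_from_config(config)
  tr <- config$training
  sweep <- epoch_budget_sweep(
    epoch_sets, spec, budgets = tr$budgets,
    n_source = tr$n_source, n_control = tr$n_control,
    n_baseline = tr$n_baseline, assignment = tr$assignment,
    plan = freeze_plan(tr$freeze_plan),
    split = split_scheme(tr$split$kind, k = tr$split$k,
                         unit = tr$split$unit,
                         rng_seed = derive_seed(config$simulator$master_seed, 7)),
    pretrain_epochs = tr$pretrain_epochs, lr = tr$lr,
    batch_size = tr$batch_size,
    master_seed = config$simulator$master_seed)
  test_budget <- config$stats$test_budget
  if (!test_budget %in% sweep$budgets) {
    test_budget <- max(sweep$budgets)
  }
  report <- compare_groups(sweep$control, sweep$baseline,
                           budget = test_budget,
                           alpha = config$stats$alpha)
  list(control = sweep$control, baseline = sweep$baseline,
       stat_report = report,
       learning_curves = list(
         budgets = sweep$budgets,
         control_mean = unname(column_means(sweep$control, rounded = FALSE)),
         baseline_mean = unname(column_means(sweep$baseline, rounded = FALSE))),
       assignment = sweep$assignment,
       pretrain_loss = sweep$checkpoint$loss,
       config = config,
       master_seed = config$simulator$master_seed)
}

#' Reproduce the reference statistical analysis
#'
#' Runs the full statistical comparison on the packaged reference tables
#' and attaches the published values next to the recomputed ones for a
#' side-by-side check: group means per budget, Shapiro-Wilk normality of
#' every column, the two-tailed paired t-test on the chosen budget column,
#' the mean paired difference and the control-table maximum.
#'
#' @param alpha Significance level for the normality decisions.
#' @param budget Budget column for the paired test (default 60).
#' @return A `stat_report` with a `published` element attached.
#' @export
reproduce_reference_stats <- function(alpha = 0.05, budget = 60) {
  tabs <- reference_tables()
  report <- compare_groups(tabs$control, tabs$baseline,
                           budget = budget, alpha = alpha)
  report$published <- list(
    control_means = c(`10` = 51.42, `20` = 63.72, `30` = 73.78,
                      `40` = 82.76, `50` = 90.43, `60` = 94.52),
    baseline_means = c(`10` = 52.14, `20` = 63.96, `30` = 64.89,
                       `40` = 66.13, `50` = 67.83, `60` = 68.95),
    t = 17.8723, df = 9, p_value = 2.443e-8,
    mean_diff = 25.58, max_control = 97.83
  )
  class(report) <- c("reference_stat_report", "stat_report")
  report
}

#' @export
print.reference_stat_report <- function(x, ...) {
  cat("Recomputed vs published reference statistics\n\n")
  cmp <- rbind(`control mean (recomputed)` = x$means$control,
               `control mean (published)` = x$published$control_means,
               `baseline mean (recomputed)` = x$means$baseline,
               `baseline mean (published)` = x$published$baseline_means)
  print(cmp)
  cat(sprintf("\npaired t (budget %d): recomputed %.4f (df %d, p %.4g) | published %.4f (df %d, p %.4g)\n",
              x$test_budget, x$paired_t$t, x$paired_t$df, x$paired_t$p_value,
              x$published$t, x$published$df, x$published$p_value))
  cat(sprintf("mean difference: recomputed %.2f | published %.2f (from rounded means)\n",
              x$mean_diff, x$published$mean_diff))
  cat(sprintf("control maximum: recomputed %.2f | published %.2f\n",
              x$max_cell$control, x$published$max_control))
  ok <- all(x$normality$control$normal) && all(x$normality$baseline$normal)
  cat(sprintf("Shapiro-Wilk: normality %s in every budget column (alpha = %g)\n",
              if (ok) "retained" else "REJECTED", x$alpha))
  invisible(x)
}

## ---- cohort disk format ----------------------------------------------------

#' Write / read one optical recording as TSV + JSON sidecar
#'
#' The TSV holds one row per (channel, wavelength) pair — columns
#' `channel`, `wavelength_nm`, then one column per sample — and the JSON
#' sidecar records sampling rate, geometry and schedule parameters.
#'
#' @param optical An `optical_recording`.
#' @param dir Destination directory (created if needed).
#' @return `save_recording` invisibly returns the TSV path;
#'   `load_recording` returns the `optical_recording`.
#' @export
save_recording <- function(optical, dir) {
  stopifnot(inherits(optical, "optical_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(optical$data)
  flat <- matrix(aperm(optical$data, c(2, 1, 3)), nrow = d[1] * d[2])
  df <- data.frame(channel = rep(seq_len(d[1]), each = d[2]),
                   wavelength_nm = rep(optical$wavelengths_nm, d[1]))
  df <- cbind(df, as.data.frame(flat))
  stem <- file.path(dir, paste0(optical$subject_id))
  tsv <- paste0(stem, ".tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  sched <- optical$schedule
  sidecar <- list(subject_id = optical$subject_id,
                  sampling_rate = optical$sampling_rate,
                  wavelengths_nm = optical$wavelengths_nm,
                  distance_mm = optical$distance_mm,
                  dpf = optical$dpf,
                  n_channels = d[1], n_samples = d[3],
                  schedule = list(sessions = sched$sessions,
                                  series_per_session = sched$series_per_session,
                                  sampling_rate = sched$sampling_rate,
                                  instruction_s = sched$series$instruction_s[1],
                                  task_s = sched$series$task_s[1],
                                  rest_s = sched$series$rest_s[1],
                                  trials_per_series = sched$series$n_trials[1]))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             paste0(stem, ".json"))
  invisible(tsv)
}

#' @param stem Path stem (without extension) as written by
#'   `save_recording`.
#' @rdname save_recording
#' @export
load_recording <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  df <- read.csv(paste0(stem, ".tsv"), sep = "\t", check.names = FALSE)
  vals <- as.matrix(df[, -(1:2)])
  d <- c(meta$n_channels, 2L, meta$n_samples)
  data <- aperm(array(vals, dim = c(2, meta$n_channels, meta$n_samples)),
                c(2, 1, 3))
  s <- meta$schedule
  schedule <- build_schedule(sessions = s$sessions,
                             series_per_session = s$series_per_session,
                             sampling_rate = s$sampling_rate,
                             instruction_s = s$instruction_s,
                             task_s = s$task_s, rest_s = s$rest_s,
                             trials_per_series = s$trials_per_series)
  structure(list(data = data,
                 sampling_rate = meta$sampling_rate,
                 wavelengths_nm = meta$wavelengths_nm,
                 distance_mm = meta$distance_mm,
                 dpf = meta$dpf,
                 subject_id = meta$subject_id,
                 schedule = schedule),
            class = "optical_recording")
}

#' Simulate a cohort and write it to disk
#'
#' One TSV + JSON sidecar per subject plus a manifest recording the master
#' seed and per-file checksums; rerunning with the same configuration
#' reproduces identical files.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
simulate_cohort_dir <- function(config = default_run_config(), out_dir) {
  cohort <- cohort_from_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort$subjects, function(s) {
    save_recording(s$optical, out_dir)
  }, character(1))
  manifest <- list(master_seed = cohort$master_seed,
                   n_subjects = length(cohort$subjects),
                   files = basename(files),
                   md5 = unname(tools::md5sum(files)))
  path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
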