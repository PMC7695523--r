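#' Analysis configuration
#'
#' Collects the tunable parameters of the detection/evaluation stages.
#' `threshold` is the significance band in baseline-SD units (1.96, the
#' 95% band). `direction` selects two-sided crossings (the stated
#' significance rule, the package default) or directional crossings in the
#' physiologically expected direction, which the evaluation stages use for
#' lead-time and performance analyses (see the methods vignette).
#' `pre_window` is the detection window relative to treatment (default
#' -14..0, the two pre-exacerbation weeks with the treatment day included).
#'
#' @param threshold crossing threshold in SD units (> 0).
#' @param direction `"two_sided"` or `"directional"`.
#' @param consecutive_days_required minimum run of abnormal days before a
#'   crossing counts (default 1).
#' @param pre_window integer 2-vector within -14..0.
#' @param post_includes_day0 include day 0 in the post phase of
#'   [phase_summaries()] (default `FALSE`).
#' @param nightly_statistic `"mean"` or `"median"` nightly summary.
#' @param seed seed recorded with the run.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(threshold = 1.96,
                            direction = c("two_sided", "directional"),
                            consecutive_days_required = 1L,
                            pre_window = c(-14L, 0L),
                            post_includes_day0 = FALSE,
                            nightly_statistic = c("mean", "median"),
                            seed = 1L) {
  direction <- match.arg(direction)
  nightly_statistic <- match.arg(nightly_statistic)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("invalid analysis_config: `threshold` must be > 0",
          class = "oxicopd_config_error")
  }
  if (!is.numeric(pre_window) || length(pre_window) != 2 ||
      pre_window[1] > pre_window[2] || pre_window[1] < -14 ||
      pre_window[2] > 0) {
    abort("invalid analysis_config: `pre_window` must lie within -14..0",
          class = "oxicopd_config_error")
  }
  if (!is.numeric(consecutive_days_required) ||
      consecutive_days_required < 1) {
    abort("invalid analysis_config: `consecutive_days_required` must be >= 1",
          class = "oxicopd_config_error")
  }
  structure(list(threshold = threshold, direction = direction,
                 consecutive_days_required = as.integer(consecutive_days_required),
                 pre_window = as.integer(pre_window),
                 post_includes_day0 = isTRUE(post_includes_day0),
                 nightly_statistic = nightly_statistic,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML file has `sim:` and `analysis:` sections whose fields mirror
#' the arguments of [sim_config()] and [analysis_config()]; omitted fields
#' take the defaults.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: list with elements `sim` (a `sim_config`)
#'   and `analysis` (an `analysis_config`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  ana_args <- raw$analysis %||% list()
  list(sim = do.call(sim_config, sim_args),
       analysis = do.call(analysis_config, ana_args))
}

#' @rdname read_run_config
#' @param config list with `sim` and `analysis` configurations.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x, drop) {
    x <- unclass(x)
    x[setdiff(names(x), drop)]
  }
  yaml::write_yaml(
    list(sim = strip(config$sim, "n_per_night"),
         analysis = strip(config$analysis, character())),
    path)
  invisible(path)
}

run_config_hash <- function(sim, analysis) {
  rlang::hash(list(sim = unclass(sim), analysis = unclass(analysis)))
}

#' Run the full pipeline: simulate, score, detect, evaluate
#'
#' Orchestrates a complete reproducible run against a simulated cohort:
#' simulation, CSV round-trip through the interchange readers, daily
#' aggregation and run-in removal, eligibility screening (with per-patient
#' exclusion logging), baseline calibration, event-aligned Z scoring,
#' threshold detection, lead-time tables, event-level performance against
#' the second stable window, group trajectories and (optionally) the
#' trajectory figure. Every output CSV carries a header and a provenance
#' comment naming the resolved configuration hash; rerunning with the same
#' configurations yields byte-identical CSVs.
#'
#' @param out_dir output directory for the run.
#' @param sim a [sim_config()].
#' @param analysis an [analysis_config()].
#' @param write_raw also write the raw oximetry/diary/manifest/truth CSVs
#'   (default `TRUE`; the oximetry file can be large).
#' @param make_plot write `trajectories.png` (default `TRUE`).
#' @return invisibly, a list of class `copd_run` with the run's tables:
#'   `daily`, `eligibility`, `baselines`, `zscores`, `detections`,
#'   `lead_times`, `lead_summary`, `performance` (possibly `NULL`),
#'   `trajectory`, `truth`, `manifest`, and `config_hash`.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(),
                         analysis = analysis_config(),
                         write_raw = TRUE, make_plot = TRUE) {
  stopifnot(inherits(sim, "sim_config"), inherits(analysis, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- run_config_hash(sim, analysis)
  log_lines <- c(sprintf("oxicopd run, config hash %s", hash))
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "oxicopd_stage_error")
    })
  }

  cohort <- stage("simulate", simulate_cohort(sim))
  say("simulated %d patients (%d overnight, %d events)",
      nrow(cohort$manifest), sum(cohort$manifest$arm == "overnight"),
      sum(!is.na(cohort$manifest$treatment_day)))
  if (write_raw) {
    stage("write", write_cohort_csv(cohort, out_dir, config_hash = hash))
    # round-trip through the interchange readers so the analysed data are
    # exactly what the files contain
    oximetry <- stage("read", read_oximetry(file.path(out_dir, "oximetry.csv")))
    diary <- stage("read", read_diary(file.path(out_dir, "diary.csv")))
    manifest <- stage("read", read_manifest(file.path(out_dir, "manifest.csv")))
  } else {
    oximetry <- flag_valid_samples(cohort$oximetry)
    diary <- cohort$diary
    manifest <- cohort$manifest
  }

  daily <- stage("daily", build_daily_series(
    oximetry, diary, manifest, nightly_statistic = analysis$nightly_statistic,
    run_in_days = sim$run_in_days))
  eligibility <- stage("eligibility", check_eligibility(daily, manifest))
  for (i in which(!eligibility$eligible)) {
    say("excluded %s: %s", eligibility$patient_id[i],
        paste(eligibility$reasons[[i]], collapse = ", "))
  }
  keep <- eligibility$patient_id[eligibility$eligible]
  daily_ok <- filter(daily, .data$patient_id %in% keep)
  manifest_ok <- filter(manifest, .data$patient_id %in% keep)

  window1 <- stage("baseline", select_stable_window(daily_ok, manifest_ok))
  baselines <- stage("baseline", baseline_stats(daily_ok, window1))
  write_output_csv(baselines, file.path(out_dir, "baselines.csv"), hash)

  has_events <- any(!is.na(manifest_ok$treatment_day))
  zscores <- detections <- lead_times <- lead_summary <- NULL
  performance <- trajectory <- NULL
  if (has_events) {
    aligned <- stage("score", align_to_event(daily_ok, manifest_ok))
    zscores <- stage("score", zseries(aligned, baselines))
    write_output_csv(zscores, file.path(out_dir, "zscores.csv"), hash)

    detections <- stage("detect", detect_abnormal_days(
      zscores, threshold = analysis$threshold,
      direction = analysis$direction,
      consecutive_days_required = analysis$consecutive_days_required,
      pre_window = analysis$pre_window))
    write_output_csv(
      detections |>
        mutate(abnormal_days = map_chr(.data$abnormal_days, paste,
                                       collapse = ";")),
      file.path(out_dir, "detections.csv"), hash)

    lead_times <- stage("evaluate", time_to_treatment(detections))
    lead_summary <- stage("evaluate",
                          summarize_lead_times(lead_times, manifest_ok))
    write_output_csv(select(lead_times, -"abnormal_days"),
                     file.path(out_dir, "lead_times.csv"), hash)
    write_output_csv(lead_summary$summary,
                     file.path(out_dir, "lead_time_summary.csv"), hash)

    window2 <- stage("evaluate", select_stable_window(
      daily_ok, manifest_ok, exclude = window1))
    if (nrow(window2)) {
      z2 <- stage("evaluate", window_zscores(daily_ok, baselines, window2))
      stable_flags <- stage("evaluate", crossing_flags(
        z2, threshold = analysis$threshold, direction = analysis$direction,
        consecutive_days_required = analysis$consecutive_days_required))
      event_ids <- manifest_ok$patient_id[!is.na(manifest_ok$treatment_day)]
      performance <- stage("evaluate", event_performance(
        filter(detections, .data$variable == "COMPOSITE",
               .data$patient_id %in% event_ids),
        filter(stable_flags, .data$variable == "COMPOSITE")))
      write_output_csv(as_tibble(unclass(performance)),
                       file.path(out_dir, "performance.csv"), hash)
    } else {
      say("no second stable window available; performance table skipped")
    }

    trajectory <- stage("evaluate", group_z_trajectory(zscores, manifest_ok))
    write_output_csv(trajectory, file.path(out_dir, "trajectory.csv"), hash)
    if (make_plot) {
      ggsave(file.path(out_dir, "trajectories.png"),
             plot_z_trajectory(trajectory, analysis$threshold),
             width = 9, height = 6, dpi = 150)
    }
  } else {
    say("no events in the cohort; evaluation stages skipped")
  }

  write_run_config(list(sim = sim, analysis = analysis),
                   file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(structure(list(
    daily = daily, eligibility = eligibility, baselines = baselines,
    zscores = zscores, detections = detections, lead_times = lead_times,
    lead_summary = lead_summary, performance = performance,
    trajectory = trajectory, truth = cohort$truth, manifest = manifest,
    config_hash = hash
  ), class = "copd_run"))
}

#' @export
print.copd_run <- function(x, ...) {
  cat(sprintf("<copd_run> config %s\n", x$config_hash))
  cat(sprintf("  %d patients, %d eligible\n", nrow(x$eligibility),
              sum(x$eligibility$eligible)))
  if (!is.null(x$performance)) {
    cat(sprintf("  composite: sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%\n",
                100 * x$performance$sensitivity,
                100 * x$performance$specificity, 100 * x$performance$ppv))
  }
  invisible(x)
}
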