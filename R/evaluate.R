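#' Evaluate a daily cohort: eligibility through detection performance
#'
#' In-memory core of the pipeline, starting from QC'd daily series:
#' applies the exclusion rules, selects the baseline and second stable
#' windows, calibrates baselines, computes event-aligned Z series,
#' detects threshold crossings, derives lead times, and builds the
#' event-level composite performance table against the second stable
#' window. Stages that need events are `NULL` when the cohort has none.
#'
#' @param daily output of [build_daily_series()].
#' @param manifest tibble with `patient_id`, `arm`, `treatment_day`.
#' @param analysis an [analysis_config()].
#' @return list with `eligibility`, `manifest` (eligible patients),
#'   `daily` (eligible patients), `window1`, `window2`, `baselines`,
#'   `aligned`, `zscores`, `detections`, `lead_times`, `lead_summary`,
#'   `stable_flags`, `performance`.
#' @export
evaluate_cohort <- function(daily, manifest, analysis = analysis_config()) {
  stopifnot(inherits(analysis, "analysis_config"))
  eligibility <- check_eligibility(daily, manifest)
  keep <- eligibility$patient_id[eligibility$eligible]
  daily_ok <- filter(daily, .data$patient_id %in% keep)
  manifest_ok <- filter(manifest, .data$patient_id %in% keep)

  window1 <- select_stable_window(daily_ok, manifest_ok)
  baselines <- baseline_stats(daily_ok, window1)

  out <- list(eligibility = eligibility, manifest = manifest_ok,
              daily = daily_ok, window1 = window1, baselines = baselines,
              window2 = NULL, aligned = NULL, zscores = NULL,
              detections = NULL, lead_times = NULL, lead_summary = NULL,
              stable_flags = NULL, performance = NULL)

  if (!any(!is.na(manifest_ok$treatment_day))) {
    return(out)
  }
  out$aligned <- align_to_event(daily_ok, manifest_ok)
  out$zscores <- zseries(out$aligned, baselines)
  out$detections <- detect_abnormal_days(
    out$zscores, threshold = analysis$threshold,
    direction = analysis$direction,
    consecutive_days_required = analysis$consecutive_days_required,
    pre_window = analysis$pre_window)
  out$lead_times <- time_to_treatment(out$detections)
  out$lead_summary <- summarize_lead_times(out$lead_times, manifest_ok)

  out$window2 <- select_stable_window(daily_ok, manifest_ok,
                                      exclude = window1)
  if (nrow(out$window2)) {
    z2 <- window_zscores(daily_ok, baselines, out$window2)
    out$stable_flags <- crossing_flags(
      z2, threshold = analysis$threshold, direction = analysis$direction,
      consecutive_days_required = analysis$consecutive_days_required)
    event_ids <- manifest_ok$patient_id[!is.na(manifest_ok$treatment_day)]
    out$performance <- event_performance(
      filter(out$detections, .data$variable == "COMPOSITE",
             .data$patient_id %in% event_ids),
      filter(out$stable_flags, .data$variable == "COMPOSITE"))
  }
  out
}
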