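#' Per-patient, per-variable baseline statistics over the stable window
#'
#' The baseline (stable state) for each patient is the mean and sample SD
#' (n-1 denominator) of each variable's daily values over the 14-day
#' stable window. Every window day must be non-missing — choose the window
#' with [select_stable_window()] — and a zero-variance window is an error:
#' Z scores are undefined on a degenerate baseline, and a fortnight of
#' identical readings indicates broken input rather than a quiet patient.
#'
#' @param daily output of [build_daily_series()].
#' @param window tibble (`patient_id`, `date`) of baseline days.
#' @return tibble with `patient_id`, `variable`, `mean`, `sd`, `n_days`.
#' @export
#' @examples
#' daily <- tibble::tibble(patient_id = "P1",
#'                         date = as.Date("2024-03-08") + 0:13,
#'                         variable = "CAT", value = 1:14, n_samples = 1L)
#' window <- daily[, c("patient_id", "date")]
#' baseline_stats(daily, window)
baseline_stats <- function(daily, window) {
  stats <- daily |>
    inner_join(window, by = c("patient_id", "date")) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_days = dplyr::n(), .by = c("patient_id", "variable"))
  expected <- window |> count(.data$patient_id, name = "n_window")
  short <- stats |>
    inner_join(expected, by = "patient_id") |>
    filter(.data$n_days < .data$n_window)
  if (nrow(short)) {
    abort(sprintf(
      "baseline window has missing days for %s (%s): the window must be chosen on complete days",
      short$patient_id[1], short$variable[1]),
      class = "oxicopd_baseline_error")
  }
  degenerate <- filter(stats, .data$sd == 0)
  if (nrow(degenerate)) {
    abort(sprintf(
      "degenerate baseline for %s (%s): zero variance over the stable window, Z scores undefined",
      degenerate$patient_id[1], degenerate$variable[1]),
      class = "oxicopd_degenerate_baseline_error")
  }
  arrange(stats, .data$patient_id, .data$variable)
}

#' Z score of a daily value against a stable baseline
#'
#' `Z = (X - xbar) / SD`, the day's value expressed in units of the
#' patient's own stable-state day-to-day variability.
#'
#' @param x daily value(s).
#' @param mean baseline mean `xbar`.
#' @param sd baseline SD; must be positive.
#' @return dimensionless Z score(s).
#' @export
#' @examples
#' zscore(80, 77.1, 3.6)
zscore <- function(x, mean, sd) {
  if (any(!is.na(sd) & sd <= 0)) {
    abort("zscore: baseline SD must be positive (degenerate baseline)",
          class = "oxicopd_degenerate_baseline_error")
  }
  (x - mean) / sd
}

#' Composite pulse-oximetry score
#'
#' `Z_HR - Z_SpO2`: rises when heart rate rises and/or oxygen saturation
#' falls, the joint physiological signature of an exacerbation. Missing in
#' either input propagates to the composite.
#'
#' @param z_hr,z_spo2 Z scores of heart rate and SpO2.
#' @return composite Z score(s).
#' @export
#' @examples
#' composite_score(1.7, -1.8)
composite_score <- function(z_hr, z_spo2) {
  z_hr - z_spo2
}

#' Event-aligned Z-score series, including the composite score
#'
#' Converts event-aligned daily values to Z scores against each patient's
#' baseline, adds the composite oximetry score on days where both HR and
#' SpO2 are available, and prepends the day -15 display slot (the stable
#' mean, Z = 0 by construction; excluded from all statistics).
#'
#' @param aligned output of [align_to_event()].
#' @param baselines output of [baseline_stats()].
#' @return tibble with `patient_id`, `variable` (HR, SpO2, CAT, PEF,
#'   COMPOSITE), `day_index` (-15..+13), `z`.
#' @export
zseries <- function(aligned, baselines) {
  z <- aligned |>
    inner_join(baselines, by = c("patient_id", "variable")) |>
    mutate(z = zscore(.data$value, .data$mean, .data$sd)) |>
    select("patient_id", "variable", "day_index", "z")
  comp <- z |>
    filter(.data$variable %in% c("HR", "SpO2")) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "z") |>
    filter(!is.na(.data$HR) & !is.na(.data$SpO2)) |>
    mutate(variable = "COMPOSITE",
           z = composite_score(.data$HR, .data$SpO2)) |>
    select("patient_id", "variable", "day_index", "z")
  out <- bind_rows(z, comp)
  stable_slot <- out |>
    distinct(.data$patient_id, .data$variable) |>
    mutate(day_index = DAY_STABLE, z = 0)
  bind_rows(stable_slot, out) |>
    arrange(.data$patient_id,
            factor(.data$variable, levels = VARIABLES_Z), .data$day_index)
}

#' Z scores over an arbitrary window of stable days
#'
#' Scores the daily values falling in the given window (e.g. the second
#' stable window used for the specificity analysis) against the baseline,
#' with `day_index` numbering the window days 1, 2, ... per patient.
#' Includes the composite score where both HR and SpO2 are present.
#'
#' @param daily output of [build_daily_series()].
#' @param baselines output of [baseline_stats()].
#' @param window tibble (`patient_id`, `date`).
#' @return tibble with `patient_id`, `variable`, `day_index`, `z`.
#' @export
window_zscores <- function(daily, baselines, window) {
  z <- daily |>
    inner_join(window, by = c("patient_id", "date")) |>
    inner_join(baselines, by = c("patient_id", "variable")) |>
    mutate(z = zscore(.data$value, .data$mean, .data$sd)) |>
    mutate(day_index = dense_rank(.data$date), .by = "patient_id") |>
    select("patient_id", "variable", "day_index", "z")
  comp <- z |>
    filter(.data$variable %in% c("HR", "SpO2")) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "z") |>
    filter(!is.na(.data$HR) & !is.na(.data$SpO2)) |>
    mutate(variable = "COMPOSITE",
           z = composite_score(.data$HR, .data$SpO2)) |>
    select("patient_id", "variable", "day_index", "z")
  bind_rows(z, comp) |>
    arrange(.data$patient_id,
            factor(.data$variable, levels = VARIABLES_Z), .data$day_index)
}

#' Days on which CAT exceeds its baseline by the MCID
#'
#' The minimal clinically important difference (MCID) for the CAT
#' questionnaire is 2 points: a day is flagged when the CAT value exceeds
#' the patient's baseline mean by at least `mcid` points. This is the
#' clinical-relevance companion to the statistical 1.96-SD threshold.
#'
#' @param aligned output of [align_to_event()] (its CAT rows are used).
#' @param baselines output of [baseline_stats()].
#' @param mcid threshold in CAT points (default 2).
#' @return tibble with `patient_id`, `day_index`, `value`, `excess`
#'   (points above baseline mean), one row per flagged day.
#' @export
mcid_flags <- function(aligned, baselines, mcid = 2) {
  aligned |>
    filter(.data$variable == "CAT") |>
    inner_join(filter(baselines, .data$variable == "CAT"),
               by = c("patient_id", "variable")) |>
    mutate(excess = .data$value - .data$mean) |>
    filter(.data$excess >= mcid) |>
    select("patient_id", "day_index", "value", "excess") |>
    arrange(.data$patient_id, .data$day_index)
}
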