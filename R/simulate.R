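#' Additive exacerbation effect at a given day offset
#'
#' The prodromal/recovery effect shape applied by the simulator: zero before
#' the prodrome, a linear ramp from 0 at `-prodrome_days` to the variable's
#' maximal effect at day 0 (treatment start), and a linear return to 0 at
#' `+recovery_days`. The sign follows the variable's physiological
#' direction: heart rate and CAT rise, SpO2 and PEF fall.
#'
#' @param day_offset integer day(s) relative to treatment start (day 0).
#' @param variable one of `"HR"`, `"SpO2"`, `"CAT"`, `"PEF"`.
#' @param config a [sim_config()].
#' @param arm `"overnight"` or `"once_daily"`; selects the arm-specific
#'   maximal HR/SpO2 effects.
#' @return numeric vector of additive effects in the variable's units.
#' @export
#' @examples
#' cfg <- sim_config()
#' exacerbation_profile(c(-30, -7, 0, 13, 20), "HR", cfg)
exacerbation_profile <- function(day_offset, variable, config,
                                 arm = "overnight") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.character(variable) || length(variable) != 1 ||
      !variable %in% VARIABLES) {
    abort(sprintf("unknown variable `%s`; expected one of %s",
                  paste(variable, collapse = ","),
                  paste(VARIABLES, collapse = ", ")),
          class = "oxicopd_variable_error")
  }
  arm <- match.arg(arm, c("overnight", "once_daily"))
  delta <- switch(variable,
    HR = if (arm == "overnight") config$delta_hr_overnight else config$delta_hr_daily,
    SpO2 = if (arm == "overnight") config$delta_spo2_overnight else config$delta_spo2_daily,
    CAT = config$delta_cat,
    PEF = config$delta_pef
  )
  p <- config$prodrome_days
  r <- config$recovery_days
  f <- numeric(length(day_offset))
  up <- day_offset >= -p & day_offset <= 0
  f[up] <- (day_offset[up] + p) / p
  if (r > 0) {
    down <- day_offset > 0 & day_offset <= r
    f[down] <- 1 - day_offset[down] / r
  }
  delta * f
}

# calendar date a sample belongs to: nights are attributed to the waking
# morning's date; works for any sample taken between noon and 11:59 the
# next day (overnight recordings and morning spot readings alike)
sample_date <- function(timestamp) {
  as.Date(timestamp + 43200, tz = "UTC")
}

#' Simulate a single patient's monitoring record
#'
#' Generates the complete (no missingness) record for one patient:
#' overnight-arm patients carry a per-night oximetry stream (one sample
#' every `sample_interval_s` seconds, heart rate and SpO2 rounded to device
#' integer resolution), once-daily patients a single morning spot reading
#' per day; both arms keep a daily diary (integer CAT 0-40, PEF). Daily
#' physiological levels fluctuate around the arm's baseline with the
#' configured day-to-day SDs (HR and SpO2 fluctuations correlated by
#' `hr_spo2_corr`), plus the [exacerbation_profile()] drift for event
#' patients.
#'
#' Noise streams are drawn from a child seed of `config$seed` and the
#' patient index, in an order that does not depend on the effect sizes, so
#' cohorts simulated under different `delta_*` values but the same seed are
#' matched draw-for-draw.
#'
#' @param config a [sim_config()].
#' @param index 1-based patient index (seed stream).
#' @param arm `"overnight"` or `"once_daily"`.
#' @param has_event does this patient have a treated exacerbation?
#' @param patient_id patient identifier string.
#' @param monitoring_start first monitored calendar date.
#' @return list with tibbles `oximetry` (patient_id, timestamp, heart_rate,
#'   spo2), `diary` (patient_id, date, cat, pef), `manifest` and `truth`
#'   (one row each).
#' @export
simulate_patient <- function(config, index, arm, has_event,
                             patient_id = sprintf("P%04d", index),
                             monitoring_start = as.Date("2024-03-01")) {
  stopifnot(inherits(config, "sim_config"))
  arm <- match.arg(arm, c("overnight", "once_daily"))
  nd <- config$total_days
  dates <- monitoring_start + seq_len(nd) - 1L
  treatment_day <- if (has_event) dates[config$treatment_day_index] else as.Date(NA)

  set.seed(child_seed(config$seed, index, 1L))
  # fixed draw order, independent of arm and effect sizes
  e_hr <- rnorm(nd)
  e_spo2 <- config$hr_spo2_corr * e_hr +
    sqrt(1 - config$hr_spo2_corr^2) * rnorm(nd)
  e_cat <- rnorm(nd)
  e_pef <- rnorm(nd)
  # spot-reading deviations share the HR/SpO2 correlation: the transient,
  # non-exacerbation factors behind a one-off morning reading (activity,
  # anxiety, medication timing) move both channels jointly
  e_spot_hr <- rnorm(nd)
  e_spot_spo2 <- config$hr_spo2_corr * e_spot_hr +
    sqrt(1 - config$hr_spo2_corr^2) * rnorm(nd)

  off <- if (has_event) seq_len(nd) - config$treatment_day_index else rep(-Inf, nd)
  eff <- function(v) if (has_event) exacerbation_profile(off, v, config, arm) else 0

  hr_level <- true_daily_mean(config, "HR", arm) + eff("HR") +
    config$sd_hr_overnight * e_hr
  spo2_level <- true_daily_mean(config, "SpO2", arm) + eff("SpO2") +
    config$sd_spo2_overnight * e_spo2
  cat_level <- config$baseline_cat + eff("CAT") + config$sd_cat * e_cat
  pef_level <- config$baseline_pef + eff("PEF") + config$sd_pef * e_pef

  if (arm == "overnight") {
    ns <- config$n_per_night
    night_start <- as.POSIXct(dates - 1L, tz = "UTC") + 22.5 * 3600
    ts <- rep(night_start, each = ns) +
      rep.int(seq(0, by = config$sample_interval_s, length.out = ns), nd)
    hr <- round(rep(hr_level, each = ns) +
                  rnorm(nd * ns, 0, config$within_night_sd_hr))
    spo2 <- round(rep(spo2_level, each = ns) +
                    rnorm(nd * ns, 0, config$within_night_sd_spo2))
  } else {
    ts <- as.POSIXct(dates, tz = "UTC") + 8 * 3600
    hr <- round(hr_level + config$spot_noise_sd_hr * e_spot_hr)
    spo2 <- round(spo2_level + config$spot_noise_sd_spo2 * e_spot_spo2)
  }

  list(
    oximetry = tibble(patient_id = patient_id, timestamp = ts,
                      heart_rate = hr, spo2 = spo2),
    diary = tibble(patient_id = patient_id, date = dates,
                   cat = pmin(pmax(round(cat_level), 0), 40),
                   pef = pmax(pef_level, 0)),
    manifest = tibble(patient_id = patient_id, arm = arm,
                      monitoring_start = monitoring_start,
                      treatment_day = treatment_day),
    truth = tibble(
      patient_id = patient_id, arm = arm, has_event = has_event,
      treatment_day = treatment_day,
      true_hr = true_daily_mean(config, "HR", arm),
      true_spo2 = true_daily_mean(config, "SpO2", arm),
      true_cat = config$baseline_cat, true_pef = config$baseline_pef,
      delta_hr = if (arm == "overnight") config$delta_hr_overnight else config$delta_hr_daily,
      delta_spo2 = if (arm == "overnight") config$delta_spo2_overnight else config$delta_spo2_daily,
      delta_cat = config$delta_cat, delta_pef = config$delta_pef
    )
  )
}

# deterministic cohort plan: arms and events assigned by patient index
cohort_plan <- function(config, monitoring_start = as.Date("2024-03-01")) {
  n <- config$n_patients
  if (n == 0) {
    return(tibble(index = integer(), patient_id = character(),
                  arm = character(), has_event = logical(),
                  monitoring_start = as.Date(character())))
  }
  n_over <- round(n * config$arm_split)
  arm <- rep(c("overnight", "once_daily"), c(n_over, n - n_over))
  has_event <- unlist(lapply(split(seq_len(n), arm)[unique(arm)], function(i) {
    k <- round(length(i) * config$exacerbation_fraction)
    seq_along(i) <= k
  }), use.names = FALSE)
  tibble(index = seq_len(n),
         patient_id = sprintf("P%04d", seq_len(n)),
         arm = arm, has_event = has_event,
         monitoring_start = monitoring_start)
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates `config$n_patients` patients (arms and exacerbation status
#' assigned deterministically by patient index), applies day-level
#' missingness via [inject_missingness()] unless disabled, and returns the
#' cohort as a set of tidy tables. Reproducible: the same `config` (and
#' seed) yields an identical cohort.
#'
#' @param config a [sim_config()].
#' @param apply_missingness drop days per `missing_day_prob` /
#'   `consecutive_miss_prob` (default `TRUE`).
#' @param monitoring_start first monitored calendar date for all patients.
#' @return an object of class `copd_cohort`: a list with tibbles
#'   `oximetry`, `diary`, `manifest`, `truth`.
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 2, arm_split = 0,
#'                                  total_days = 30, treatment_day_index = 25,
#'                                  recovery_days = 5, seed = 7))
#' co$manifest
simulate_cohort <- function(config, apply_missingness = TRUE,
                            monitoring_start = as.Date("2024-03-01")) {
  stopifnot(inherits(config, "sim_config"))
  plan <- cohort_plan(config, monitoring_start)
  pats <- pmap(plan, function(index, patient_id, arm, has_event,
                              monitoring_start) {
    simulate_patient(config, index, arm, has_event, patient_id,
                     monitoring_start)
  })
  cohort <- structure(list(
    oximetry = map_dfr(pats, "oximetry"),
    diary = map_dfr(pats, "diary"),
    manifest = map_dfr(pats, "manifest"),
    truth = map_dfr(pats, "truth")
  ), class = "copd_cohort")
  if (apply_missingness) {
    cohort <- inject_missingness(cohort, config, patient_index = plan$index)
  }
  cohort
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("<copd_cohort> %d patients (%d overnight), %d with events\n",
              nrow(x$manifest), sum(x$manifest$arm == "overnight"),
              sum(!is.na(x$manifest$treatment_day))))
  cat(sprintf("  %s oximetry samples, %d diary days\n",
              format(nrow(x$oximetry), big.mark = ","), nrow(x$diary)))
  invisible(x)
}

#' Inject day-level missingness into a simulated cohort
#'
#' Each monitored day is independently dropped with probability
#' `missing_day_prob` (all of that day's oximetry samples and the diary
#' entry). For event patients, with probability `consecutive_miss_prob` an
#' additional run of 2 consecutive days inside the pre-exacerbation window
#' (days -14..-2 relative to treatment) is dropped, so the analysis
#' exclusion rule for consecutive missing data is exercisable. Deterministic
#' given the config seed: each patient uses a dedicated child stream.
#'
#' @param cohort a `copd_cohort`.
#' @param config the [sim_config()] used to generate it.
#' @param patient_index integer index per manifest row used to derive the
#'   per-patient seed stream; defaults to manifest row order.
#' @return the cohort with dropped days removed.
#' @export
inject_missingness <- function(cohort, config, patient_index = NULL) {
  stopifnot(inherits(cohort, "copd_cohort"), inherits(config, "sim_config"))
  man <- cohort$manifest
  if (nrow(man) == 0 ||
      (config$missing_day_prob == 0 && config$consecutive_miss_prob == 0)) {
    return(cohort)
  }
  patient_index <- patient_index %||% seq_len(nrow(man))

  dropped <- pmap(list(man$patient_id, man$monitoring_start,
                       man$treatment_day, patient_index),
                  function(pid, start, tday, idx) {
    set.seed(child_seed(config$seed, idx, 2L))
    dates <- start + seq_len(config$total_days) - 1L
    drop <- dates[runif(config$total_days) < config$missing_day_prob]
    if (!is.na(tday) && runif(1) < config$consecutive_miss_prob) {
      run_start <- tday + sample(-14:-2, 1)
      drop <- c(drop, run_start, run_start + 1L)
    }
    if (length(drop)) tibble(patient_id = pid, date = unique(drop)) else NULL
  })
  dropped <- bind_rows(dropped)
  if (nrow(dropped) == 0) return(cohort)

  key <- paste(dropped$patient_id, dropped$date)
  ox_key <- paste(cohort$oximetry$patient_id,
                  sample_date(cohort$oximetry$timestamp))
  cohort$oximetry <- cohort$oximetry[!ox_key %in% key, ]
  di_key <- paste(cohort$diary$patient_id, cohort$diary$date)
  cohort$diary <- cohort$diary[!di_key %in% key, ]
  cohort
}

#' Simulate a cohort and reduce it to daily series, patient by patient
#'
#' Memory-lean driver for large simulations: each patient's raw record is
#' generated, missingness applied, and the record immediately aggregated to
#' one-value-per-day series via [build_daily_series()]; raw oximetry streams
#' are retained only for the requested patients.
#'
#' @inheritParams simulate_cohort
#' @param keep_raw_ids patient ids whose raw oximetry stream should be
#'   returned alongside the daily series.
#' @param nightly_statistic `"mean"` (default) or `"median"` nightly summary.
#' @return list with `daily` (see [build_daily_series()]), `manifest`,
#'   `truth`, `oximetry` (subset), `diary` (all patients).
#' @export
simulate_daily_cohort <- function(config, keep_raw_ids = character(),
                                  apply_missingness = TRUE,
                                  nightly_statistic = "mean",
                                  monitoring_start = as.Date("2024-03-01")) {
  stopifnot(inherits(config, "sim_config"))
  plan <- cohort_plan(config, monitoring_start)
  out <- pmap(plan, function(index, patient_id, arm, has_event,
                             monitoring_start) {
    p <- simulate_patient(config, index, arm, has_event, patient_id,
                          monitoring_start)
    one <- structure(list(oximetry = p$oximetry, diary = p$diary,
                          manifest = p$manifest, truth = p$truth),
                     class = "copd_cohort")
    if (apply_missingness) {
      one <- inject_missingness(one, config, patient_index = index)
    }
    daily <- build_daily_series(one$oximetry, one$diary, one$manifest,
                                nightly_statistic = nightly_statistic)
    list(daily = daily, manifest = one$manifest, truth = one$truth,
         diary = one$diary,
         oximetry = if (patient_id %in% keep_raw_ids) one$oximetry else NULL)
  })
  list(daily = map_dfr(out, "daily"),
       manifest = map_dfr(out, "manifest"),
       truth = map_dfr(out, "truth"),
       diary = map_dfr(out, "diary"),
       oximetry = map_dfr(out, "oximetry"))
}
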