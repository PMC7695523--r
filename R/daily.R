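#' Aggregate oximetry streams to one value per night
#'
#' Groups each patient's samples into recording sessions (a gap of more
#' than an hour starts a new session), attributes each session to the
#' waking morning's date — the date of the final sample, with dates rolling
#' at noon so a recording that starts in the evening belongs to the
#' following morning — and summarises
#' valid samples with the arithmetic mean (or median). Invalid-flagged
#' samples (see [read_oximetry()]) are excluded; a session with no valid
#' samples yields a missing night (`NA` values, `n_valid = 0`). Once-daily
#' spot readings pass through unchanged as single-sample sessions.
#'
#' @param oximetry tibble with `patient_id`, `timestamp`, `heart_rate`,
#'   `spo2` and optionally `valid` (computed if absent).
#' @param statistic `"mean"` (default) or `"median"` nightly summary.
#' @return tibble with `patient_id`, `date`, `hr`, `spo2`, `n_valid`.
#' @export
#' @examples
#' ox <- tibble::tibble(
#'   patient_id = "P1",
#'   timestamp = as.POSIXct("2024-03-02 05:00:00", tz = "UTC") + c(0, 4, 8),
#'   heart_rate = c(68, 70, 72), spo2 = c(91, 92, 93))
#' aggregate_nights(ox)
aggregate_nights <- function(oximetry, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (!"valid" %in% names(oximetry)) {
    oximetry <- flag_valid_samples(oximetry)
  }
  if (nrow(oximetry) == 0) {
    return(tibble(patient_id = character(), date = as.Date(character()),
                  hr = numeric(), spo2 = numeric(), n_valid = integer()))
  }
  ord <- order(oximetry$patient_id, oximetry$timestamp)
  pid <- oximetry$patient_id[ord]
  ts <- as.numeric(oximetry$timestamp[ord])
  hr <- oximetry$heart_rate[ord]
  sp <- oximetry$spo2[ord]
  ok <- oximetry$valid[ord]

  n <- length(pid)
  new_session <- c(TRUE, pid[-1] != pid[-n] | (ts[-1] - ts[-n]) > 3600)
  session <- cumsum(new_session)
  last <- c(which(new_session[-1]), n)  # index of each session's final sample

  agg <- function(x) {
    x_ok <- ifelse(ok, x, NA_real_)
    if (statistic == "mean") {
      sums <- rowsum(ifelse(ok, x, 0), session, reorder = FALSE)[, 1]
      cnt <- rowsum(as.numeric(ok), session, reorder = FALSE)[, 1]
      unname(ifelse(cnt > 0, sums / cnt, NA_real_))
    } else {
      unname(as.numeric(tapply(x_ok, session, median, na.rm = TRUE)))
    }
  }
  n_valid <- unname(as.integer(
    rowsum(as.numeric(ok), session, reorder = FALSE)[, 1]))
  out <- tibble(
    patient_id = pid[last],
    date = sample_date(as.POSIXct(ts[last], origin = "1970-01-01",
                                  tz = "UTC")),
    hr = agg(hr), spo2 = agg(sp), n_valid = n_valid
  )
  out$hr[is.nan(out$hr)] <- NA_real_
  out$spo2[is.nan(out$spo2)] <- NA_real_
  out
}

#' Build QC'd one-value-per-day series for every patient
#'
#' Combines nightly (or spot) oximetry aggregates with the daily diary into
#' a long per-day table and removes each patient's run-in period (the first
#' `run_in_days` monitored days, excluded from all analysis while patients
#' learn the equipment). Days without data are simply absent; gaps
#' propagate as missing days.
#'
#' @param oximetry see [aggregate_nights()].
#' @param diary tibble with `patient_id`, `date`, `cat`, `pef`.
#' @param manifest tibble with `patient_id` and optionally
#'   `monitoring_start`; when absent, the first observed date per patient
#'   is used as the monitoring start.
#' @param nightly_statistic `"mean"` or `"median"`.
#' @param run_in_days days removed from the start of monitoring (default 7).
#' @return tibble with `patient_id`, `date`, `variable` (HR, SpO2, CAT,
#'   PEF), `value`, `n_samples` (raw samples contributing).
#' @export
build_daily_series <- function(oximetry, diary, manifest,
                               nightly_statistic = "mean",
                               run_in_days = 7L) {
  nights <- aggregate_nights(oximetry, statistic = nightly_statistic)
  long_ox <- nights |>
    filter(.data$n_valid > 0) |>
    tidyr::pivot_longer(c("hr", "spo2"), names_to = "variable",
                        values_to = "value") |>
    mutate(variable = ifelse(.data$variable == "hr", "HR", "SpO2"),
           n_samples = .data$n_valid) |>
    select("patient_id", "date", "variable", "value", "n_samples") |>
    filter(!is.na(.data$value))
  long_diary <- diary |>
    tidyr::pivot_longer(c("cat", "pef"), names_to = "variable",
                        values_to = "value") |>
    mutate(variable = ifelse(.data$variable == "cat", "CAT", "PEF"),
           n_samples = 1L) |>
    select("patient_id", "date", "variable", "value", "n_samples") |>
    filter(!is.na(.data$value))
  daily <- bind_rows(long_ox, long_diary)

  if (!is.null(manifest$monitoring_start)) {
    starts <- select(manifest, "patient_id", "monitoring_start")
  } else {
    starts <- daily |>
      summarise(monitoring_start = min(.data$date), .by = "patient_id")
  }
  daily |>
    inner_join(starts, by = "patient_id") |>
    filter(.data$date >= .data$monitoring_start + run_in_days) |>
    select(-"monitoring_start") |>
    mutate(variable = factor(.data$variable, levels = VARIABLES)) |>
    arrange(.data$patient_id, .data$variable, .data$date) |>
    mutate(variable = as.character(.data$variable))
}

# last calendar date of a patient's stable period: the day before the
# pre-exacerbation window opens, or the end of follow-up without an event
stable_period_end <- function(treatment_day, last_date) {
  if_else(is.na(treatment_day), last_date, treatment_day - 15L)
}

#' Apply the stable-data and consecutive-missing exclusion rules
#'
#' A patient is eligible when (a) every variable has at least
#' `min_stable_days` non-missing days during the stable state (after
#' run-in, before the 14-day pre-exacerbation window), and (b) for event
#' patients, no variable has a run of 2 or more consecutive missing days
#' during the pre-exacerbation window (days -14..-1).
#'
#' @param daily output of [build_daily_series()].
#' @param manifest tibble with `patient_id`, `treatment_day`.
#' @param min_stable_days required non-missing stable days (default 14).
#' @return tibble with `patient_id`, `eligible`, and a `reasons` list
#'   column drawing from `"insufficient_stable_data"` and
#'   `"consecutive_missing_preexacerbation"`; `eligible` is `TRUE` iff
#'   `reasons` is empty.
#' @export
check_eligibility <- function(daily, manifest, min_stable_days = 14L) {
  by_patient <- split(daily, daily$patient_id)
  res <- map(seq_len(nrow(manifest)), function(i) {
    pid <- manifest$patient_id[i]
    tday <- manifest$treatment_day[i]
    d <- by_patient[[pid]]
    reasons <- character()
    if (is.null(d) || nrow(d) == 0) {
      reasons <- "insufficient_stable_data"
    } else {
      send <- stable_period_end(tday, max(d$date))
      n_stable <- map_dbl(VARIABLES, function(v) {
        sum(d$variable == v & d$date <= send & is.finite(d$value))
      })
      if (any(n_stable < min_stable_days)) {
        reasons <- c(reasons, "insufficient_stable_data")
      }
      if (!is.na(tday)) {
        window <- seq(tday - 14L, tday - 1L, by = "day")
        gap <- any(map_lgl(VARIABLES, function(v) {
          present <- window %in% d$date[d$variable == v & is.finite(d$value)]
          has_consecutive_run(!present, 2L)
        }))
        if (gap) reasons <- c(reasons, "consecutive_missing_preexacerbation")
      }
    }
    tibble(patient_id = pid, eligible = length(reasons) == 0,
           reasons = list(reasons))
  })
  bind_rows(res)
}

# TRUE when `flags` contains a run of at least `k` consecutive TRUEs
has_consecutive_run <- function(flags, k) {
  if (!any(flags)) return(FALSE)
  r <- rle(flags)
  any(r$values & r$lengths >= k)
}

#' Select each patient's baseline (stable-state) window
#'
#' Picks, per patient, the first `n_days` stable-period days on which all
#' four variables are present, so baseline statistics can always be
#' computed on complete data. Call with `exclude =` a previous window to
#' obtain the *second* stable window used for the false-positive
#' (specificity) analysis. Patients without enough complete stable days are
#' omitted from the result.
#'
#' @param daily output of [build_daily_series()].
#' @param manifest tibble with `patient_id`, `treatment_day`.
#' @param n_days window length (default 14).
#' @param exclude optional tibble (`patient_id`, `date`) of days already
#'   spoken for, e.g. the baseline window.
#' @return tibble with `patient_id`, `date` (`n_days` rows per retained
#'   patient).
#' @export
select_stable_window <- function(daily, manifest, n_days = 14L,
                                 exclude = NULL) {
  last_dates <- daily |> summarise(last = max(.data$date), .by = "patient_id")
  ends <- manifest |>
    inner_join(last_dates, by = "patient_id") |>
    mutate(stable_end = stable_period_end(.data$treatment_day, .data$last)) |>
    select("patient_id", "stable_end")
  complete_days <- daily |>
    filter(is.finite(.data$value)) |>
    distinct(.data$patient_id, .data$date, .data$variable) |>
    count(.data$patient_id, .data$date) |>
    filter(.data$n == length(VARIABLES)) |>
    inner_join(ends, by = "patient_id") |>
    filter(.data$date <= .data$stable_end)
  if (!is.null(exclude)) {
    complete_days <- anti_join(complete_days, exclude,
                               by = c("patient_id", "date"))
  }
  complete_days |>
    arrange(.data$patient_id, .data$date) |>
    slice_head(n = n_days, by = "patient_id") |>
    filter(n() == n_days, .by = "patient_id") |>
    select("patient_id", "date")
}

#' Align daily series to the exacerbation treatment day
#'
#' Maps calendar dates to day indices -14..+13 with day 0 the treatment
#' start, for every event patient. (Day -15 is reserved downstream for the
#' stable-period mean and is not a data day.)
#'
#' @param daily output of [build_daily_series()].
#' @param manifest tibble with `patient_id`, `treatment_day`; at least one
#'   patient must have a treatment day.
#' @return tibble with `patient_id`, `variable`, `day_index`, `date`,
#'   `value`.
#' @export
align_to_event <- function(daily, manifest) {
  events <- filter(manifest, !is.na(.data$treatment_day))
  if (nrow(events) == 0) {
    abort("align_to_event: no patient in the manifest has a treatment day",
          class = "oxicopd_no_event_error")
  }
  daily |>
    inner_join(select(events, "patient_id", "treatment_day"),
               by = "patient_id") |>
    mutate(day_index = as.integer(.data$date - .data$treatment_day)) |>
    filter(.data$day_index >= DAY_MIN, .data$day_index <= DAY_MAX) |>
    select("patient_id", "variable", "day_index", "date", "value") |>
    arrange(.data$patient_id, .data$variable, .data$day_index)
}
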