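#' Threshold-crossing detection on Z-score series
#'
#' A day is abnormal when its Z score lies outside the 95% band of the
#' baseline mean: `|Z| >= threshold` (two-sided, the stated significance
#' rule) or, with `direction = "directional"`, only crossings in the
#' variable's physiological direction (HR, CAT and the composite upward;
#' SpO2 and PEF downward). `consecutive_days_required` (k) optionally
#' demands a run of k consecutive abnormal days before a crossing counts,
#' a false-alarm control; `abnormal_days` always lists every crossing day,
#' while `first_abnormal_day` and `flagged` honour k.
#'
#' The day -15 display slot is excluded. `first_abnormal_day` is the
#' earliest qualifying day inside `pre_window` (days -14..0 by default,
#' i.e. the two weeks before treatment with the treatment day included);
#' `flagged` records whether any qualifying day falls in that window.
#'
#' @param z output of [zseries()] (or any tibble with `patient_id`,
#'   `variable`, `day_index`, `z`).
#' @param threshold crossing threshold in baseline-SD units (default 1.96).
#' @param direction `"two_sided"` (default) or `"directional"`.
#' @param consecutive_days_required minimum run length k (default 1).
#' @param pre_window integer range (low, high) of the pre-exacerbation
#'   detection window (default `c(-14, 0)`).
#' @return tibble of class `copd_detections` with `patient_id`,
#'   `variable`, `abnormal_days` (list column), `n_abnormal`,
#'   `first_abnormal_day` (NA when the variable never qualifies in the
#'   window), `flagged`.
#' @export
detect_abnormal_days <- function(z, threshold = 1.96,
                                 direction = c("two_sided", "directional"),
                                 consecutive_days_required = 1L,
                                 pre_window = c(-14L, 0L)) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0, consecutive_days_required >= 1,
            length(pre_window) == 2, pre_window[1] <= pre_window[2])
  k <- as.integer(consecutive_days_required)
  out <- z |>
    filter(.data$day_index >= DAY_MIN, !is.na(.data$z)) |>
    arrange(.data$patient_id, .data$variable, .data$day_index) |>
    summarise(
      res = {
        ab <- is_abnormal(.data$z, .data$variable[1], threshold, direction)
        days <- .data$day_index[ab]
        qual <- qualifying_days(days, k)
        in_win <- qual[qual >= pre_window[1] & qual <= pre_window[2]]
        list(list(days = days,
                  first = if (length(in_win)) min(in_win) else NA_integer_,
                  flagged = length(in_win) > 0))
      },
      .by = c("patient_id", "variable")
    )
  tibble(
    patient_id = out$patient_id,
    variable = out$variable,
    abnormal_days = map(out$res, "days"),
    n_abnormal = lengths(map(out$res, "days")),
    first_abnormal_day = map_int(out$res, "first"),
    flagged = map_lgl(out$res, "flagged")
  ) |>
    structure(class = c("copd_detections", class(tibble())))
}

is_abnormal <- function(z, variable, threshold, direction) {
  if (direction == "two_sided") {
    abs(z) >= threshold
  } else {
    VARIABLE_SIGN[[variable]] * z >= threshold
  }
}

# subset of sorted abnormal day indices that belong to a run of at least k
# consecutive calendar days
qualifying_days <- function(days, k) {
  if (k <= 1L || length(days) == 0) return(days)
  grp <- cumsum(c(1L, diff(days) != 1L))
  keep <- ave(grp, grp, FUN = length) >= k
  days[keep]
}

#' Per-patient crossing flags over an arbitrary scored window
#'
#' Applies the same crossing rule as [detect_abnormal_days()] to Z scores
#' of any window (e.g. the second stable window) and reports, per patient
#' and variable, whether the threshold was crossed at some point.
#'
#' @param z_window output of [window_zscores()].
#' @inheritParams detect_abnormal_days
#' @return tibble with `patient_id`, `variable`, `flagged`.
#' @export
crossing_flags <- function(z_window, threshold = 1.96,
                           direction = c("two_sided", "directional"),
                           consecutive_days_required = 1L) {
  direction <- match.arg(direction)
  k <- as.integer(consecutive_days_required)
  z_window |>
    filter(!is.na(.data$z)) |>
    arrange(.data$patient_id, .data$variable, .data$day_index) |>
    summarise(
      flagged = {
        ab <- is_abnormal(.data$z, .data$variable[1], threshold, direction)
        length(qualifying_days(.data$day_index[ab], k)) > 0
      },
      .by = c("patient_id", "variable")
    )
}

#' Time from first abnormality to treatment
#'
#' The lead time is the number of days between a variable's first
#' qualifying crossing in the pre-exacerbation window and treatment start:
#' `0 - first_abnormal_day`. Patients whose variable never crossed in the
#' window are censored (`NA` lead time) and are reported as counts, not
#' included in medians.
#'
#' @param detections output of [detect_abnormal_days()] for event patients.
#' @return the input with `lead_time_days` and `censored` columns added.
#' @export
time_to_treatment <- function(detections) {
  detections |>
    mutate(lead_time_days = if_else(is.na(.data$first_abnormal_day),
                                    NA_integer_,
                                    0L - .data$first_abnormal_day),
           censored = is.na(.data$first_abnormal_day))
}

# SPSS-convention quantiles (type 6), matching the reporting style of the
# monitoring study this package models
iqr_quantile <- function(x, p) {
  as.numeric(quantile(x, p, type = 6, names = FALSE))
}

#' Summarise lead times by arm and variable
#'
#' Medians and IQRs (quantile type 6, the SPSS convention) of uncensored
#' lead times per monitoring arm and variable, with two families of
#' rank-based comparisons: within each arm, symptoms (CAT) versus each
#' physiological variable, paired within patients; and for each variable,
#' once-daily versus overnight arm (unpaired). Censored patients are
#' counted separately and excluded from summaries and tests.
#'
#' @param lead_times output of [time_to_treatment()].
#' @param manifest tibble with `patient_id`, `arm`.
#' @return object of class `copd_lead_times`: a list with tibbles
#'   `summary`, `paired_tests` (CAT vs variable within arm),
#'   `arm_comparisons` (once-daily vs overnight per variable).
#' @export
summarize_lead_times <- function(lead_times, manifest) {
  lt <- inner_join(lead_times, select(manifest, "patient_id", "arm"),
                   by = "patient_id")
  summary <- lt |>
    summarise(
      n = dplyr::n(),
      n_censored = sum(.data$censored),
      median = if (any(!.data$censored)) {
        median(.data$lead_time_days[!.data$censored])
      } else NA_real_,
      q1 = if (any(!.data$censored)) {
        iqr_quantile(.data$lead_time_days[!.data$censored], 0.25)
      } else NA_real_,
      q3 = if (any(!.data$censored)) {
        iqr_quantile(.data$lead_time_days[!.data$censored], 0.75)
      } else NA_real_,
      .by = c("arm", "variable")
    ) |>
    arrange(.data$arm, factor(.data$variable, levels = VARIABLES_Z))

  wide <- lt |>
    select("patient_id", "arm", "variable", "lead_time_days") |>
    tidyr::pivot_wider(names_from = "variable",
                       values_from = "lead_time_days")
  paired_tests <- map_dfr(unique(lt$arm), function(a) {
    w <- filter(wide, .data$arm == a)
    if (!"CAT" %in% names(w)) return(tibble())
    map_dfr(setdiff(intersect(VARIABLES_Z, names(w)), "CAT"), function(v) {
      ok <- !is.na(w$CAT) & !is.na(w[[v]])
      p <- if (sum(ok) >= 2) {
        safe_p(wilcox.test(w$CAT[ok], w[[v]][ok], paired = TRUE,
                           exact = FALSE))
      } else NA_real_
      tibble(arm = a, comparison = sprintf("CAT vs %s", v),
             n_pairs = sum(ok), p_value = p)
    })
  })
  arm_comparisons <- map_dfr(unique(lt$variable), function(v) {
    x <- lt$lead_time_days[lt$variable == v & lt$arm == "once_daily" &
                             !lt$censored]
    y <- lt$lead_time_days[lt$variable == v & lt$arm == "overnight" &
                             !lt$censored]
    p <- if (length(x) >= 1 && length(y) >= 1 && length(c(x, y)) >= 3) {
      safe_p(wilcox.test(x, y, exact = FALSE))
    } else NA_real_
    tibble(variable = v, n_once_daily = length(x),
           n_overnight = length(y), p_value = p)
  })
  structure(list(summary = summary, paired_tests = paired_tests,
                 arm_comparisons = arm_comparisons),
            class = "copd_lead_times")
}

safe_p <- function(test) {
  tryCatch(suppressWarnings(test$p.value), error = function(e) NA_real_)
}

#' @export
print.copd_lead_times <- function(x, ...) {
  cat("<copd_lead_times>\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %-9s %s days (IQR %s-%s), %d/%d censored\n",
                s$arm[i], s$variable[i],
                format(s$median[i]), format(s$q1[i]), format(s$q3[i]),
                s$n_censored[i], s$n[i]))
  }
  invisible(x)
}

#' @export
tidy.copd_lead_times <- function(x, ...) x$summary

#' @export
glance.copd_lead_times <- function(x, ...) {
  x$arm_comparisons |>
    select("variable", "p_value") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "p_value",
                       names_prefix = "p_arm_")
}

#' Event-level detection performance
#'
#' Builds the 2x2 event-level table: true positives are exacerbation
#' patients whose score crossed the threshold at some point during the
#' pre-exacerbation window; false positives are patients whose score
#' crossed during a separate 2-week stable window. Sensitivity, specificity
#' and positive predictive value follow the standard definitions
#' `tp/(tp+fn)`, `tn/(tn+fp)`, `tp/(tp+fp)`; an empty denominator yields
#' `NA` (reported as undefined rather than 0).
#'
#' @param event_flags logical vector (or tibble with `patient_id`,
#'   `flagged`) over exacerbation patients: crossed in the pre-event
#'   window?
#' @param stable_flags logical vector (or tibble) over patients observed in
#'   the second stable window: crossed there?
#' @return one-row tibble of class `copd_performance` with `tp`, `fn`,
#'   `fp`, `tn`, `sensitivity`, `specificity`, `ppv`.
#' @export
#' @examples
#' event_performance(rep(c(TRUE, FALSE), c(11, 2)),
#'                   rep(c(TRUE, FALSE), c(3, 8)))
event_performance <- function(event_flags, stable_flags) {
  event_flags <- extract_flags(event_flags, "event_flags")
  stable_flags <- extract_flags(stable_flags, "stable_flags")
  if (length(event_flags) == 0 && length(stable_flags) == 0) {
    abort("event_performance: no patients in either window",
          class = "oxicopd_empty_error")
  }
  tp <- sum(event_flags); fn <- sum(!event_flags)
  fp <- sum(stable_flags); tn <- sum(!stable_flags)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    tibble(tp = tp, fn = fn, fp = fp, tn = tn,
           sensitivity = ratio(tp, tp + fn),
           specificity = ratio(tn, tn + fp),
           ppv = ratio(tp, tp + fp)),
    class = c("copd_performance", class(tibble()))
  )
}

extract_flags <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"flagged" %in% names(x)) {
      abort(sprintf("%s must have a `flagged` column", what),
            class = "oxicopd_format_error")
    }
    x <- x$flagged
  }
  as.logical(x[!is.na(x)])
}

#' @export
tidy.copd_performance <- function(x, ...) {
  tibble(metric = c("sensitivity", "specificity", "ppv"),
         estimate = c(x$sensitivity, x$specificity, x$ppv),
         numerator = c(x$tp, x$tn, x$tp),
         denominator = c(x$tp + x$fn, x$tn + x$fp, x$tp + x$fp))
}

#' @export
glance.copd_performance <- function(x, ...) as_tibble(unclass(x))
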