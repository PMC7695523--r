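# brute-force oracle: scan a z table day by day
brute_detect <- function(z, threshold = 1.96, direction = "two_sided",
                         pre_window = c(-14, 0)) {
  sign_of <- c(HR = 1, SpO2 = -1, CAT = 1, PEF = -1, COMPOSITE = 1)
  out <- list()
  for (pid in unique(z$patient_id)) {
    for (v in unique(z$variable[z$patient_id == pid])) {
      d <- z[z$patient_id == pid & z$variable == v & z$day_index >= -14 &
               !is.na(z$z), ]
      d <- d[order(d$day_index), ]
      days <- integer()
      for (i in seq_len(nrow(d))) {
        hit <- if (direction == "two_sided") abs(d$z[i]) >= threshold
               else sign_of[[v]] * d$z[i] >= threshold
        if (hit) days <- c(days, d$day_index[i])
      }
      win <- days[days >= pre_window[1] & days <= pre_window[2]]
      out[[paste(pid, v)]] <- list(
        patient_id = pid, variable = v, days = days,
        first = if (length(win)) min(win) else NA_integer_)
    }
  }
  out
}

random_z <- function(seed) {
  set.seed(seed)
  tidyr::expand_grid(patient_id = c("P1", "P2", "P3"),
                     variable = c("HR", "SpO2", "CAT", "PEF", "COMPOSITE"),
                     day_index = -15:13) |>
    dplyr::mutate(z = ifelse(day_index == -15, 0, rnorm(dplyr::n(), 0, 1.4)))
}

test_that("threshold crossing agrees with a brute-force scan", {
  for (seed in 1:5) {
    z <- random_z(seed)
    for (dir in c("two_sided", "directional")) {
      det <- detect_abnormal_days(z, direction = dir)
      oracle <- brute_detect(z, direction = dir)
      for (i in seq_len(nrow(det))) {
        o <- oracle[[paste(det$patient_id[i], det$variable[i])]]
        expect_equal(det$abnormal_days[[i]], o$days)
        expect_equal(det$first_abnormal_day[i], o$first)
      }
    }
  }
})

test_that("worked crossing patterns give the expected first abnormal day", {
  z <- tibble::tibble(patient_id = "P1", variable = "CAT",
                      day_index = -15:13,
                      z = c(0, rep(0.5, 9), rep(2.5, 19)))
  det <- detect_abnormal_days(z)
  expect_equal(det$first_abnormal_day, -5L)  # abnormal from -5 onwards
  expect_equal(det$abnormal_days[[1]], -5:13)

  zc <- tibble::tibble(patient_id = "P1", variable = "COMPOSITE",
                       day_index = -15:13,
                       z = ifelse(-15:13 %in% -7:0, 2.2, 0.3))
  detc <- detect_abnormal_days(zc)
  expect_true(all(-7:0 %in% detc$abnormal_days[[1]]))
  expect_equal(detc$first_abnormal_day, -7L)

  quiet <- tibble::tibble(patient_id = "P1", variable = "HR",
                          day_index = -15:13, z = 0.9)
  detq <- detect_abnormal_days(quiet)
  expect_equal(detq$n_abnormal, 0L)
  expect_true(is.na(detq$first_abnormal_day))
  expect_false(detq$flagged)
})

test_that("directional crossings follow each variable's physiology", {
  z <- tibble::tibble(patient_id = "P1",
                      variable = rep(c("SpO2", "HR"), each = 2),
                      day_index = c(-5L, -4L, -5L, -4L),
                      z = c(-2.5, 2.5, -2.5, 2.5))
  det <- detect_abnormal_days(z, direction = "directional")
  expect_equal(det$abnormal_days[[which(det$variable == "SpO2")]], -5L)
  expect_equal(det$abnormal_days[[which(det$variable == "HR")]], -4L)
  det2 <- detect_abnormal_days(z, direction = "two_sided")
  expect_equal(det2$n_abnormal, c(2L, 2L))
})

test_that("a consecutive-days requirement suppresses isolated crossings", {
  z <- tibble::tibble(patient_id = "P1", variable = "COMPOSITE",
                      day_index = -14:0,
                      z = ifelse(-14:0 %in% c(-12, -5, -4), 2.5, 0))
  det1 <- detect_abnormal_days(z, consecutive_days_required = 1)
  expect_equal(det1$first_abnormal_day, -12L)
  det2 <- detect_abnormal_days(z, consecutive_days_required = 2)
  expect_equal(det2$first_abnormal_day, -5L)  # only the -5,-4 run qualifies
  expect_equal(det2$abnormal_days[[1]], c(-12L, -5L, -4L))  # days still listed
  det3 <- detect_abnormal_days(z, consecutive_days_required = 3)
  expect_true(is.na(det3$first_abnormal_day))
  expect_false(det3$flagged)
})

test_that("lead times count days from first abnormality to treatment", {
  det <- tibble::tibble(patient_id = c("P1", "P2", "P3"), variable = "CAT",
                        abnormal_days = list(-5L, 0L, integer()),
                        n_abnormal = c(1L, 1L, 0L),
                        first_abnormal_day = c(-5L, 0L, NA),
                        flagged = c(TRUE, TRUE, FALSE))
  lt <- time_to_treatment(det)
  expect_equal(lt$lead_time_days, c(5L, 0L, NA))
  expect_equal(lt$censored, c(FALSE, FALSE, TRUE))
})

test_that("lead-time summaries report SPSS-convention medians and IQRs", {
  man <- tibble::tibble(patient_id = sprintf("P%d", 1:6),
                        arm = rep(c("once_daily", "overnight"), each = 3))
  lt <- tibble::tibble(
    patient_id = rep(sprintf("P%d", 1:6), each = 2),
    variable = rep(c("CAT", "COMPOSITE"), 6),
    first_abnormal_day = NA_integer_,
    lead_time_days = as.integer(c(5, 0, 5, 2, 5, 10,   # once-daily
                                  5, 0, 5, 2, 5, 10)), # overnight
    censored = FALSE)
  s <- summarize_lead_times(lt, man)
  cat_od <- s$summary[s$summary$arm == "once_daily" &
                        s$summary$variable == "CAT", ]
  expect_equal(cat_od$median, 5)
  expect_equal(c(cat_od$q1, cat_od$q3), c(5, 5))
  comp_od <- s$summary[s$summary$arm == "once_daily" &
                         s$summary$variable == "COMPOSITE", ]
  expect_equal(comp_od$median, 2)
  expect_equal(c(comp_od$q1, comp_od$q3), c(0, 10))  # type-6 quantiles
  # identical arms: between-arm comparison finds nothing
  p_arm <- s$arm_comparisons$p_value
  expect_true(all(p_arm[!is.na(p_arm)] > 0.99))
  expect_equal(tidy(s), s$summary)
})

test_that("censored lead times are excluded from summaries but counted", {
  man <- tibble::tibble(patient_id = c("P1", "P2"), arm = "overnight")
  lt <- tibble::tibble(patient_id = c("P1", "P2"), variable = "SpO2",
                       first_abnormal_day = c(-3L, NA),
                       lead_time_days = c(3L, NA),
                       censored = c(FALSE, TRUE))
  s <- summarize_lead_times(lt, man)
  expect_equal(s$summary$n_censored, 1L)
  expect_equal(s$summary$median, 3)
  # all censored: undefined, reported as such
  lt$censored <- TRUE; lt$lead_time_days <- NA_integer_
  s2 <- summarize_lead_times(lt, man)
  expect_true(is.na(s2$summary$median))
})

test_that("event-level performance follows the standard 2x2 definitions", {
  perf <- event_performance(rep(c(TRUE, FALSE), c(11, 2)),
                            rep(c(TRUE, FALSE), c(3, 8)))
  expect_equal(perf$tp, 11); expect_equal(perf$fn, 2)
  expect_equal(perf$fp, 3); expect_equal(perf$tn, 8)
  expect_equal(perf$sensitivity, 11 / 13)
  expect_equal(perf$specificity, 8 / 11)
  expect_equal(perf$ppv, 11 / 14)
  # complements: fn and fp rates
  expect_equal(perf$sensitivity + perf$fn / (perf$tp + perf$fn), 1)
  expect_equal(perf$specificity + perf$fp / (perf$tn + perf$fp), 1)

  # no positives at all: PPV undefined, not zero
  p0 <- event_performance(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(p0$ppv))
  expect_equal(p0$specificity, 1)

  expect_error(event_performance(logical(), logical()),
               class = "oxicopd_empty_error")

  td <- tidy(perf)
  expect_equal(td$estimate[td$metric == "ppv"], 11 / 14)
})

test_that("phase comparisons: identical values give no evidence", {
  aligned <- tidyr::expand_grid(patient_id = c("P1", "P2"),
                                day_index = -14:13) |>
    dplyr::mutate(variable = "CAT", value = 16,
                  date = as.Date("2024-04-01") + day_index)
  stable <- tibble::tibble(patient_id = rep(c("P1", "P2"), each = 14),
                           variable = "CAT", value = 16)
  ph <- phase_summaries(aligned, stable, "CAT")
  expect_equal(ph$omnibus$p_value, 1)
  expect_equal(ph$omnibus$statistic, 0)
  expect_equal(unique(ph$summary$mean), 16)
})

test_that("phase comparisons detect the configured symptom effect sizes", {
  set.seed(21)
  pats <- sprintf("P%02d", 1:15)
  aligned <- tidyr::expand_grid(patient_id = pats, day_index = -14:13) |>
    dplyr::mutate(
      variable = "CAT",
      date = as.Date("2024-04-01") + day_index,
      value = dplyr::case_when(
        day_index <= -1 ~ rnorm(dplyr::n(), 17.4, 2.34),
        day_index == 0 ~ rnorm(dplyr::n(), 19.7, 2.0),
        TRUE ~ rnorm(dplyr::n(), 19.7, 2.0)))
  stable <- tidyr::expand_grid(patient_id = pats, day = 1:14) |>
    dplyr::mutate(variable = "CAT", value = rnorm(dplyr::n(), 15.6, 1.46))
  ph <- phase_summaries(aligned, stable, "CAT")
  expect_lt(ph$omnibus$p_value, 0.001)
  means <- setNames(ph$summary$mean, as.character(ph$summary$phase))
  expect_true(means["stable"] < means["pre"] && means["pre"] < means["post"])
  # variability rose before the exacerbation (SD 2.34 vs 1.46)
  expect_lt(ph$variance_test$p_value, 0.01)
  expect_gt(ph$variance_test$sd_pre, ph$variance_test$sd_stable)
  g <- glance(ph)
  expect_equal(g$p_value, ph$omnibus$p_value)
})

test_that("a pure variability change moves the variance test, not the means", {
  set.seed(22)
  pats <- sprintf("P%02d", 1:15)
  aligned <- tidyr::expand_grid(patient_id = pats, day_index = -14:-1) |>
    dplyr::mutate(variable = "PEF",
                  date = as.Date("2024-04-01") + day_index,
                  value = rnorm(dplyr::n(), 214, 28))
  stable <- tidyr::expand_grid(patient_id = pats, day = 1:14) |>
    dplyr::mutate(variable = "PEF", value = rnorm(dplyr::n(), 214, 14))
  ph <- phase_summaries(aligned, stable, "PEF")
  expect_gt(ph$omnibus$p_value, 0.05)
  expect_lt(ph$variance_test$p_value, 0.001)
})

test_that("group trajectories average available patients per day", {
  z1 <- tibble::tibble(patient_id = "P1", variable = "HR",
                       day_index = c(-15L, -1L, 0L), z = c(0, 1, 2))
  tr1 <- group_z_trajectory(z1)
  expect_equal(tr1$mean_z, z1$z)
  z2 <- dplyr::bind_rows(z1, dplyr::mutate(z1, patient_id = "P2", z = -z))
  tr2 <- group_z_trajectory(z2)
  expect_equal(tr2$mean_z, c(0, 0, 0))
  expect_equal(tr2$n_patients, c(2L, 2L, 2L))
  # with a manifest, trajectories split by arm
  man <- tibble::tibble(patient_id = c("P1", "P2"),
                        arm = c("overnight", "once_daily"))
  tr3 <- group_z_trajectory(z2, man)
  expect_equal(nrow(tr3), 6)
  p <- plot_z_trajectory(tr3)
  expect_s3_class(p, "ggplot")
})
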