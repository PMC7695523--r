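test_that("a night is the arithmetic mean of its valid samples, dated by morning", {
  ts0 <- as.POSIXct("2024-03-01 23:30:00", tz = "UTC")
  ox <- tibble::tibble(patient_id = "P1", timestamp = ts0 + c(0, 1800, 3600),
                       heart_rate = c(68, 70, 72), spo2 = c(91, 92, 93))
  # 23:30, 00:00, 00:30 -> one session attributed to the morning of March 2
  agg <- aggregate_nights(ox)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$date, as.Date("2024-03-02"))
  expect_equal(agg$hr, 70)
  expect_equal(agg$spo2, 92)

  # a night with no valid samples is reported missing, not dropped silently
  ox_bad <- dplyr::mutate(ox, spo2 = c(40, 45, 49))
  agg_bad <- aggregate_nights(ox_bad)
  expect_equal(agg_bad$n_valid, 0L)
  expect_true(is.na(agg_bad$hr) && is.na(agg_bad$spo2))
})

test_that("nightly aggregation equals a brute-force mean over raw samples", {
  co <- simulate_cohort(quick_config(n_patients = 2, arm_split = 1,
                                     missing_day_prob = 0))
  agg <- aggregate_nights(co$oximetry)
  ox <- co$oximetry
  night <- paste(ox$patient_id, as.Date(ox$timestamp + 43200, tz = "UTC"))
  brute_hr <- tapply(ox$heart_rate, night, mean)
  key <- paste(agg$patient_id, agg$date)
  expect_equal(agg$hr, as.numeric(brute_hr[key]), tolerance = 1e-12)
  brute_sp <- tapply(ox$spo2, night, mean)
  expect_equal(agg$spo2, as.numeric(brute_sp[key]), tolerance = 1e-12)
})

test_that("the first monitored week is excluded and spot readings pass through", {
  start <- as.Date("2024-03-01")
  dates <- start + 0:20
  ox <- tibble::tibble(
    patient_id = "P1",
    timestamp = as.POSIXct(dates, tz = "UTC") + 8 * 3600,
    heart_rate = 78, spo2 = 94)
  diary <- tibble::tibble(patient_id = "P1", date = dates, cat = 16, pef = 210)
  man <- make_manifest(arm = "once_daily")
  daily <- build_daily_series(ox, diary, man)
  expect_equal(sort(unique(daily$date)), start + 7:20)
  hr <- daily[daily$variable == "HR", ]
  expect_true(all(hr$value == 78))
  expect_true(all(daily$value[daily$variable == "SpO2"] == 94))
  # removal is idempotent: rerunning on the retained dates changes nothing
  daily2 <- build_daily_series(ox[dates >= start + 7, ],
                               diary[dates >= start + 7, ], man)
  expect_equal(daily2, daily)
})

test_that("eligibility applies the stable-data and consecutive-missing rules", {
  tday <- as.Date("2024-04-19")
  man <- make_manifest(treatment_day = tday)
  full <- make_daily(n_days = 56)  # 2024-03-08 .. 2024-05-02

  ok <- check_eligibility(full, man)
  expect_true(ok$eligible)
  expect_length(ok$reasons[[1]], 0)

  # only 10 stable days before the pre-exacerbation window
  short <- full[full$date >= tday - 24, ]
  r <- check_eligibility(short, man)
  expect_false(r$eligible)
  expect_true("insufficient_stable_data" %in% r$reasons[[1]])

  # days -6 and -5 both missing
  gap2 <- full[!full$date %in% (tday - c(5, 6)), ]
  r2 <- check_eligibility(gap2, man)
  expect_false(r2$eligible)
  expect_equal(r2$reasons[[1]], "consecutive_missing_preexacerbation")

  # a single missing day does not exclude
  gap1 <- full[full$date != tday - 5, ]
  expect_true(check_eligibility(gap1, man)$eligible)
})

test_that("stable windows are complete, ordered and disjoint", {
  man <- make_manifest(treatment_day = as.Date("2024-04-26"))
  daily <- make_daily(n_days = 63)
  # knock one variable out on the second stable day: that day is unusable
  drop <- daily$date == as.Date("2024-03-09") & daily$variable == "PEF"
  daily <- daily[!drop, ]
  w1 <- select_stable_window(daily, man)
  expect_equal(nrow(w1), 14)
  expect_false(as.Date("2024-03-09") %in% w1$date)
  expect_equal(w1$date[1], as.Date("2024-03-08"))
  w2 <- select_stable_window(daily, man, exclude = w1)
  expect_equal(nrow(w2), 14)
  expect_equal(nrow(dplyr::inner_join(w1, w2, by = c("patient_id", "date"))), 0)
  # both windows end before the pre-exacerbation fortnight
  expect_true(max(w2$date) <= as.Date("2024-04-26") - 15)
})

test_that("event alignment maps calendar dates to day indices", {
  tday <- as.Date("2017-02-10")
  man <- make_manifest(treatment_day = tday,
                      monitoring_start = as.Date("2017-01-01"))
  daily <- tibble::tibble(
    patient_id = "P1",
    date = as.Date(c("2017-02-05", "2017-02-10", "2017-02-23", "2017-02-24")),
    variable = "CAT", value = c(18, 22, 17, 16), n_samples = 1L)
  al <- align_to_event(daily, man)
  expect_equal(al$day_index, c(-5L, 0L, 13L))  # +14 falls outside
  expect_equal(al$value, c(18, 22, 17))

  expect_error(align_to_event(daily, make_manifest()),
               class = "oxicopd_no_event_error")
})
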