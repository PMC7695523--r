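test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(sd_cat = -1), "sd_cat",
               class = "oxicopd_config_error")
  expect_error(sim_config(arm_split = 1.4), "arm_split",
               class = "oxicopd_config_error")
  expect_error(sim_config(sample_interval_s = 11), "sample_interval_s",
               class = "oxicopd_config_error")
  expect_error(sim_config(prodrome_days = 0), "prodrome_days",
               class = "oxicopd_config_error")
  expect_error(sim_config(treatment_day_index = 20), "treatment_day_index",
               class = "oxicopd_config_error")
  # once-daily total SD cannot be below the physiological day-to-day SD
  expect_error(sim_config(sd_hr_daily = 1.0), "sd_hr_daily",
               class = "oxicopd_config_error")
  # derived spot noise completes the once-daily variance budget
  cfg <- sim_config()
  expect_equal(sqrt(cfg$sd_hr_overnight^2 + cfg$spot_noise_sd_hr^2),
               cfg$sd_hr_daily)
  expect_equal(sqrt(cfg$sd_spo2_overnight^2 + cfg$spot_noise_sd_spo2^2),
               cfg$sd_spo2_daily)
})

test_that("an empty cohort is empty everywhere", {
  co <- simulate_cohort(quick_config(n_patients = 0))
  expect_equal(nrow(co$oximetry), 0)
  expect_equal(nrow(co$diary), 0)
  expect_equal(nrow(co$manifest), 0)
  expect_equal(nrow(co$truth), 0)
})

test_that("noise-free simulation reproduces the configured baselines exactly", {
  co <- simulate_cohort(noisefree_config())
  daily <- build_daily_series(co$oximetry, co$diary, co$manifest)
  daily <- dplyr::inner_join(daily,
                             dplyr::select(co$manifest, patient_id, arm),
                             by = "patient_id")
  expected <- function(v, arm) {
    switch(v, HR = ifelse(arm == "overnight", 70, 77),
           SpO2 = ifelse(arm == "overnight", 91, 94), CAT = 16, PEF = 214)
  }
  for (v in c("HR", "SpO2", "CAT", "PEF")) {
    d <- daily[daily$variable == v, ]
    expect_true(all(d$value == expected(v, d$arm)),
                label = sprintf("noise-free %s equals its baseline", v))
  }
  # raw overnight samples are constant too
  ox <- co$oximetry[co$oximetry$patient_id == "P0001", ]
  expect_true(all(ox$heart_rate == 70) && all(ox$spo2 == 91))
})

test_that("the exacerbation effect is a linear ramp with the configured extremes", {
  cfg <- sim_config(prodrome_days = 8, recovery_days = 13)
  expect_equal(exacerbation_profile(-30, "HR", cfg), 0)
  expect_equal(exacerbation_profile(0, "HR", cfg), 10)
  expect_equal(exacerbation_profile(0, "HR", cfg, arm = "once_daily"), 7)
  expect_equal(exacerbation_profile(-4, "CAT", cfg), 3.5)
  expect_equal(exacerbation_profile(cfg$recovery_days + 1, "CAT", cfg), 0)
  # oracle: linear interpolation through the ramp's corner points
  oracle <- approx(x = c(-9, -8, 0, 13, 14), y = c(0, 0, -1.2, 0, 0),
                   xout = -9:14)$y
  expect_equal(exacerbation_profile(-9:14, "SpO2", cfg), oracle)
  expect_error(exacerbation_profile(0, "RR", cfg),
               class = "oxicopd_variable_error")
})

test_that("the same seed reproduces an identical cohort", {
  a <- simulate_cohort(quick_config())
  b <- simulate_cohort(quick_config())
  expect_identical(a$oximetry, b$oximetry)
  expect_identical(a$diary, b$diary)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth, b$truth)
})

test_that("missingness is absent, total, or calibrated as configured", {
  co0 <- simulate_cohort(quick_config(missing_day_prob = 0,
                                      consecutive_miss_prob = 0))
  co0b <- inject_missingness(co0, quick_config(missing_day_prob = 0,
                                               consecutive_miss_prob = 0))
  expect_identical(co0, co0b)

  co1 <- simulate_cohort(quick_config(n_patients = 2, arm_split = 0,
                                      missing_day_prob = 1))
  expect_equal(nrow(co1$diary), 0)
  expect_equal(nrow(co1$oximetry), 0)

  # binomial Monte-Carlo check over ~10,000 patient-days (spot-reading arm)
  cfg <- sim_config(n_patients = 160, arm_split = 0, exacerbation_fraction = 0,
                    missing_day_prob = 0.1, consecutive_miss_prob = 0,
                    seed = 11)
  co <- simulate_cohort(cfg)
  expected_days <- 160 * cfg$total_days
  observed <- 1 - nrow(co$diary) / expected_days
  expect_lt(abs(observed - 0.1), 0.01)
})

test_that("missingness drops whole days coherently across streams", {
  cfg <- quick_config(missing_day_prob = 0.2)
  co <- simulate_cohort(cfg)
  ox_days <- unique(paste(co$oximetry$patient_id,
                          as.Date(co$oximetry$timestamp + 43200, tz = "UTC")))
  diary_days <- paste(co$diary$patient_id, co$diary$date)
  expect_setequal(ox_days, diary_days)
})

test_that("overnight nightly means recover the configured stable level", {
  cfg <- sim_config(n_patients = 20, arm_split = 1, exacerbation_fraction = 0,
                    total_days = 35, treatment_day_index = 22,
                    missing_day_prob = 0, seed = 5)
  dc <- simulate_daily_cohort(cfg)
  hr <- dc$daily$value[dc$daily$variable == "HR"]
  expect_lt(abs(mean(hr) - 70), 0.5)
  expect_lt(abs(sd(hr) - 1.8), 0.4)
})

test_that("overnight design yields smaller day-to-day SD than spot readings", {
  cfg <- sim_config(n_patients = 32, arm_split = 0.5,
                    exacerbation_fraction = 0, night_length_h = 2,
                    missing_day_prob = 0, seed = 9)
  dc <- simulate_daily_cohort(cfg)
  d <- dplyr::inner_join(dc$daily,
                         dplyr::select(dc$manifest, patient_id, arm),
                         by = "patient_id")
  per_patient_sd <- d |>
    dplyr::filter(variable %in% c("HR", "SpO2")) |>
    dplyr::summarise(s = sd(value), .by = c(patient_id, arm, variable))
  for (v in c("HR", "SpO2")) {
    s <- per_patient_sd[per_patient_sd$variable == v, ]
    expect_lt(mean(s$s[s$arm == "overnight"]),
              mean(s$s[s$arm == "once_daily"]))
  }
})
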