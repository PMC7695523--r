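# small cohort for machinery tests: short nights keep the sample streams light
quick_config <- function(n_patients = 6, arm_split = 0.5,
                         exacerbation_fraction = 0.34, night_length_h = 1,
                         seed = 42, ...) {
  sim_config(n_patients = n_patients, arm_split = arm_split,
             exacerbation_fraction = exacerbation_fraction,
             night_length_h = night_length_h, seed = seed, ...)
}

# all noise sources off, baselines integer-representable so device
# quantization (integer HR/SpO2/CAT) is exact
noisefree_config <- function(...) {
  sim_config(n_patients = 4, arm_split = 0.5, exacerbation_fraction = 0,
             baseline_hr_overnight = 70, baseline_hr_daily = 77,
             baseline_spo2_overnight = 91, baseline_spo2_daily = 94,
             baseline_cat = 16, baseline_pef = 214,
             sd_hr_overnight = 0, sd_hr_daily = 0,
             sd_spo2_overnight = 0, sd_spo2_daily = 0,
             sd_cat = 0, sd_pef = 0,
             within_night_sd_hr = 0, within_night_sd_spo2 = 0,
             spot_noise_sd_hr = 0, spot_noise_sd_spo2 = 0,
             missing_day_prob = 0, consecutive_miss_prob = 0,
             night_length_h = 1, seed = 1, ...)
}

# hand-built daily series: one patient, dates chosen so run-in is already gone
make_daily <- function(patient_id = "P1", start = as.Date("2024-03-08"),
                       n_days = 42, values = NULL) {
  dates <- start + seq_len(n_days) - 1
  purrr::map_dfr(c("HR", "SpO2", "CAT", "PEF"), function(v) {
    base <- switch(v, HR = 70, SpO2 = 91, CAT = 16, PEF = 214)
    tibble::tibble(patient_id = patient_id, date = dates, variable = v,
                   value = if (is.null(values)) base + seq_len(n_days) %% 3
                           else values,
                   n_samples = 1L)
  })
}

make_manifest <- function(patient_id = "P1", treatment_day = as.Date(NA),
                          arm = "overnight",
                          monitoring_start = as.Date("2024-03-01")) {
  tibble::tibble(patient_id = patient_id, arm = arm,
                 monitoring_start = monitoring_start,
                 treatment_day = treatment_day)
}
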