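---
title: "Detecting COPD exacerbations from home monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting COPD exacerbations from home monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxicopd)
```

## The problem and the model

COPD exacerbations announce themselves days before patients seek
treatment: symptoms climb, peak flow sags, heart rate rises, oxygen
saturation drifts down. Home telemonitoring can only exploit this
prodrome if a *change* can be told apart from each patient's own
day-to-day variability — absolute alarm limits fail because stable levels
differ enormously between patients. The approach implemented here is
therefore entirely patient-relative:

1. **Run-in.** The first monitored week is discarded; patients are still
   learning the equipment and those data are unreliable.
2. **Baseline calibration.** For each patient and variable, a 14-day
   stable window gives the baseline mean $\bar x$ and the sample SD
   (with $n-1$ denominator — the conventional choice for a 14-point
   estimate; the underlying procedure does not dictate one).
3. **Z transformation.** Each daily value $X$ becomes
   $Z = (X - \bar x)/SD$, so every variable is measured in units of that
   patient's own stable variability.
4. **Threshold detection.** A day is abnormal when $Z$ lies outside the
   95% band of the baseline mean, $|Z| \ge 1.96$.
5. **Composite oximetry score.** $Z_{HR} - Z_{SpO_2}$ combines the two
   pulse-oximetry channels with their physiological signs (exacerbations
   raise heart rate *and* lower saturation), so concordant changes
   reinforce each other.

Event-aligned analyses index days relative to the start of exacerbation
treatment (day 0): days −14..−1 are the pre-exacerbation window, days
+1..+13 the recovery. Day −15 is a display slot carrying the stable-period
mean ($Z = 0$ by construction); it is stored for figure parity but
excluded from every statistic.

Two exclusion rules guard the calibration: patients with fewer than 14
non-missing stable days (for any variable) cannot be baselined, and event
patients with a run of ≥ 2 consecutive missing days inside the
pre-exacerbation fortnight are excluded because the first-crossing day
would be unreliable. Single missing days are left missing — no
imputation.

## Why two monitoring arms differ

The once-daily arm takes one morning spot reading; the overnight arm
records a sample every 4 s for a full night (6,300 samples at the 7-hour
default). Both observe the same physiology, but the overnight nightly
mean averages away within-night fluctuation and one-off disturbances, so
its day-to-day SD is close to the true physiological variability while
the spot reading adds measurement-occasion noise on top. Since the
detection threshold is $1.96\,SD$ in the patient's *observed* units, a
smaller stable SD directly buys sensitivity to smaller absolute changes —
the signal-to-noise argument for overnight monitoring.

The simulator encodes exactly this structure. A single day-level
physiological state (SD 1.8 beats/min for HR, 0.36% for SpO2) underlies
both arms; the overnight arm observes it through 6,300 quantized samples
(within-night SD 8 beats/min and 2% — the stated device accuracy — i.i.d.
Gaussian, rounded to integer device resolution), the once-daily arm
through one reading with additional spot noise sized so the *total*
once-daily SD matches the configured 3.6 beats/min and 0.81%. Nothing
hard-codes an arm-level SD difference; it emerges from the design.

## What the simulator emulates

`sim_config()` defaults are the study conditions: stable levels of
70.0 beats/min (overnight) and 77.1 (once daily), SpO2 91.0% and 94.0%,
CAT 15.6 points (day-to-day SD 1.46), PEF 214 L/min (day-to-day SD 13.8);
maximal prodromal effects of +10/+7 beats/min, −1.2%/−2.0% SpO2, +7 CAT
points and −34 L/min PEF. Where a group-level SEM-like figure and a
day-to-day variability were both available for the same variable, the
day-to-day value is used — it is the quantity the Z denominator
estimates.

Design choices worth spelling out:

* **Prodrome/recovery shape.** The additive effect ramps linearly from 0
  at −7 days to its maximum at day 0 and returns linearly to 0 over 13
  recovery days. The underlying trajectories are gradual drifts with no
  published functional form; a linear ramp is the simplest shape that
  reproduces threshold crossings several days before treatment.
* **HR–SpO2 correlation (`hr_spo2_corr = 0.7`).** With independent
  day-level noise the composite score would have stable variance ≈ 2 and
  cross 1.96 during almost every stable fortnight — irreconcilable with
  the observed stable-state behaviour of this design, where the composite
  goes abnormal at some point in roughly a quarter of stable 2-week
  windows. A correlation of 0.7 between the day-level HR and SpO2
  fluctuations reproduces that fraction (Monte-Carlo calibration at the
  design stage). The correlation applies to the whole day-level
  measurement state, including the once-daily spot deviation: the
  transient non-exacerbation factors that contaminate a one-off reading —
  activity, anxiety, medication timing — move both channels of the same
  measurement jointly.
* **Timeline.** 63 monitored days per patient: 7 run-in + 28 stable days
  (baseline window plus room for a disjoint second stable window) + the
  14-day pre-exacerbation window + day 0 at day 50 + 13 recovery days.
  Monitoring stops after the first exacerbation's recovery, so each event
  patient has exactly one event.
* **Missingness.** Each monitored day is dropped independently with
  probability 0.05 (a realistic adherence level for home diaries and
  wearables); with probability 0.02 an event patient additionally loses a
  2-day run inside the pre-exacerbation window, so the consecutive-missing
  exclusion rule is exercised.
* **Quantization.** Device outputs are integers: HR in beats/min, SpO2 in
  %, CAT in points (bounded 0–40). `true_daily_sd()` accounts for the
  rounding variance (1/12 per rounded reading) when reporting the
  generator-implied SD of an observed daily value.
* **Randomness.** One root seed; each patient derives two child streams
  (measurement noise, missingness) from the root seed and the patient
  index. Noise is drawn in a fixed order that does not depend on the
  effect sizes, so cohorts with different `delta_*` but the same seed are
  matched draw-for-draw — effect-size monotonicity can be tested with
  common random numbers.

The simulator deliberately does **not** model circadian structure, sleep
apnea, temporal autocorrelation of noise, device drift, or
between-patient heterogeneity in baseline levels. Passing tests therefore
demonstrate that the pipeline's statistics behave as designed under the
stated first- and second-moment structure — not that the method meets any
particular performance level on real patients, whose noise is
autocorrelated, non-Gaussian and non-stationary.

## Detection and evaluation choices

* **Direction.** `detect_abnormal_days()` defaults to the stated
  two-sided rule ($|Z| \ge 1.96$). The *evaluation* analyses (lead times,
  performance) use the directional variant — HR, CAT and the composite
  crossing upward, SpO2 and PEF downward — because exacerbation
  physiology fixes the expected sign, trajectory figures in this design
  are drawn against one-sided thresholds, and reported saturation
  crossings are negative. Two-sided detection turns ~8% of stable
  patient-days into crossings once baselines are estimated (see
  calibration below), and those spurious crossings, not physiology, would
  dominate single-variable "first abnormal days". Both variants are one
  argument apart.
* **Detection window.** Days −14..0 inclusive: summaries of crossing days
  in this design run through day 0, and a crossing on the treatment day
  is still a (zero-lead) detection. The window is configurable to
  −14..−1.
* **Consecutive-days requirement.** A single crossing day flags a patient
  by default ("abnormal at some point"); `consecutive_days_required = k`
  offers run-length filtering for false-alarm control without changing
  the recorded crossing days.
* **Stable windows.** The baseline window is the first 14 stable days
  complete for all four variables (baseline statistics require complete
  windows, and under day-level missingness the first 14 *calendar* days
  are often incomplete). The second stable window — for specificity — is
  the next 14 complete stable days, disjoint from the first.
* **Phases.** The post-exacerbation phase is days +1..+13; day 0 is
  reported separately (recovery conventionally starts the day after
  treatment), with a switch to include it. Omnibus comparisons use ANOVA,
  falling back to Kruskal-Wallis when a Shapiro-Wilk check rejects
  residual normality; variability changes use a variance-ratio F test.
  These are standard library routines; the bespoke content is the phase
  construction and crossing logic.
* **Quantiles.** Lead-time IQRs use quantile type 6 (the SPSS
  convention), matching the reporting style of this literature: the
  median of {0, 2, 10} is printed as 2.0 (0–10).
* **Performance definitions.** Sensitivity, specificity and PPV follow
  the standard 2×2 formulas applied to the per-patient counts; undefined
  ratios (empty denominators) are reported as `NA`, never coerced to 0.
* **Degenerate baselines** (zero variance over the window) raise an
  error rather than flooring the SD: a fortnight of identical readings
  indicates broken input, and silently huge Z scores would be worse than
  a stop.
* **Group mean vs per-patient crossings.** Figure-style group
  trajectories (`group_z_trajectory()`) average Z across patients per
  day; detection and performance are per-patient, which is what the
  sensitivity/specificity construction requires. Both views are exported
  because the threshold can meaningfully be applied to either.

## Calibration of the 1.96-SD rule

Under a no-event simulation, with Z computed against the *true*
generator mean and SD, two-sided crossings occur on ≈ 5% of patient-days
— the nominal size of the 95% band. With the realistic 14-day *estimated*
baseline the rate inflates to ≈ 8% (the Z of an independent day is
$\sqrt{15/14}\,t_{13}$-distributed, and $P(|Z|>1.96) \approx 0.081$),
still below 10%. The acceptance checks verify both rates on ~10,000
simulated stable patient-days using the continuous channels (overnight
nightly-mean HR and SpO2, PEF). Integer-valued CAT is excluded from this
particular check by design: on a discrete scale the achievable test sizes
are quantized (with SD 1.46, the smallest integer exceedance beyond
1.96 SD corresponds to ±2.5 points, giving ≈ 9% rather than 5%), so the
Gaussian calibration band cannot apply to it.

## Problem sizes

The test suite and the acceptance script use cohorts of 200 patients
(100 per arm, one third with events) for the study-scale checks, 64
overnight no-event patients (~10,000 stable patient-days) for the
false-alarm calibration, and 4–32 patients with shortened nights for
machinery tests — sizes chosen so Monte-Carlo assertions have comfortable
margins while the whole suite stays quick to run.

## Known limitations

* The composite score's stable-state variance depends on the HR–SpO2
  correlation; the 1.96 threshold applied to a *difference* of Z scores
  is not a calibrated 5% test, and its false-alarm rate is governed by
  that correlation (this is a property of the method, reproduced rather
  than repaired here).
* Estimated 14-day baselines inflate crossing rates above nominal;
  analyses that need exact sizes should use longer windows or explicit
  t-quantiles.
* Lead-time medians censor never-crossing patients; with few events the
  medians are coarse (integer days).
* The simulator's missingness is missing-completely-at-random;
  adherence in real cohorts correlates with illness, which would bias
  pre-exacerbation data availability in ways this package does not model.
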