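# oxicopd

Early detection of COPD exacerbations from home telemonitoring.

People with chronic obstructive pulmonary disease (COPD) suffer acute
worsenings — *exacerbations* — whose early treatment speeds recovery and
reduces hospitalisation risk. Home telemonitoring tries to spot the
prodrome: a rising symptom burden (CAT questionnaire), falling peak
expiratory flow (PEF), rising heart rate and falling oxygen saturation
(SpO2) in the days before a patient seeks treatment. `oxicopd` implements
the full analysis pipeline for a two-arm monitoring design that compares
**once-daily morning spot pulse-oximetry** with **overnight pulse-oximetry
sampled every 4 seconds**, together with a synthetic cohort simulator so
every stage runs, and is tested, without any patient data.

## The method

For each patient and variable, a 14-day stable window defines the
baseline mean $\bar{x}$ and standard deviation $SD$. Daily values $X$
(nightly means for the overnight arm, spot readings for the once-daily
arm, diary entries for CAT and PEF) are expressed as Z scores

$$Z = \frac{X - \bar{x}}{SD},$$

and a day is *abnormal* when $Z$ falls outside the 95% band
($|Z| \ge 1.96$, or crossing in the physiologically expected direction
for the directional variant). The **composite pulse-oximetry score**

$$Z_{composite} = Z_{HR} - Z_{SpO_2}$$

rises with tachycardia and/or desaturation. From per-patient crossings
the package derives:

- **lead times** — days from a variable's first abnormal day to treatment
  start (day 0), summarised as medians/IQRs per arm with rank-based
  comparisons;
- **event-level performance** — sensitivity, specificity and PPV of
  "crossed at some point", with false positives measured on a *second*
  2-week stable window disjoint from the baseline;
- **phase comparisons** — stable vs pre-exacerbation (days −14..−1) vs
  recovery (days +1..+13) means and variabilities (ANOVA/Kruskal-Wallis,
  variance-ratio tests);
- **group trajectories** — per-day mean Z with the day −15 slot holding
  the stable mean, plus `ggplot2` figures with the ±1.96 band.

The simulator emulates the monitoring design that makes the overnight arm
attractive: a shared physiological day-to-day variability plus
arm-specific measurement layers (6,300 quantized samples per night
averaged down vs a single noisy spot reading), so the overnight arm's
smaller stable-state SD — and hence its better signal-to-noise ratio —
*emerges* from the design instead of being hard-coded.

## Worked example

```r
library(oxicopd)

cfg <- sim_config(n_patients = 30, exacerbation_fraction = 0.4, seed = 42)
dc  <- simulate_daily_cohort(cfg)
ev  <- evaluate_cohort(dc$daily, dc$manifest,
                       analysis_config(direction = "directional"))

ev$baselines |> dplyr::filter(patient_id == "P0001")
#>   patient_id variable  mean     sd n_days
#> 1 P0001      CAT       15.9  1.54      14
#> 2 P0001      HR        70.4  1.52      14
#> 3 P0001      PEF      216.  13.7       14
#> 4 P0001      SpO2      91.0  0.378     14
```

Patient P0001's stable fortnight sits at the configured overnight-arm
levels (HR ≈ 70 beats/min, SpO2 ≈ 91%) with a nightly-mean HR SD of 1.5 —
the averaging of thousands of overnight samples leaves mostly true
day-to-day variability.

```r
ev$lead_summary
#> <copd_lead_times>
#>   once_daily COMPOSITE 4 days (IQR 2-4.25), 0/6 censored
#>   overnight  COMPOSITE 5 days (IQR 5-7), 0/6 censored
#>   overnight  SpO2      3 days (IQR 1.75-12.25), 0/6 censored
#>   ...

glance(ev$performance)
#>      tp    fn    fp    tn sensitivity specificity   ppv
#> 1    12     0     4    14           1       0.778  0.75
```

The overnight composite score warns a median of 5 days before treatment
versus 4 days once-daily and 3 days for SpO2 alone, and flags all 12
simulated exacerbations while staying quiet in 78% of stable fortnights.
The group trajectory shows the composite climbing through the threshold
as the prodrome develops:

```r
tr <- group_z_trajectory(ev$zscores, ev$manifest)
dplyr::filter(tr, variable == "COMPOSITE", arm == "overnight",
              day_index >= -6, day_index <= 0)
#>   variable  arm       day_index mean_z n_patients
#> 1 COMPOSITE overnight        -6   1.93          6
#> 2 COMPOSITE overnight        -5   2.97          6
#> 3 COMPOSITE overnight        -4   4.79          6
#> 4 COMPOSITE overnight        -3   6.08          6
#> 5 COMPOSITE overnight        -2   7.09          6
#> 6 COMPOSITE overnight        -1   8.91          6
#> 7 COMPOSITE overnight         0  10.7           6
autoplot(tr)   # figure-style panels with the ±1.96 band
```

`run_pipeline("run1", sim = cfg)` performs the same analysis as a
file-based run: it writes the interchange CSVs, re-reads them through the
validating readers, and emits Z scores, detections, lead-time tables,
the performance table, trajectories, a figure, a per-patient exclusion
log, and the resolved configuration with its hash stamped into every
output as a provenance comment. Identical configurations reproduce
byte-identical CSVs.

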