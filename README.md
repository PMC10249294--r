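# hrvaf — heart-rate-variability analysis for post-operative AF risk

Post-operative atrial fibrillation (PoAF) occurs in roughly a third of
patients after cardiac surgery, and autonomic imbalance is one of its
drivers.  `hrvaf` is an R package for the corresponding risk analysis: it
turns a pre-operative resting RR-interval recording into the full HRV
feature battery and reproduces the cohort statistics that link attenuated
HRV to PoAF.

**Who it is for.**  Biostatisticians and physiologists who have beat
(RR-interval) series plus a patient covariate table and want a
reproducible, scriptable version of the standard HRV risk workflow — or
who want to study that workflow's behaviour on simulated data with known
ground truth.

## What it computes

* **RR ingestion & cleaning** — plain-text RR lists (ms or s) and
  annotated beat CSVs; deterministic artifact/ectopy filtering by a
  local-median rule (window 11 beats, 30% threshold), with removal or
  spline interpolation, and a corruption gate at 20% flagged beats.
* **Time domain** — mean RR, mean HR, SDNN, RMSSD, NN50/pNN50 (strict
  \> 50 ms), TINN via least-squares triangle fit to the 7.8125-ms NN
  histogram.
* **Frequency domain** — cubic-spline tachogram resampling at 4 Hz,
  smoothness-priors detrending (λ = 500), Burg autoregressive spectrum
  (order 32), band powers by pole-aware adaptive quadrature over
  VLF 0–0.04 / LF 0.04–0.15 / HF 0.15–0.4 Hz, with
  total = VLF + LF + HF exactly and LF/HF flagged `NA` when undefined.
* **Non-linear** — Poincaré SD1/SD2 (SD1² + SD2² = var(x) + var(y) holds
  exactly), Guzik/Porta/Slope heart-rate-asymmetry indices, approximate
  and sample entropy (m = 2, r = 0.2·SDNN, Chebyshev), Grassberger–
  Procaccia correlation dimension and recurrence rate (embedding m = 10,
  lag 1).
* **Cohort statistics** — Shapiro-Wilk-driven test selection
  (Wilcoxon / pooled t / Welch), uncorrected Pearson chi-square for
  categorical tables, univariate logistic screening, deterministic
  stepwise-AIC model selection, ROC with Youden and
  sensitivity-≥ 0.95 operating points, and feature correlation tables.
* **Synthetic data** — RR generator with prescribed per-band modulation
  power and ectopic-beat injection; cohort generator with configurable
  covariate prevalences and a logistic outcome model (defaults emulate a
  137-patient cardiac-surgery cohort with 35% PoAF).

## Worked example

```r
library(hrvaf)

## a 30-minute recording with known band powers (VLF 1800, LF 500, HF 200 ms^2)
rr <- simulate_rr_series(simulation_params(duration_s = 1800, seed = 42))
rr
#> <rr_series> 1930 intervals, 1800.5 s, source sim-seed42
#>   labels: normal=1930

cfg <- analysis_config(freq_domain = list(fs = 4, detrend_lambda = NULL,
                                          ar_order = 32, n_freq = 1025,
                                          band_edges = c(0, 0.04, 0.15, 0.4)))
row <- analyze_patient(rr, cfg)
round(row[c("mean_rr", "sdnn", "rmssd", "pnn50", "power_vlf", "power_lf",
            "power_hf", "lf_hf", "sd2", "apen", "sampen", "rec")], 3)
#>   mean_rr   sdnn rmssd pnn50 power_vlf power_lf power_hf lf_hf    sd2  apen sampen    rec
#> 1 932.881 49.888 25.06  4.51  1654.166  625.827  203.001 3.083 68.291 1.451   1.46 33.067
```

The recovered band powers sit near their prescriptions (single-seed AR
estimates scatter by ~10–15%; seed averages converge to the prescription).
On real, non-stationary recordings keep the default `detrend_lambda = 500`;
it removes slow drift at the cost of some genuine VLF power (see the
methods vignette).

```r
## a full cohort pass at study scale
cohort <- simulate_cohort(cohort_params(seed = 7))
analyze_cohort(cohort)
#> <hrv_cohort_report>
#>   cohort: n = 137 (50 events / 87 non-events)
#>   comparisons: 44 variables (chi_square=11, t=21, welch=1, wilcoxon=11)
#>   univariate: 12 of 44 candidates significant at alpha 0.05
#>   selected: age, chadsvasc, diabetes, mean_rr, nn50, power_vlf, sd2, sampen, d2, rec
#>   ROC: AUC 0.894; Youden sens 0.84 spec 0.82; sens>=0.95 spec 0.53
```

Reading the report: 50 of 137 simulated patients developed PoAF; each
variable was compared between groups with the test its distribution
demands; twelve passed the univariate screen; the stepwise-AIC model kept
ten of them; and at the 0.95-sensitivity operating point the model reaches
specificity 0.53.  Because the simulated HRV features are genuinely
attenuated in the PoAF group, the selected variables are dominated by the
true effect carriers (age, diabetes, SD2, entropy, D2, REC, VLF power).

A thin command-line front end over the same functions ships in
`inst/cli/hrvaf` (`analyze`, `cohort`, `simulate`, `simulate-cohort`).

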