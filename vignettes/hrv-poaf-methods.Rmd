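---
title: "Methods: heart-rate-variability analysis for post-operative AF risk"
author: "hrvaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate-variability analysis for post-operative AF risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvaf)
```

## Scope and model of the analysis

Post-operative atrial fibrillation (PoAF) complicates roughly a third of
cardiac-surgery admissions.  Because autonomic imbalance is one of its
drivers, attenuated pre-operative heart-rate variability (HRV) is a
plausible risk marker: a 2-hour resting ECG the day before surgery yields
an RR-interval series whose time-domain, spectral and non-linear structure
can be condensed into a feature vector per patient and combined with
clinical covariates in a logistic risk model.

`hrvaf` implements that workflow end to end:

1. **RR ingestion and cleaning** (`read_rr_series()`, `filter_artifacts()`,
   `select_segment()`): plain-text RR lists or annotated beat CSVs become a
   validated `rr_series`; ectopic beats and artifacts are removed or
   interpolated so metrics see normal-to-normal (NN) intervals only.
2. **Metric engine**: `time_domain_metrics()` (mean RR/HR, SDNN, RMSSD,
   NN50/pNN50, TINN), `freq_domain_metrics()` (autoregressive band powers
   in VLF 0–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz), `nonlinear_metrics()`
   (Poincaré SD1/SD2, Guzik/Porta/Slope asymmetry, ApEn/SampEn,
   correlation dimension, recurrence rate).
3. **Cohort statistics** (`compare_groups()`, `univariate_screen()`,
   `stepwise_aic()`, `roc_analysis()`, `correlation_matrix()`), orchestrated
   by `analyze_cohort()`.
4. **Synthetic data** (`simulate_rr_series()`, `simulate_cohort()`) so that
   every stage above is testable without clinical recordings.

## Cleaning: a deterministic surrogate for visual inspection

Clinical HRV practice removes premature beats and artifacts by eye.  A
package cannot reproduce a person, so cleaning is a deterministic
local-median rule: beat *i* is flagged when
\(|rr_i - \tilde m_i| > c\,\tilde m_i\), with \(\tilde m_i\) the median over a
centred window of 11 beats (shrinking symmetrically at the edges) and
\(c = 0.3\).  Flagged beats are removed, or spline-interpolated over beat
time when series length must be preserved.  Both parameters are exposed in
`analysis_config()`.  A recording with more than 20% flagged beats is
rejected outright — the analogue of excluding unusable recordings from a
cohort before analysis.  The window/threshold defaults were chosen once for a clear
operating point: on simulated recordings with 1.5 premature beats per
minute the rule recovers over 95% of injected positions while flagging
essentially nothing on clean recordings.

## Frequency domain: resampling, detrending, Burg spectra

RR intervals arrive at beat times, not on a clock grid, so the tachogram is
cubic-spline resampled at 4 Hz (comfortably above twice the 0.4-Hz HF
edge).  Slow aperiodic drift is removed by smoothness-priors detrending:
the trend is \((I + \lambda^2 D_2^\top D_2)^{-1}x\) with \(D_2\) the
second-difference operator and \(\lambda = 500\) by default.  This is a
time-varying high-pass: at 4 Hz, \(\lambda = 500\) has half-amplitude near
0.028 Hz, so most genuine sub-0.03-Hz oscillation is removed along with the
drift.  That trade-off is deliberate for real, non-stationary recordings —
but it means VLF power measured after detrending is a lower bound.  For
that reason every *prescription-recovery* validation in this package (can
the chain recover known oscillatory band powers?) runs with
`detrend_lambda = NULL`: recovery is a property of the
resample → AR → integrate chain, and the detrender would otherwise remove
the very signal whose recovery is being measured.

The spectrum itself is parametric: Burg AR coefficients (via
`stats::ar.burg`), evaluated as \(S(f) \propto |1-\sum_k a_k
e^{-2\pi i f k/f_s}|^{-2}\) and Parseval-normalised so the integral over
\([0, f_s/2]\) equals the sample variance.  Two numerical choices matter:

* **Model order 32.**  With 2-hour records and tri-band content, order 16
  lacks the resolution to separate a large VLF complex from LF: on
  simulated recordings with known band powers it overestimated LF by ~40%
  while a smoothed-periodogram reference put LF within 10% of prescription.
  Order 32 recovers VLF/LF/HF within −2/+10/−4% (5-seed averages) and
  agrees with the periodogram reference.  The order remains configurable.
* **Pole-aware band integration.**  Burg spectra of nearly periodic
  signals have peaks far narrower than any display grid; integrating them
  with grid trapezoids is arbitrarily wrong.  `band_powers()` therefore
  integrates the *continuous* AR spectrum by adaptive quadrature with the
  pole-angle frequencies as break points.  Band powers are then independent
  of the display grid (doubling the grid changes nothing), and the total
  power equals the sum of the three band integrals by construction.

Band intervals are half-open \([lo, hi)\) so no frequency is counted twice;
the 0-Hz endpoint belongs to VLF.  When HF power is zero (or the whole
spectrum is numerically empty, as for a constant recording) LF/HF is
reported as `NA` rather than infinity.

One caveat carried in the documentation rather than the code: some HRV
software reports the LF "peak" at the band's lower edge whenever the
density decreases monotonically across the band (the argmax of a spectrum
dominated by VLF), which shows up in published tables as an LF peak
pinned near 0.04 Hz with implausibly small spread.  `hrvaf` reports the
in-band argmax of the density and makes no attempt to reproduce an
edge-pinning convention.

## Non-linear battery: conventions pinned

* **Poincaré**: points \((rr_i, rr_{i+1})\) rotated by −45°; SD1/SD2 are
  sample standard deviations (n−1 throughout the package) of the rotated
  coordinates.  The rotation is orthogonal, so
  \(SD1^2 + SD2^2 = \mathrm{var}(x) + \mathrm{var}(y)\) exactly — a tested
  identity.
* **Asymmetry**: points on the identity line are excluded from numerators
  and denominators.  Porta = % of points below the line; Guzik = % of
  summed *squared* perpendicular distances above the line (the original
  published form; first-power distances are a config toggle because the
  prose definitions in the applied literature often say "distance");
  Slope = % of summed absolute phase-angle deviations from 45°.
* **Entropies**: templates of length m = 2, Chebyshev distance, tolerance
  r = 0.2·SDNN, natural log.  ApEn includes the self-match; SampEn excludes
  it and reports `NA` (flagged) when no (m+1)-matches exist rather than
  an infinite value.
* **Correlation dimension**: Grassberger–Procaccia slope of
  \(\log C(r)\) vs \(\log r\) over the middle third of 30 log-spaced radii
  between the 1st and 99th percentiles of pairwise embedded distances
  (dimension 10, lag 1).  Embedded vectors are strided down to at most
  3000 before pair evaluation; this caps the O(M²) pair count on 2-hour
  records at a size where the slope estimate is stable.
* **Recurrence rate**: % of distinct embedded pairs within
  \(\sqrt{m}\,\cdot\) SDNN (ties recurrent), main diagonal excluded.

ApEn, SampEn, REC and TINN are each verified against independent
brute-force enumeration oracles on hundreds of fuzzed short series — the
implementations are compiled (Rcpp) for 2-hour records, the oracles plain
R loops.

TINN fits a triangle to the NN histogram (bins of 1/128 s = 7.8125 ms
aligned to multiples of the width from 0): apex fixed at the modal bin,
baseline endpoints chosen on the bin-centre grid to minimise the squared
error.  Because the error separates into a left term (N only) and a right
term (M only), the endpoints are optimised independently; an exhaustive
O(bins²) search is kept as the test oracle.  A single-occupied-bin
histogram returns one bin width by convention; modal ties resolve to the
lowest bin.

## Cohort statistics

Two-group comparisons follow a deterministic gate: Shapiro–Wilk on each
group at α = 0.05; any non-normality (or a zero-variance group) routes to
the two-sample Wilcoxon rank-sum test (exact when combined n ≤ 20 without
ties, otherwise the tie- and continuity-corrected normal approximation);
otherwise an F-test of variances at α = 0.05 chooses pooled t versus
Welch.  Categorical tables use Pearson's chi-square **without** continuity
correction — on the emulated cohort's sex table (15/33 vs 18/71) the
uncorrected test gives p = 0.15 while the Yates-corrected one gives 0.22,
and the uncorrected form is the one this workflow standardises on.

Logistic fits use maximum likelihood through `stats::glm` (IRLS,
tolerance 1e−8, 100 iterations cap) with Wald z-tests;
AIC = −2 logL + 2k and OR = exp(coef) hold as identities.  Any
|coefficient| > 15 on the final iterate (odds ratios beyond ~3 million
per unit on a flat likelihood) is treated as complete/quasi-separation
and raised as a typed error; the stepwise search skips and records such
moves.

Stepwise selection is greedy and fully deterministic: from the supplied
start (all candidates by default), every single-variable addition and
deletion is evaluated, the lowest-AIC move is applied, ties break by
fewer parameters then input order, and the search stops when no move
improves AIC.  Two calibration facts shape expectations here.  A noise
variable survives the AIC gate iff its χ²(1) deviance gain exceeds 2
(probability 0.157), so with ten pure-noise candidates the intercept-only
model is selected in only ≈ 0.84¹⁰ ≈ 18% of null replicates — a *correct*
AIC stepwise is expected to keep a spurious variable or two, and the test
suite checks the empirical rate against that number, not against an
informal "usually empty" intuition (which would require a BIC-strength
penalty of ln n).  Conversely a predictor with log-odds 1 per SD at
n = 1000 is retained essentially always.

No multiple-testing correction is applied anywhere — a deliberate
mirror of common practice in this literature; with ~30 candidate variables the univariate screen is expected
to pass a false positive or two into the multivariate stage.  Missing
data are handled complete-case per analysis.  Before the stepwise stage,
one member of any feature pair with |r| above 0.999 is dropped (NN50 and
pNN50 are deterministically related, for example).

ROC curves enumerate all distinct score thresholds; the trapezoid AUC is
verified (to 1e−12) against the tie-corrected Mann–Whitney concordance.
Two operating points are reported: the Youden optimum and the
highest-specificity point subject to sensitivity ≥ 0.95 — clinical
screening for a preventable complication prioritises sensitivity, so the
floor rule is the headline and the floor is configurable.

CHA₂DS₂-VASc uses the standard component sum (heart failure 1,
hypertension 1, age ≥75 → 2 / 65–74 → 1, diabetes 1, stroke/TIA 2,
vascular disease 1, female 1).  Non-standard score variants
(e.g. a "CHA2DS2-Risc" sometimes seen in applied reports without a
definition) are not implemented.

## The synthetic-data generator: what it does and does not emulate

`simulate_rr_series()` builds a modulation signal on a 4-Hz grid as, per
band, 20 random-phase sinusoids with frequencies uniform in the band, and
places beats iteratively, \(t_{k+1} = t_k + (RR_0 + m(t_k))/1000\).  Three
deliberate simplifications:

* Interval-sampled modulation rather than an integral-pulse-frequency
  model — adequate for metric-level testing; it slightly distorts
  harmonics but preserves band powers.
* Frequencies are floored at 2/duration so every component completes at
  least two cycles; below that the realised variance of a component is
  ill-defined at the record length (physiologically, slower content
  belongs to the ULF band a 2-h recording cannot resolve anyway).
* Each band's signal is rescaled so its realised sample variance equals
  the prescription exactly.  With random frequencies, near-coincident
  pairs otherwise leave several-percent realisation error in a band's
  variance, which would be mistaken for estimator bias in the
  recovery tests.

The default prescription — mean RR 935 ms, VLF 1800 / LF 500 / HF 200
ms² over 7200 s — is the resting pre-operative no-PoAF profile the
analysis assumes.  `inject_ectopics()` adds premature-beat/compensatory
pause pairs (×0.6, ×1.4) at Poisson positions for cleaning tests.

`simulate_cohort()` draws clinical covariates at the emulated cohort's
prevalences (137 patients, 35% PoAF, 24% women, diabetes 28%,
hypertension 78%, CABG 64%, …; COPD is absent from the emulated baseline
table and is set to a realistic 0.15), generates the outcome from a
logistic model on the clinical covariates (intercept auto-centred to the
target rate), then draws HRV features per outcome group with attenuated
means in the PoAF group.  `total_power` is constructed as the sum of the
three band powers and LF/HF as their ratio, so the dominant
power-correlation structure (VLF–total strongest) is present.  What the
generator does **not** model: cross-metric correlations beyond the power
identity (real RMSSD and SD1 are deterministically related; simulated ones
are independent draws), respiratory/baroreflex coupling, non-stationarity,
and circadian structure.  Passing tests therefore demonstrate that the
*pipeline* is correct under its stated assumptions, not that the package
reproduces any particular clinical dataset.

One directional property deserves a note: halving all prescribed band
powers reduces SD2 and total power, but leaves the correlation dimension
unchanged — amplitude scaling is invisible to D2 because its radii are
distance quantiles.  The lower D2 reported in PoAF patients is a change in
dynamics, not amplitude, and in the simulated cohorts it enters through
the group-specific feature means, not through the RR generator.

## Problem sizes and runtime choices

Validation sizes were chosen to keep the full suite fast while leaving
each estimate well-determined: spectral-fidelity checks average 5
seeds × 7200-s recordings; oracle-equivalence fuzzing uses 200 series of
n ≤ 60 per metric; stepwise behaviour uses 50 replicates at n = 1000;
screening calibration uses 1000 null replicates at the study's size
(n = 137, event rate 0.35); cohort pipeline tests run at n = 137 and
n = 2000.

## Known limitations

* The package starts from RR/beat series; QRS detection from raw ECG is
  out of scope.
* Apparent (in-sample) model performance only — no bootstrap optimism
  correction or cross-validation; reported AUCs are optimistic by design.
* The AR model order, detrending strength, entropy tolerances and
  embedding settings are conventions, not estimated quantities; all are
  exposed in `analysis_config()` and recorded with results.
* D2 magnitudes depend on the (unpublishable) radius-range and slope-fit
  conventions of any given implementation; only degenerate cases, the
  closed-curve benchmark (D2 ≈ 1) and oracle equivalence of the
  correlation sum are asserted, not absolute clinical magnitudes.
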