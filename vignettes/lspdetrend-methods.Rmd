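---
title: "Detecting seasonal diagnosis incidence: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seasonal diagnosis incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lspdetrend)
```

## The model

The unit of analysis is the monthly count of *unique* patients receiving
a diagnosis code. Counting patients rather than events keeps one
patient's repeat visits within a month from inflating incidence; the
time axis is placed at month midpoints in decimal years (Jan 1997 is
1997.0417), so that the spectral analysis sees no systematic half-month
phase bias.

Raw monthly series from a hospital EHR are dominated by two nuisance
components. First, a secular multi-year growth in recorded visits, which
a periodogram reads as overwhelming low-frequency power — before trend
removal, genuinely seasonal codes can fail to register at all. Second, a
shared oscillation of *total* visits with an approximately 6-month
period (spring and fall peaks). Any code that is a roughly fixed
proportion of total visits — chronic diagnoses above all — inherits that
oscillation after de-trending and would be falsely called seasonal. Both
corrections are per-code:

1. **De-trending.** The trend is a Gaussian-kernel Nadaraya–Watson
   regression of the counts on the month index. This is the estimator an
   automatic-bandwidth *weighted* kernel density of event times implies
   once its monthly evaluations are rescaled to counts, and it is exact
   on constant series. The months within two bandwidths of either end of
   the record are trimmed: kernel estimates there borrow mass from
   outside the observation window. On a 13-year record with the default
   bandwidth this leaves a 10-year analyzable core.
2. **De-totaling.** The summed counts over all codes are de-trended the
   same way; each code's expected share is that total scaled by
   `mean(code)/mean(total)` (computed on the trimmed axis, total
   including the code itself — with many codes self-inclusion is
   negligible). Subtracting the scaled de-trended total removes exactly
   the signal a fixed-proportion code would carry: for a noiseless
   fixed-proportion series the result is identically zero, a property
   the tests assert.

The adjusted series is scored with the classical normalized Lomb–Scargle
periodogram (phase offset `τ` per frequency, sample variance with the
`N−1` denominator). Under Gaussian white noise the power at one
frequency is exponentially distributed with mean 1, so the maximum over
`M` independent frequencies gives the false-alarm probability
`1 − (1 − e^(−z))^M`. Codes are scanned on periods of 2–60 months; a
best period longer than 18 months is reported non-significant outright —
on a ten-year usable record such periods complete too few cycles to be
interpretable — and Benjamini–Hochberg q-values are reported across
codes alongside the raw p-values.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bw_floor` | 9 | months | A bandwidth shorter than the periods under test would absorb the seasonal signal into the "trend". A cosine of period `T` survives smoothing at bandwidth `h` with factor `1 − exp(−(2πh/T)²/2)`; at `h = 9, T = 12` the trend takes essentially none of it. Silverman's rule on count-weighted months is used above the floor and `bandwidth` can be forced. |
| trim | `⌈2h⌉` | months/end | Kernel estimates near the edges are unreliable. |
| grid | 2–60, `ofac = 4` | months | Periods below 2 months are beyond the monthly Nyquist limit; above 60 months is far outside the admissible band. Oversampling 4 gives ~0.1-month period resolution near 12 months. |
| `n_indep` (M) | `n_grid / ofac` | — | The natural independent-frequency count for an oversampled grid; the null-calibration tests confirm the resulting false-alarm rate is approximately nominal (≈1–2% flagged at p < 0.01 on pure noise). |
| `max_admissible_period` | 18 | months | The 1.5-year rule; applied to the *best* period after a full-grid search, not by truncating the grid, so long-period power can win the argmax and then be zeroed rather than silently promoting a runner-up peak. |
| `p_threshold` | 0.01 | — | Significance flag on the raw false-alarm p; BH q is reported alongside. |
| `min_cases` | 500 | patients | Common-code filter: totals must *exceed* the threshold (strict inequality). Unique-patient totals are used — the same unit the matrix counts — configurable via the aggregation itself. |
| comorbidity `window` | 60 | days | Look-back `[index − 60 d, index)`: half-open, so events on the index day are excluded as plausibly consequent rather than antecedent. |

## The synthetic world

`simulate_counts()` draws the code × month counts first —
`Poisson(baseline_c × growth(t) × (1 + A cos(2π(t−φ)/P_total)) × (1 + a_c cos(2π(t−φ_c)/P_c)))`
— and then materializes events from the counts, so the truth table is
exact by construction and parameter-recovery tests are sharp. Chronic
codes instead receive `fraction_c ×` (summed mean of the non-chronic
codes), making them fixed proportions of the total by construction.
Defaults chosen once as a realistic hospital:

* growth linear, ×2 over 12 years;
* shared seasonal amplitude 5% with a 6-month period peaking in April
  and October (spring/fall);
* every event a fresh patient, with `extra_visit_prob` available to add
  same-month repeat visits (these exercise unique-patient counting
  without breaking the exact counts↔events round-trip).

The generator emulates growth, shared seasonality, planted per-code
signals, fixed-proportion chronic codes, Poisson noise and rare-code
sparsity. It does **not** emulate code hierarchies, cross-patient
correlation, coding-practice changes, or gaps in the record — so a green
test establishes that the pipeline recovers the stated structure from
realistic count noise, not that it is robust to every failure mode of
production EHR extracts.

One consequence of de-totaling worth stating: a seasonal signal carried
coherently by codes that dominate the total is, by design,
indistinguishable from a shared hospitalization trend and is removed.
The power checks therefore embed the 50 planted seasonal codes (phases
spread over the year, as real diseases peak in different seasons) in a
larger non-seasonal background — the regime the method targets, where a
few hundred seasonal codes sit among thousands.

## Numerical choices and degenerate inputs

* False-alarm probabilities are computed as
  `-expm1(M · log1p(-exp(-z)))`, which degrades gracefully to the
  `M e^(−z)` small-p branch without underflow.
* A constant adjusted series (zero variance) is an error in
  `lomb_scargle()`; an all-zero raw series smooths to a zero trend with
  a sentinel `NA` bandwidth.
* Vanishing periodogram denominators (e.g. the sine term exactly at the
  Nyquist frequency on integer sampling) carry vanishing numerators and
  contribute zero power.
* Series must have ≥ 24 months before smoothing and after trimming;
  shorter inputs are errors, not silent truncations.
* Clustering uses `stats::hclust`, whose merge order is deterministic
  given the input row order; ties in the distance matrix are resolved by
  its internal ordering rather than a bespoke lowest-index rule —
  reproducibility is preserved, which is what the rule was for.
* The comorbidity ratio reports the sentinel −1 when the control count
  is zero (the ratio is undefined); the printed statistic is the
  incidence (risk) ratio `(a/n1)/(b/n2)`, which published case-control
  tables of this design label "odds ratio" although it is not the
  cross-product odds ratio.

## Design choices where the design was open

* **Smoother identity.** The description "weighted KDE evaluated at
  every month with automatic bandwidth" fixes the estimator only up to
  normalization; Gaussian Nadaraya–Watson with Silverman's rule on
  count-weighted months reproduces the described behavior without
  depending on one vendor's implementation. Exact numerical equality
  with any particular legacy implementation is not claimed.
* **What de-totaling subtracts.** The raw de-trended total is
  subtracted, not a re-smoothed version; the fixed-proportion
  cancellation is exact this way.
* **Which series is clustered.** The de-totaled series — the same
  series the significance call is made on.
* **Per-code trims.** Each code is trimmed by its own bandwidth and then
  aligned to the shared component's axis (effective trim = the larger of
  the two), since the subtraction requires a common axis.
* **Comorbidity exact test.** Two-sided Fisher exact on
  `(a, n1−a; b, n2−b)` stands in for the original bootstrap-FDR
  procedure of the upstream comorbidity algorithm; its p-values are
  indicative, with BH q-values alongside. With ≥ 2 control cohorts,
  findings must be significant against *every* control, and the
  first-listed control's statistics are reported.

## Limitations

Monthly binning caps the frequency range at the 2-month Nyquist period;
sub-monthly patterns are invisible. The exponential null assumes
approximately Gaussian noise — adequate for de-trended counts of common
codes, increasingly approximate for very sparse ones. The 18-month rule
is a reporting convention, not a claim that longer cycles are absent.
De-totaling removes any signal proportional to the total, including a
true epidemic that happened to move the whole hospital. P-values are
calibrated against white noise; autocorrelated residuals (e.g. long
epidemics) inflate apparent significance.
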