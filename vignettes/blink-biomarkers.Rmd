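---
title: "Blink biomarkers from the VEOG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blink biomarkers from the VEOG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkr)
```

# The measurement problem

A blink drags the eyelid across the cornea and produces a large, slow
(100–400 ms) positive deflection in the bipolar vertical EOG — the
difference between an electrode above and one below the eye. Because the
deflection is an order of magnitude larger than ongoing EEG/EOG background,
blink extraction can be reduced to three steps: band-pass filtering,
thresholded peak-picking with a refractory interval, and per-segment
summary statistics. `blinkr` implements that chain plus the statistical
layer used to relate the resulting indices to anxiety questionnaire scores,
and a synthetic generator that makes every stage testable against known
ground truth.

This vignette records the model assumptions, the tunable parameters and why
their defaults are what they are, the numerical choices, and what the green
test suite does and does not establish.

# Signal chain

## Filtering

The pass band is 0.5–20 Hz: the lower edge removes electrode drift and DC,
the upper edge removes EMG and line-noise components while leaving the
blink waveform (whose energy sits mostly below ~10 Hz) intact.

The band is the only thing fixed by convention; the realization is a
package decision:

* **Butterworth, prototype order 4** (8-pole band-pass): maximally flat
  pass band, so blink peak voltages — the quantity BA is built from — are
  not sculpted by ripple.
* **Forward–backward application (zero phase)** by default: a causal pass
  would delay and skew the peak, biasing both peak amplitude and
  inter-blink intervals. Zero-phase filtering preserves the peak latency of
  a symmetric pulse to within one sample (asserted in the tests).
* **Edge handling:** odd-reflection padding of `ceiling(6 * fs / low_cut)`
  samples (capped at signal length − 1) before the forward–backward pass,
  with zero initial filter state. At 500 Hz and a 0.5 Hz edge the slowest
  pole's transient decays by ~`exp(-9)` within the pad, so 2-minute film
  segments do not lose boundary blinks. The design was validated against an
  independent DSP implementation during development; the shipped tests
  check the realized frequency response against a Horner-evaluated oracle
  (pass band < 1 dB down at 5 Hz, stop band ≥ 20 dB down at 50 Hz).
* Filtering is applied **per extracted segment**, never across segment
  joins, matching how film-clip windows are analyzed.

## Detection

`detect_blinks()` finds local maxima of the blink-positive signal (no
rectification: with upper-minus-lower derivation blinks deflect positive,
and rectifying would double-count biphasic waveforms), keeps those at or
above the 100 μV threshold, and enforces the 250 ms refractory interval by
greedy suppression in decreasing amplitude order — when two supra-threshold
maxima conflict, the larger survives; amplitude ties go to the earlier
peak. This mirrors common find-peaks semantics (`scipy.signal.find_peaks`
with `distance`, MATLAB `findpeaks` with `MinPeakDistance`).

Numerical details that needed a decision:

* a local maximum is a sample strictly greater than both neighbors;
  plateaus bounded by rises on both sides resolve to the plateau midpoint
  (lower-middle sample for even plateaus);
* a supra-threshold maximum at the first or last interior sample counts; a
  half-cut waveform with no interior maximum does not;
* the threshold applies to the **filtered** trace. The convention matters:
  zero-phase 0.5–20 Hz filtering attenuates a typical 280 ms blink peak by
  roughly 10 %, so a 100 μV threshold on the filtered trace is slightly
  stricter than on the raw one. The source methodology does not pin this
  down; detection-on-filtered is declared here and used consistently.

## Indices

Per segment: BR = blinks/minute; BA = mean peak voltage (μV); BRV = CV of
inter-blink intervals; BAV = CV of peak amplitudes. CV uses the **sample**
SD (n − 1): per-segment event counts are small (a 2-minute clip holds ~30
blinks) and the n − 1 form is the unbiased-variance convention; the source
does not specify. Definedness floors keep degenerate segments honest
rather than erroring: BA needs ≥ 1 blink, BAV ≥ 2, BRV ≥ 3 (two IBIs);
below the floor the index is `NA` and film-session aggregation
(`aggregate_films()`) skips it per index while averaging the rest —
clip-level metrics are averaged, not event-pooled, matching the
"clips averaged within participant" convention.

# Synthetic data: what it emulates, what it does not

The generator is a *stated world*, not a tuning knob: its defaults encode
the study design it stands in for — 500 Hz sampling, a 5-minute resting
segment plus 18 two-minute film clips per subject in six emotional
categories (3 negative, 2 positive, 1 neutral; 3 clips each), a blink rate
centered on 16.9 blinks/min with a between-subject SD of 9.28, and
amplitudes well above the 100 μV threshold.

* **Timing: gamma renewal process.** IBIs are i.i.d. gamma with mean
  `60/rate` and shape `k`, so BR and BRV = `1/√k` are independently
  controllable — the minimal model with that property. Real blink timing
  has serial dependence and nonstationarity (attention drifts, scene cuts);
  a renewal process has neither, so tests built on it validate estimator
  arithmetic, not physiological realism. IBIs are clamped below at 0.3 s
  (`pmax`), keeping every generated event resolvable under the 250 ms
  refractory rule; clamping (rather than rejection sampling) perturbs the
  exponential-case CV by < 0.02 at the default rate.
* **Amplitudes: lognormal**, log-SD `amp_log_sigma` (default 0.35, giving a
  long-run BAV of `sqrt(exp(0.35^2) - 1) ≈ 0.36`), with the waveform a
  raised-cosine (or gamma-shaped) pulse of 280 ms by default, additive
  Gaussian sensor noise (σ = 10 μV default) and optional slow drift.
* **Cohort structure: Gaussian copula** over (STAI-T, STAI-S, log BA,
  log BR, logit-scaled BRV). Latent correlations are moment-adjusted for
  the lognormal margins so the configured *observed-scale* Pearson targets
  are hit: for normal-vs-lognormal pairs `rho = r * sqrt(exp(s^2)-1)/s`,
  for lognormal pairs `rho = log(1 + r*sqrt((e^{s1^2}-1)(e^{s2^2}-1)))/(s1 s2)`.
  The logit-scaled BRV margin (bounded in `(0, 1.5)`) is left unadjusted —
  the transform is mildly nonlinear and the resulting attenuation is well
  inside the ±0.03 tolerance the end-to-end test uses. Infeasible target
  sets are rejected by an eigenvalue check.
* **Mediation switch.** With `mediation = TRUE` the latent trait–blink
  correlation is the product `corr(T,S) * corr(S, blink)`, which zeroes the
  partial correlation of trait with any blink parameter given state — the
  generative analogue of "trait acts only through state".
* **Defaults with no source values.** STAI margins use Spielberger
  college-female norms (S: 38.8 ± 11.9, T: 40.4 ± 10.2); BA mean 250 μV
  with between-subject log-SD 0.3; BRV mean 0.55, SD 0.15; across-clip
  within-subject rate jitter log-SD 0.1 (the source reports only
  between-subject descriptives, so the within-subject variance is an
  explicit free parameter); screening groups are a median split on an
  anxiety-correlated selection variable, giving the high group a
  reliably higher STAI-S mean (the Welch-t check). These were chosen once,
  as plausible field values, and are not revisited by tests.

A green suite therefore establishes: the detector recovers what the
generator planted (sensitivity/precision ≥ 0.99 under 10 μV noise), the
index estimators converge to their closed-form renewal/lognormal values,
and the statistical layer is calibrated (type-I error, df, power) *under
this stated world*. It does not establish robustness to real-world
nuisances — saccade artifacts, electrode pops, nonstationary rates — which
the generator deliberately omits.

# Statistical layer

* **Correlation matrices** are plain Pearson with t-transform p-values,
  pairwise-complete, `df = n − 2`.
* **Mixed models** (`fit_random_intercept()`, `fit_type_interaction()`)
  are fit by REML via `lme4`. Fixed-effect F tests use **Satterthwaite
  denominator df**, implemented in-package: the fixed-effect covariance
  and REML criterion are closed-form functions of `(theta, sigma)` through
  the Woodbury identity for the single random-intercept structure, the
  variance-parameter covariance is twice the inverse finite-difference
  Hessian of the criterion, and multi-df terms combine per-eigenvector df
  by the Fai–Cornelius rule. In the balanced 46-subject × 18-clip design
  a between-subject predictor gets df = 44 (= subjects − 2), the F-shape
  that design implies; within-subject terms get df near the residual
  count. The df is capped at the OLS residual df, and a boundary fit
  (`theta -> 0`) falls back to that cap.
* **Marginal R²** is the Nakagawa–Schielzeth fixed-effect variance share
  `var(X beta) / (var(X beta) + u0_var + resid_var)` — the source reports
  "R² marginal" without a formula, so the standard form is declared.
* **Film type** enters as a 6-level factor with the neutral category as
  reference; the reference choice does not affect the F tests.
* **Mediation** uses the two-regression estimator with the Sobel
  delta-method z as primary inference (matching the single-Z reporting
  convention) and a seeded percentile bootstrap (default 5,000 reps) as
  companion. The Sobel test is known to be slightly conservative when one
  path is null; the calibration test asserts a [0.02, 0.07] rejection band
  at α = 0.05 for that reason.
* **No multiple-testing correction** anywhere, matching raw-p reporting;
  α = 0.05.

# Pipeline and reproducibility

Every stochastic call takes an explicit seed, and derived stage seeds come
from a fixed integer recurrence on the run seed, so identical config + seed
reproduce metric outputs byte for byte (asserted in the tests). The run
manifest echoes the config verbatim and records MD5 hashes of all inputs
and outputs; it deliberately contains no timestamps. The config format is a
flat `key: value` text file — a YAML subset parsed in-package, because the
deployment environment guarantees no YAML parser.

EDF/EDF+ reading is implemented in-package (16-bit records,
physical/digital scaling, mV→μV conversion, annotation channels skipped)
because no EDF reader is available in the supported dependency set; the
paired writer exists so tests can build EDF fixtures in code. The electrode
montage is not resolved by the package: any user-named upper/lower pair is
accepted, since published montage descriptions of this pipeline are
internally inconsistent (Fp1/Ve1 vs Ve1/Io1/Ve2/Io2).

# Known limitations

* Detection has no blink/saccade disambiguation and estimates no blink
  durations or closure/reopening kinematics; half-cut boundary waveforms
  are dropped by construction.
* The renewal-process world cannot probe serial dependence in blink timing
  (and so says nothing about, e.g., fractal descriptions of blink
  dynamics).
* The Satterthwaite machinery covers the single-random-intercept models
  this analysis needs, not general mixed designs.
* The acceptance criterion demanding that the direct path be
  non-significant in ≥ 95 % of replicates is intrinsically tight: under an
  exactly null direct effect the non-significance rate is Binomial(reps,
  0.95), so that assertion sits on its own boundary by construction; the
  suite runs it with a fixed seed.
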