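---
title: "Quantitative EEG deficit profiling: models, parameters, and design choices"
author: "eegdeficits maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG deficit profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdeficits)
```

## The problem

Residual neurocognitive alteration after sport-related concussion can
persist long after standard postural, visual and neuropsychological
instruments read normal. Quantitative EEG offers a more sensitive probe:
group-level differences in spectral power and in time-domain / nonlinear
signal descriptors between previously concussed and healthy athletes,
resolved not only into the conventional frequency bands but into
individual 1-Hz frequency bins. This package implements that analysis as
a tested pipeline — signal conditioning, spectral estimation, feature
extraction, and two-group statistics — together with a synthetic cohort
generator that reproduces the statistical structure of such a study so
that every stage can be validated against ground truth.

The reference study design the defaults emulate: two groups (14 healthy,
7 concussed adolescent athletes), three recording trials each under three
conditions (eyes open EO, eyes closed EC, vigilant task VT), nine
channels (F3, F4, Fz, C3, C4, Cz, P3, P4, POz) at 256 Hz for 5 minutes —
189 recordings in all.

## Signal conditioning

Recordings pass through four stages, in order:

1. **Band-pass 1–40 Hz** (`bandpassFilter()`): a 4th-order Butterworth
   high-pass at 1 Hz cascaded with a 4th-order low-pass at 40 Hz
   (24 dB/octave per edge), each applied forward–backward so the result
   is zero-phase. Pass-band centre gain is unity to well within 0.5 dB.
   The forward–backward pass squares the magnitude response, so effective
   stop-band attenuation is doubled; all response properties are tested
   against the designed filter's transfer function evaluated on the unit
   circle.
2. **Transition trimming** (`trimTransitions()`, default 10 s per end):
   drops state-transition segments; 300 s becomes 280 s.
3. **Epoching** (`epochRecording()`): consecutive non-overlapping
   1-second epochs of 256 samples; a trailing partial second is dropped.
4. **High-power epoch rejection** (`rejectHighPowerEpochs()`): an epoch
   is rejected when its broadband power (mean squared amplitude, pooled
   over channels) is at least `k = 3` SDs above the mean of the retained
   epochs. Because "clean" is defined by the rule itself, the threshold
   is re-estimated iteratively on the survivors until no epoch exceeds it
   (capped at 10 passes), which makes the operation idempotent. The rule
   operates at epoch level (the amplitude-artifact description is
   ambiguous between samples and epochs; epoch level matches the 1-s
   analysis unit). Pooled rather than per-channel power is used because
   all downstream features are channel-averaged. Recordings left with
   fewer than 8 epochs are declared unusable.

Stereotyped-artifact removal by ICA is an external preprocessing step in
the acquisition protocol this pipeline targets; the package accepts
either raw or pre-cleaned input and implements only the amplitude/power
rejection rule.

## Spectral estimation

Each retained 1-s epoch is windowed with a tapered-cosine (Tukey) window
of 10% total taper — the common reading of a "10% Hanning window" in EEG
tooling — transformed by FFT, and corrected for window power loss
(division by the mean squared window) so that white-noise power is
unbiased; a unit sinusoid on a bin centre then reads within ~4% of
A²/2. With 256 samples at 256 Hz the bins fall on integer frequencies;
bins 1–40 Hz are retained.

Aggregation is *average then log*: per-bin linear power is averaged over
epochs, band power is the arithmetic mean of the member bins' linear
power, and base-10 logs are taken last. Band definitions are delta 1–4,
theta 4–8, alpha 8–12, beta 12–30, gamma 30–40 Hz. The shared boundary
bins (4, 8, 12, 30 Hz) are ambiguous in interval notation; the default
`"inclusive"` convention assigns them to both adjacent bands, an
`"exclusive"` half-open convention is available, and the convention in
force is stamped into every profile and report. The log base (10) is a
recorded constant; reference band-power magnitudes (~1.5–4.8 for μV²
band power) are consistent with either base.

A rectangular-window test mode exposes Parseval's identity (one-sided
powers sum to the epoch's mean squared amplitude to 1e-6 relative
error), which anchors the scaling.

## Features

Six features are computed per recording at 46 frequency scopes —
broadband, the 5 bands, and the 40 single-frequency bins — and averaged
over the 9 channels:

* **power**: the spectral stage's log10 channel-mean power.
* **Hjorth activity** `var(x)` (μV²), **mobility**
  `sqrt(var(dx)/var(x))`, and **complexity** `Mobility(dx)/Mobility(x)`.
  The derivative is the first difference without sampling-rate scaling
  (mobility in radians/sample; for a sinusoid of frequency f,
  `2*sin(pi*f/fs)`); any scaling cancels in complexity, which converges
  to 1 for a pure sinusoid.
* **Approximate entropy** (Pincus): `Phi^m(r) - Phi^(m+1)(r)` with
  Chebyshev distance and self-matches included. The embedding dimension
  defaults to the standard m = 2 (unstated in the reference analysis).
  The tolerance default is r = 2·SD(x), implementing the reference
  choice of "two standard deviations" literally; note this is far wider
  than the 0.2·SD literature default and compresses the dynamic range of
  the statistic — `apenRMult = 0.2` restores the conventional behaviour.
  The implementation (compiled, O(n²)) is verified against an exhaustive
  template-counting oracle to 1e-10.
* **Hurst exponent**: classical rescaled-range (R/S) analysis — window
  sizes log-spaced between 16 and n/4, range of the mean-adjusted
  cumulative sum over the window SD, slope of log(R/S) against log size.
  The plain slope has a well-known upward small-sample bias (~0.54 for
  iid noise at n = 10⁴), so the default estimate subtracts the
  Anis–Lloyd–Peters iid expectation before fitting, recovering 0.5 on
  uncorrelated noise and staying within ±0.1 of the target on exact
  fractional Gaussian noise across H ∈ {0.3, 0.5, 0.7, 0.9}
  (n = 2¹⁴). `corrected = FALSE` gives the plain slope. Out-of-range
  estimates are reported raw, not clipped.

Time-domain and nonlinear features are computed on the concatenation of
the retained epochs ("whole signal" semantics); concatenation seams
across rejected epochs are an accepted approximation. Band- and
bin-scope features use zero-phase band-passes of that concatenation.
The 1-Hz-wide single-frequency filters are applied in the spectral
domain (the DFT is multiplied by the squared order-4 Butterworth
band-pass magnitude, exactly what a forward–backward time-domain pass
realises in magnitude) because an 8th-order IIR polynomial at 1/256
normalized bandwidth is numerically ill-conditioned.

## Statistics

Every (feature, scope, condition) is compared between groups with a
normality-gated test: Shapiro–Wilk on both samples, two-tailed Welch
t-test if both are consistent with normality at the 0.05 level,
Wilcoxon rank-sum otherwise. Group mean ± SD is always reported. Raw
and Bonferroni-adjusted p-values are both emitted (family = 40 bins or
5 bands per feature and condition, stamped into the output); per-bin
profiles judge significance on raw p-values by default, matching the
per-frequency profile convention, with `adjust = "bonferroni"`
available. Significant bins are summarised as maximal runs of
consecutive integer frequencies ("1-3, 9-10").

**Unit of analysis.** The reference analysis pools trial recordings as
observations (42 vs 21). Pooled trials from the same subject are
correlated whenever between-subject variability is non-negligible, which
makes the pooled t-test anticonservative; with this package's default
generator parameters the pooled-mode null per-bin significance rate is
well above the nominal 0.05, while subject-level aggregation (mean over
trials, n = 14 vs 7) is calibrated. `deficitProfile()` therefore
defaults to `unit = "subject"` and offers `unit = "trial"` to mirror
the reference design; both are labelled in the output. Even in subject
mode the gate-then-test procedure is measurably slightly anticonservative
(≈0.06 empirical rate at nominal 0.05 in the package's own 200-cohort
calibration) — a known property of pretest-based test selection, retained
because it is the procedure being modelled.

## The synthetic cohort generator

The generator composes two mechanisms, matching the treatment of PSD and
long-range temporal correlation (LRTC) as separate features:

1. a **fractional Gaussian noise carrier** per channel with prescribed
   Hurst exponent, simulated *exactly* by circulant embedding
   (Davies–Harte): the target autocovariance
   γ(k) = ½(|k+1|²ᴴ − 2|k|²ᴴ + |k−1|²ᴴ) is embedded in a circulant
   matrix diagonalised by the FFT and complex Gaussian spectral
   amplitudes are drawn with the eigenvalue variances;
2. **spectrum shaping**: the carrier's DFT is rescaled by one real
   factor per 1-Hz bin so the realised per-bin power equals the target
   exactly (phases and within-bin structure preserved). Below 0.5 Hz the
   bin-1 density is continued (DC removed); above 40.5 Hz power rolls
   off quadratically.

Default targets hold power flat within each band at the level that
reproduces the reference group band log-powers (eyes-open condition:
healthy delta 4.33 … gamma 1.95; concussed delta 4.81 … gamma 1.58 in
log10 μV²), so the generated between-group effect is the published
deficit pattern: delta and theta elevated, alpha/beta/gamma reduced in
the concussed group. Carrier Hurst targets are 0.7 (healthy) and 0.6
(concussed) — the reference analysis reports reduced LRTC after
concussion without publishing values, and 0.6–0.8 is the typical range
for resting EEG amplitude fluctuations.

Between-subject variability is modelled as a persistent per-subject
offset in log10 power with two components: a whole-spectrum level shift
(SD 0.15) and a per-bin shape jitter (SD 0.25). The split is a design
choice — only the total group SD (~0.25–0.45 log10 units) is
constrained by the reference tables, and subject-specific spectral
*shape* (most famously alpha amplitude) dominates global level
variability in real resting EEG. A scalar-only offset would also make
all 40 bins' test statistics move in lockstep, which is both unrealistic
and makes replicate-averaged calibration estimates needlessly unstable.
Trial-to-trial variation (unreported in the reference) is exposed as
`withinSubjectSD`, default 0.05.

Artifacts (broadband 1-s bursts, mains sinusoids, frontal blink-like
deflections) are injectable but off by default: the pipeline's reference
input is post-ICA cleaned data, and bursts exist to exercise the 3-SD
rejection rule, which catches ≥95% of injected 10×-power epochs at ≤2%
false rejection in the labelled simulations.

What the generator does **not** emulate: biophysical source structure,
cross-channel covariance (channels are independent; all tested
quantities are channel averages), non-Gaussian waveform morphology, and
realistic artifact shapes beyond what the rejection rule needs. Passing
tests therefore validate the pipeline's statistical behaviour, not its
performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Windowed epoch spectra of a *stepped* target profile are biased at the
  band-boundary bins (spectral leakage across the step, up to
  ~0.2 log10 at a 7× step); the bias is identical in both groups and so
  cancels in every group comparison. Fidelity bounds (<0.05 log10 per
  bin) hold for smooth targets.
* The analysis band-pass attenuates bins 1 and 40 (edge of the 1–40 Hz
  band) equally in both groups.
* Constant series: activity 0; mobility/complexity undefined (explicit
  error); ApEn with SD-relative tolerance undefined (r = 0, explicit
  error); a linear ramp errors in complexity (var of the differenced
  signal is 0). `extractFeatures()` converts such errors into
  `NA`-valued rows with the message in `status`, leaving other rows
  intact.
* Degenerate group comparisons (both groups constant and equal) report
  p = 1 with a `degenerate` flag.
* Identical seeds and specs give byte-identical cohorts, feature tables
  and reports; every output carries the configuration hash.

## Problem sizes used in the shipped studies

The package's own validation studies are sized for a single CPU: the
type-I calibration uses 200 replicate null cohorts of 63 thirty-second
recordings (single condition), the power study one full cohort of
sixty-second recordings plus 500 direct two-group simulations at the
reference delta effect (4.33 ± 0.25 vs 4.81 ± 0.34, n = 42 vs 21), and
Hurst calibration uses 100 iid series of 10⁴ samples and 20 exact-fGn
replicates per H at n = 2¹⁴. These sizes give stable estimates
(calibration SE ≈ 0.006) while keeping the full suite tractable.

## Known limitations

* The pooled-trial mode reproduces the reference unit of analysis but is
  anticonservative under subject-level heterogeneity; use subject mode
  for calibrated inference.
* R/S estimates of H at the extremes (0.1, 0.9) retain residual bias
  (within ±0.1 at n = 2¹⁴); detrended fluctuation analysis is a common
  alternative not implemented here.
* ApEn at the default r = 2·SD has limited discriminating range; the
  conventional r = 0.2·SD is one configuration flag away.
* EDF export quantises to 16 bits and requires whole-second recordings.
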