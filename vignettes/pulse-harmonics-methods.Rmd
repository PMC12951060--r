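---
title: "Inter-hand pulse wave harmonics and coronary lesion severity: methods"
author: "pulseharmonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-hand pulse wave harmonics and coronary lesion severity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseharmonics)
```

## The problem

Fingertip photoplethysmography (PPG) records the arterial pressure-wave
surrogate at the two index fingers simultaneously. Several cardiovascular
conditions, coronary artery disease among them, are associated with
left–right asymmetry of this waveform. This package implements a complete,
reproducible version of an analysis that asks whether inter-hand
differences of *harmonic* waveform indices predict severe coronary lesion
complexity, operationalized as a SYNTAX score of 22 or more — the
threshold clinical guidelines use to distinguish intermediate/high
anatomical complexity.

Because the underlying clinical recordings are not publicly available,
the package is exercised end to end on a synthetic cohort generator whose
composition mirrors the clinical study it emulates: 249 male subjects
(32 events) and 99 female subjects (13 events). Every quantity reported
by the analysis is computed by the package at run time.

## Harmonic decomposition of a beat

Each recording is segmented into beats (pulse periods). A beat resampled
onto $L$ uniform points is decomposed as

$$f(x) = A_0 + \sum_{n=1}^{11} A_n \cos\!\left(\frac{2\pi n x}{L} - \theta_n\right),$$

so $A_0$ is the beat mean ("order 0"), $A_n \ge 0$ the amplitude and
$\theta_n \in (-\pi, \pi]$ the (delay-convention) phase of the $n$-th
harmonic of the beat fundamental. Harmonic orders up to 11 are retained:
on physiological pulse waves these orders carry more than 98 % of the
spectral energy, which the package verifies by Parseval's theorem on the
full discrete spectrum (`beat_energy_spectrum()`); for the default
synthetic beat the retained fraction is essentially 100 %.

Per-beat energies use the Parseval decomposition
$E_0 = A_0^2 / \overline{f^2}$ and $E_n = A_n^2 / (2\,\overline{f^2})$,
so the fractions over all orders of the discrete spectrum sum to exactly 1.

## Record-level indices

With $A(n,m)$, $\theta(n,m)$, $E(n,m)$ the decomposition of beat
$m = 1,\dots,M$, the record-level indices are

* amplitude $C_n = \operatorname{mean}_m\, A(n,m)/A(0,m)$,
* phase $P_n$ = circular mean of $\theta(n,\cdot)$,
* energy $D_n = \operatorname{mean}_m E(n,m)$,

with beat-to-beat coefficients of variation $C_n^{CV}$, $P_n^{CV}$,
$D_n^{CV}$ (sample SD divided by the mean). Three numerical choices are
worth stating because the source figure defining the original formulas is
not available in machine-readable form, making them genuinely open design
points:

* **$A_0$ normalization.** Raw PPG amplitude depends on sensor gain and
  contact pressure, which differ between hands. Normalizing each beat's
  amplitudes by its own $A_0$ makes $C_n$ dimensionless and inter-hand
  comparable; it also fixes $C_0 \equiv 1$ and $P_0 \equiv 0$, so those
  orders are dropped from the candidate predictors automatically.
  Scale invariance (multiplying a record by any positive constant leaves
  every index unchanged) is enforced by test.
* **Circular phase handling.** Phases are angles; a plain linear CV is
  ill-defined for them. $P_n$ is the circular mean, and $P_n^{CV}$ is the
  linear CV computed after re-branching each beat's phase to within
  $\pi$ of that mean. When the mean phase is numerically zero the CV
  denominator is guarded and the order flagged.
* **Energy as a Parseval fraction.** $D_n$ is the fraction of the beat's
  power carried by order $n$, consistent with the energy-concentration
  property above and bounded in $[0,1]$.

The predictors are the left-minus-right differences
$\Delta C_n, \Delta P_n, \Delta D_n, \Delta C_n^{CV}, \Delta P_n^{CV},
\Delta D_n^{CV}$ and their absolute values. Phase differences are wrapped
to $(-\pi, \pi]$ before the absolute value, so hands whose phases
straddle the branch cut difference the short way round. In CSV output the
Greek symbols map to portable names: $\Delta \to$ `d`,
$|\Delta| \to$ `absd` (e.g. `dC6`, `absdC9CV`).

One caveat the test suite encodes: beats are analyzed in windows anchored
at the detected foot, so recovered phases equal the generating phases
only up to a linear-in-order ramp $2\pi n s/L$ ($s$ the foot offset).
Amplitudes and energies are shift-invariant; shift-invariant phase
comparisons use $\theta_n - n\,\theta_1$. For inter-hand differences the
ramp largely cancels because both hands share cardiac timing, but
high-order $\Delta P_n$ retains sensitivity to differential foot
placement — a genuine property of beat-anchored phase features, not an
artifact the package hides.

## Beat segmentation

The original analysis presumes beat-wise decomposition but specifies no
segmentation algorithm, so the package uses a standard robust scheme:
a zero-phase 4th-order Butterworth low-pass at 10 Hz, candidate systolic
upstrokes as local maxima of the smoothed derivative (non-maximum
suppression at the minimum admissible period), and the beat foot as the
smoothed local minimum preceding each upstroke. Feet within 0.35 s of the
record edges are discarded — zero-phase filtering has warm-up and tail
transients there, and partial edge beats must be dropped anyway. Beats
with periods outside [0.3, 2.0] s (200–30 bpm) or peak-to-peak amplitude
more than 4 MAD from the record median are flagged rejected; at least 5
accepted beats are required to summarize a record.

Resampling onto the fixed analysis grid ($L = 256$, a power of two with
comfortable Nyquist margin above order 11) is band-limited (discrete
Fourier) by default: it is exact for periodic beats whose content lies
below the input Nyquist order, which the generator produces and the
round-trip tests exploit at $10^{-9}$ tolerance. Cubic-spline resampling
is available for signals with appreciable inter-period discontinuity.

## The synthetic cohort generator

The generator is first-class, tested code. Each subject's ground truth is
a 12-order harmonic template (amplitudes and phases), per-order additive
asymmetry offsets, beat-to-beat jitter scales, and noise levels.

* **Beat template.** A time-domain morphology — baseline plus a dominant
  systolic Gaussian bump and a smaller, wider dicrotic bump — whose first
  12 harmonics form the default template. The shape gives a dominant
  order 1, monotone amplitude decay above order 6, a dicrotic inflection
  from the low orders, and ≥ 98 % of spectral energy in orders 0–11.
  The emulated study publishes no waveform parameters; these were chosen
  once for physiological plausibility.
* **Acquisition defaults** (200 Hz, 60 s per hand, 70 bpm) are package
  assumptions: the study states only that the measurement takes about one
  minute. All sampling-rate/duration/heart-rate settings are explicit
  configuration.
* **Beat-to-beat variability.** Multiplicative lognormal amplitude jitter
  (mean 1), wrapped-normal phase jitter, lognormal period jitter — the
  simplest strictly-positive/circular families. Both hands share the
  cardiac realizations (one heart drives both); additive white noise and
  slow sinusoidal baseline wander (0.05–0.15 Hz) are drawn per hand.
  Records start mid-beat so the segmenter sees partial edge beats.
* **Disease link.** Event subjects (SYNTAX ≥ 22) draw Gaussian additive
  offsets on the amplitudes of orders {2, 3, 5, 6, 9, 10} (SD 0.3 of the
  order's template amplitude) and the phases of orders {1, 8, 10}
  (SD 0.3 rad) — the orders the emulated study's final models feature.
  Non-event subjects draw from the same distributions at half scale
  (`null_fraction = 0.5`): a baseline physiological inter-hand asymmetry
  that disease amplifies. With near-zero instead of half-scale baseline
  offsets the two classes separate almost perfectly and every
  default-scale model degenerates into separation; the 2:1 ratio was
  chosen once so the default study conditions show the moderate
  discriminability regime the method is meant for. The offset is defined
  as the target left-minus-right difference (subtracted from the right
  hand), so a configured positive order-6 amplitude offset produces a
  positive $\Delta C_6$.
* **Outcome scores.** SYNTAX scores are drawn uniformly on [0, 21.5] for
  non-events and [22, 45] for events, rounded to 0.5 (two-reader
  averaging yields half-integer scores). Event counts are exact by
  default (32/249 male, 13/99 female); a per-sex prevalence mode is
  available. Ages are normal around the study means (59.8 male,
  67.5 female).

What the generator deliberately does **not** emulate: hemodynamic
propagation (no arterial-tree model), motion artifacts, contact-pressure
drift, arrhythmia, or any angiographic imaging — SYNTAX scores are
assigned directly. Passing tests therefore demonstrate the correctness
and internal consistency of the pipeline under a known generative model,
not clinical validity on real recordings.

## Models and selection

Per sex stratum, logistic regression predicts SYNTAX ≥ 22 from the
difference features. Fitting is maximum likelihood (IRLS) with an always
estimated intercept; inference is Wald (SE, t statistic, two-sided normal
P), matching the reporting schema Coefficient / SE / tStat / P Value.
Complete separation is detected by the maximum-likelihood nonexistence
criterion — the fitted linear predictor strictly ranking every event
above every non-event — and reported as an explicit error rather than a
silent divergence. Singular designs fail naming the collinear columns.

Variable selection minimizes AIC ($2k - 2\ell$, $k$ counting the
intercept) by three greedy searches: forward addition, backward
elimination (falling back to forward, with a warning, when the full
candidate model is unfittable — the usual case when candidates outnumber
events), and bidirectional stepwise. Moves are accepted only while AIC
strictly decreases; ties break toward removals, then lexicographically by
variable name, so every search is deterministic. Searches never move to
models that are separated, non-converged, or whose information matrix is
numerically singular (undefined Wald SEs). The minimum-AIC model across
the three searches wins, ties broken toward fewer parameters. The
candidate pool contains both signed and absolute differences (the
emulated study's final models mix the two); the collinearity this invites
is tolerated by the greedy searches. A post-hoc P < 0.05 retention filter
is **not** applied: the study's own tables keep P = 0.06–0.11 terms, so
AIC minimization is taken as the operative rule.

The events-per-variable (EPV) advisory warns — never blocks — whenever
more than one parameter per ten events is estimated. At the default
study conditions the advisory fires in both strata, by design: 136
candidates against 32 (male) and 13 (female) events is exactly the
overfitting regime the emulated analysis operated in, and the default
run shows what greedy AIC does there (many selected variables, inflated
apparent discrimination) while bootstrap validation quantifies the
optimism.

## Validation

* **Discrimination.** Apparent AUC by trapezoidal integration of the
  empirical ROC; this equals Mann-Whitney pairwise concordance with
  half-credit ties, an identity tested to $10^{-12}$ against brute-force
  pair counting and cross-checked against pROC.
* **Calibration.** Hosmer-Lemeshow with equal-count risk deciles
  (ties to the lower group), $\chi^2$ on $g - 2$ degrees of freedom
  (in-sample convention), plus the decile calibration curve. Its size is
  verified by simulation on correctly specified fitted models
  (rejection rate held within 3–8 % at the 5 % level over 200
  replicates).
* **Internal validity.** Bootstrap: each resample refits the
  *fixed* selected-variable set and scores the original sample; the mean
  resample AUC and the 2.5/97.5 percentile interval are reported
  (percentile, not BCa, matching the emulated study's bracketed
  intervals). Re-selection inside resamples is not done — the study gives
  no sign of it — which is a known source of residual optimism and is
  reported as such. One-class resamples are redrawn and counted;
  separated resample fits are used with capped coefficients. The default
  is 2000 resamples; the test suite uses smaller counts (the vignette's
  problem sizes are package choices: 200 resamples for the optimism
  property, 40–60 for determinism checks).

## Problem sizes and determinism

Unit and property tests run the full chain at reduced scale (10–20 s
records, cohorts of tens of subjects); the end-to-end study check runs
the full default configuration (348 subjects, 60 s records, 2000
resamples). Every stochastic stage takes an explicit integer seed, and
one global seed drives cohort generation, per-subject waveforms (seed +
subject index) and the bootstrap, so reports are reproducible to the
byte. Re-running the analysis from a serialized feature table reproduces
identical models.

## Known limitations

* Synthetic validation only: no real PPG recordings are available, so
  agreement with the emulated study's coefficient values cannot be (and
  is not) claimed — its headline numbers come from a 348-patient clinical
  dataset that is not public.
* The exact normalizations of the original index formulas live in a
  figure unavailable as text; the $A_0$-normalized, Parseval-based
  reconstruction here is self-consistent but may differ from the original
  in per-order scale factors (which a logistic model absorbs into
  coefficients).
* Beat-anchored phase indices are sensitive to differential foot
  placement at high orders, as discussed above.
* The original study's apparent AUC is quoted as 0.88 in its results and
  0.89 in its abstract for the male model; the report schema here carries
  a single apparent AUC and takes no side.
* Single contact pressure per hand is assumed; the original device may
  aggregate across pressures.
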