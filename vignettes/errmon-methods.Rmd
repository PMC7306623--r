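---
title: "Methods: performance-monitoring analysis of Go/Nogo EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: performance-monitoring analysis of Go/Nogo EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errmon)
```

## The problem

In a speeded Go/Nogo task, a frequent stimulus class demands a button press
and a rare class demands withholding it. Failed withholds are errors of
inhibition, and participants can signal that they noticed an error with a
delayed second press. Performance monitoring leaves three kinds of traces in
such a session: behavioral adjustments (post-error slowing), response-locked
ERP components over fronto-central and central midline sites (the error
negativity Ne/ERN and its correct-trial counterpart CRN; the error positivity
Pe and its counterpart Pc), and stimulus-locked components reflecting
conflict processing and attention (N2, P3). `errmon` implements the complete
analysis chain for such experiments — behavioral scoring, ERP quantification
after a current source density transform, sliding-window multivariate
decoding with a shuffled-label null, and the group statistics layer — plus a
calibrated synthetic-cohort generator, so the whole pipeline can be
exercised and validated end to end without access to clinical recordings.

The emulated study design is a two-group clinical comparison (stroke
patients versus matched controls, 24 and 32 subjects), 360 trials per
session in six blocks with an 80:20 go/nogo ratio, colour discrimination as
the difficulty manipulation (one nogo colour among eight), a ~20% nogo error
rate, error signaling inside a 1200–2000 ms window after stimulus onset, and
EEG from 61 scalp electrodes (plus 4 EOG) at 500 Hz.

## Behavioral model

Each trial is classified into exactly one of six categories: `correct_go`,
`miss_go`, `incorrect_go` (a go response followed by an error-signaling
press), `correct_withhold`, `detected_error`, `undetected_error`. A second
press counts as error signaling only inside the 1200–2000 ms window; earlier
or later second presses are ignored, so such errors count as undetected.
This strict reading of the signaling rule is configurable
(`classify_trials(signaling_window = )`).

Post-error slowing is the one-trial-back contrast ΔPES = PES − PCS, where
PES is the median RT of correct go trials immediately preceded (within the
same block) by a detected error and PCS the median RT of correct go trials
preceded by a correct go. Trials following misses, undetected errors or
incorrect-go trials enter neither term. This is the strictest reading
consistent with reporting ΔPES "after detected errors"; since sessions with
no qualifying pair yield `NA` (never 0), subject attrition in the ΔPES
analysis arises naturally.

Inclusion criteria: ERP analyses require at least 6 trials of each analysed
response type (correct go, detected error); decoding requires at least 10
error trials with detected and undetected errors collapsed.

### The synthetic agent

`simulate_behavior()` draws RTs from a shifted lognormal,
`rt = 150 + exp(N(log 266, 0.28))` ms by default (median ≈ 416 ms). Error
RTs use the same draw plus a constant negative shift (−66 ms default), which
reproduces the observed ordering (errors faster than correct responses)
with a single parameter instead of an evidence-accumulation model. The go
trial immediately after a nogo error receives a `pes_increment` (86 ms
default) on its draw — exactly the quantity the one-trial-back ΔPES contrast
estimates, so generator and estimator are linked by construction and the
recovery test is meaningful. Default calibration anchors: 20% nogo error
rate (the task's design target), 78% detection rate, and the RT values
above. The packaged group profiles
(`default_group_profiles()`) instead encode the published group-level
behavioral means (patients: 22.1% errors, 77.8% detection, 433 ms baseline
RT, −81 ms error shift, 65 ms slowing; controls: 24.3%, 78.3%, 416 ms,
−66 ms, 86 ms).

## EEG forward model

`synthesize_recording()` inserts, per trial, each applicable component as a
Gaussian-windowed half-sine: amplitude × `sin(π(t−t₀+w/2)/w)` ×
`exp(−(t−t₀)²/(2(w/4)²))` on a support of width `w`. This waveform is
smooth, unimodal, and equals its nominal amplitude exactly at its nominal
latency, so peak recovery is analytic: in the noise-free limit every
embedded amplitude and latency is recovered exactly by the measurement
code (the test suite asserts this identity). Topographies fall off as a
Gaussian of angular distance from the peak electrode (FCz for N2/P3/Ne/CRN,
Cz for Pe/Pc). Condition routing: N2/P3 on every stimulus with separate
go/nogo amplitudes; Ne/Pe on error responses; CRN/Pc on correct responses.
Latencies are jittered per trial (SD 8 ms by default).

Noise is 1/f^α background (α = 1, 8 μV RMS per channel by default),
blinks as smooth 300 ms deflections entering the vertical EOG at 150 μV and
propagating to the scalp proportionally to the squared anterior coordinate
(maximum factor 0.4), and optional 50 Hz line noise. The original study
measured real EEG and specifies no forward model; all synthesis choices here
are the package's own stand-ins, chosen for analytic tractability. The
component amplitudes are calibrated against the published group means,
which were reported in CSD units (μV/m²); the generator embeds the same
numbers as μV templates, so recovered voltage-domain values are directly
comparable to the component specification but not to the published table
values (which additionally depend on the CSD scaling).

What passing tests on this generator do show: the measurement, decoding and
statistics code implements its definitions correctly, recovers known ground
truth, and is calibrated under the null. What they cannot show: robustness
to real artifact taxonomies (muscle, drift, channel pops), realistic
single-trial ERP variability, or undetected-error morphology (undetected
errors reuse the error templates; modeling them as a distinct morphology is
out of scope).

Three timing details matter for exactness. Latencies land on the 2 ms
sample grid (odd-millisecond latencies are recoverable only to the nearest
sample — the published patient N2 latency of 303 ms is carried in the
default patient profile and recovers as 302/304 ms). Stimulus- and
response-locked components overlap in time on trials with a response (as in
real EEG), so exact-recovery tests synthesise one lock type at a time;
correct withholds never contain response-locked activity and are exact in
any mixture. Component supports must not reach into the baseline window.

## Preprocessing

The stage order is enforced (calling out of order is an error, not a
warning): EOG regression on the continuous recording → epoching with
baseline correction → amplitude-based artifact rejection → current source
density.

* **Ocular correction** is whole-recording least-squares regression of every
  scalp channel on all EOG channels plus an intercept. The blink-triggered
  algorithm used by the original acquisition chain is cited but not
  described there; plain regression is the simplest faithful stand-in and is
  exact when propagation is truly linear.
* **Epochs** are half-open windows `[t_min, t_max)` with time 0 at the lock
  sample: stimulus-locked `[−100, 800)` (450 samples), response-locked
  `[−100, 600)` (350 samples), decoding `[−100, 300)` (200 samples = 40 × 5).
  The 100 ms before the lock event is the baseline. Epochs that would cross
  the recording edge are flagged `rejected (edge)`, never silently dropped.
  Only scalp channels enter epochs; EOG is excluded from all analyses.
* **Artifact rejection** flags epochs whose scalp samples *strictly* exceed
  ±150 μV ("exceeding" read literally, so samples touching the threshold are
  kept; both reading and threshold are configurable). Kept epochs are
  bitwise untouched.
* **Current source density** is the spherical-spline surface Laplacian:
  per time sample, a regularised spline interpolation of the potentials on
  the unit sphere is solved with a zero-sum constraint on the coefficients,
  and the output is the negative surface Laplacian scaled by `head_radius⁻²`
  (μV/m²). The transform is linear, maps constants to zero, and is invariant
  to re-referencing (both tested to tight tolerance). Its parameters are not
  stated in the emulated study; the package fixes the common literature
  defaults m = 4, 50 Legendre terms, λ = 1e−5, head radius 0.09 m, all
  configurable and recorded with the output. The analytic validation uses a
  degree-2 spherical harmonic, whose surface Laplacian is `l(l+1)/r²` times
  itself; this identity holds for the exact (unregularised) spline, so the
  oracle test sets λ = 0 — the default λ trades a ~2% bias for noise
  robustness. CSD is applied to epochs (whether the original applied it to
  continuous or epoched data is unstated; for a linear transform the
  difference is only the baseline path). Decoding uses CSD-transformed
  epochs by default with a configuration switch to voltage, making an
  assumption the original leaves implicit explicit and reversible.

## ERP quantification

Per subject and condition, kept epochs are averaged pointwise
(`condition_average()`); measures are taken on the average, not on single
trials. Peaks are the global extremum inside a closed window (the "most
negative/positive peak" reading; deterministic, ties to the earliest
sample, latency at 2 ms resolution): N2 200–350 ms and P3 350–500 ms at
FCz; Ne/CRN 0–150 ms at FCz; Pe/Pc 150–300 ms at Cz. The area under the
curve is the trapezoidal integral of the *signed* waveform over the same
windows (whether the original rectified is unstated; signed is consistent
with comparing negative and positive areas, and rectification is a flag
away). Peak-to-peak subtracts the negativity's amplitude/latency from the
positivity's. Difference scores (nogo − go for stimulus-locked, error −
correct for response-locked) feed the covariate correlations. A 10 Hz
display filter exists in the plotting helpers only and never touches
measurement.

## Decoding

Response-locked epochs `[−100, 300)` are tiled by 40 non-overlapping 10 ms
windows of 5 samples; each window's feature vector concatenates all scalp
channels channel-major (61 × 5 = 305 features). Detected and undetected
errors are collapsed into one class and balanced against correct go trials
by seeded subsampling of the majority class (minimum 10 per class). The
classifier is a linear soft-margin SVM with C = 1, solved to a tight
tolerance so solutions are reproducible; accuracy is estimated by 10-fold
cross-validation repeated 10 times (100 train/test analyses per window,
averaged). Folds are class-stratified — the plain 90/10 random splits of
the emulated procedure can produce one-class folds at these trial counts —
which is the one deliberate deviation in this stage. The shuffled-label
null repeats the identical procedure with the label vector permuted
independently before every cross-validation step; the folds are
re-stratified on the permuted labels, because stratifying on the real
labels leaves the permuted training sets imbalanced and drags the null
measurably below chance (a majority-vote artifact at small trial counts).
This gives one empirical chance value per subject and window (one value, not a full permutation
distribution — the emulated description is ambiguous; the group-level
paired test only needs the value). Group statistics per window: paired t
(real vs shuffled) within each group, pooled t between groups on real
accuracies, at the Bonferroni-adjusted alpha 0.05/40 = 0.00125.

Seed policy: one master seed expands deterministically into per-subject,
per-stage, per-window streams (`derive_seed()`), so a full cohort decode is
bit-reproducible and no two streams collide.

## Statistics

* Independent t-tests are pooled-variance Student (df = n₁+n₂−2), matching
  the degrees-of-freedom convention of the emulated reports; Welch is not
  the default. Degenerate inputs (zero pooled variance) return 0 or signed
  infinity with a flag instead of erroring, so window-wise sweeps never
  crash.
* The JZS Bayes factor integrates the effect size over a zero-centred
  Cauchy prior (scale 0.707 by default) via adaptive quadrature over the
  auxiliary inverse-χ² mixing variable; effective N is n₁n₂/(n₁+n₂)
  (independent) or the pair count (paired). The implementation is verified
  against an independently authored reference implementation to six digits.
* The 2×2 mixed ANOVA uses the classical split-plot decomposition; with two
  within levels sphericity is trivial (ε = 1) and the
  Greenhouse–Geisser machinery (`gg_epsilon()`) exists for k > 2 designs.
  Two algebraic identities are tested: the group effect equals the squared
  pooled t on subject means, and the interaction equals the squared pooled
  t on difference scores.
* Correlations are Pearson with the exact t-transform p-value; the clinical
  correlation sweep uses the adjusted alpha 0.025. Patients are split into
  sub-acute (4–28 days post-stroke) and chronic (> 28 days) phases.
* Bayesian repeated-measures ANOVA factors are out of scope (they require
  g-prior model averaging disproportionate to their role); only t-design
  Bayes factors are computed.

## Problem sizes used in validation

The test suite validates on reduced but structurally faithful problems: the
9-electrode sub-montage for pipeline mechanics (the full 61-channel montage
for everything CSD- and feature-dimension related), 12–240 trial sessions,
6-subject pipeline cohorts, 60 seeded datasets for decoder chance
calibration, 200 replicate null cohorts for the family-wise error check,
and 100 sessions for the generator-calibration and slowing-recovery
checks. Tolerances on stochastic checks are stated in Monte-Carlo standard
errors of the quantity under test, never as free constants.

## Known limitations

Undetected errors share the detected-error ERP morphology. The ocular
stand-in is linear regression, not the cited blink-triggered method. The
montage is an idealised spherical cap, not digitised positions. The
decoder's fold stratification deviates (documented above). Single-process
execution only.
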