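---
title: "Models and methods behind emgmpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emgmpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgmpr)
```

This vignette documents the scientific model behind each pipeline stage, the
parameters that matter (with units and defaults), the design choices made
where the design was genuinely open, and — importantly — what the synthetic
data generator does and does not emulate, hence what a green test does and
does not establish.

## 1. The recording protocol and its synthetic stand-in

The package models a standard non-weight-bearing lower-limb MPR session:
eight movements, each recorded as three consecutive 4 s contractions
followed by 4 s of rest, 16 channels sampled at 2 kHz with 16-bit
resolution after a gain of 200. `protocol_spec()` carries these constants;
`session_duration_s(protocol_spec())` is 192 s and a session records
8 × 3 = 24 contraction ranges, stored as 0-based half-open sample intervals
so all trimming and windowing arithmetic is exact integer arithmetic.

### The activation model

Real subjects produce movement-specific spatial patterns of muscle
activity across the electrodes. The generator encodes this as an
`n_movements × n_channels` matrix of weights in [0, 1]
(`make_activation_matrix()`). A single scalar, `overlap`, interpolates
linearly between a seeded set of clearly distinct patterns (`overlap = 0`,
pairwise row cosines around 0.55) and one pattern shared by all movements
(`overlap = 1`). `overlap` is a *calibration-free knob*: no quantitative
electrode-configuration SNR is modelled, so `overlap` positions problems on
an easy-to-impossible axis rather than estimating any physical quantity.

The signal model for channel *c* during a contraction of movement *m* is

    x_c(t) = activation[m, c] · mvc_fraction · mvc_rms · env(t) · carrier_c(t) + noise_c(t)

* `carrier_c` — zero-mean Gaussian noise band-limited to 20–450 Hz (2nd-order
  Butterworth high-pass, 4th-order low-pass), normalized to unit RMS. The
  20–450 Hz band is the standard surface-EMG energy band; the amplifier
  specification constrains only the front-end filters, not tissue
  physiology, so this is the package's own spectral model.
* `env` — a trapezoidal effort envelope with ramps of `ramp_fraction`
  (default 0.15) of the contraction at each end, modelling the instruction
  to contract smoothly without jerks. It also guarantees that the trimming
  stage (15 %) removes exactly the transient edges.
* `mvc_fraction` — 0.7: subjects contract at roughly 70 % of maximal
  voluntary contraction to avoid premature fatigue.
* `mvc_rms` — 2 mV electrode-referred RMS at full activation and 100 % MVC,
  a realistic surface-EMG amplitude; `baseline_noise_rms` — 5 µV, a typical
  recording noise floor. Both are pre-gain volts, so deadband thresholds
  for the ZC/SSC features keep physical meaning.

The summed signal then passes the front-end model (`frontend_spec()`):
1st-order Butterworth high-pass at 1 Hz, 3rd-order low-pass at 750 Hz, gain
200, and mid-tread 16-bit quantization over ±2.5 V. Quantization clips at
the extreme codes with a warning; clipping behaviour is otherwise
unspecified by the hardware description, and mid-tread (zero is an exact
level) is chosen so that rest-period signals quantize cleanly. Butterworth
design uses the bilinear transform with frequency pre-warping; the
coefficients agree with standard references to machine precision.

**What the generator does not emulate:** motor-unit physiology, force or
kinematics, electrode geometry, skin-electrode impedance drift, motion
artifacts, inter-channel crosstalk (available as an optional mixing matrix,
off by default) and inter-subject variability beyond the seeded activation
matrix. A green pipeline test therefore establishes numerical correctness
of every stage and the qualitative behaviour of the chain (separable
patterns are classified; identical patterns are not) — it does not validate
performance claims on human data, which depend on all of the above.

## 2. Signal treatment

Each 4 s contraction loses 15 % of its samples at both ends (ambiguous
onset/offset data), yielding a centered 2.8 s segment — 5600 samples at
2 kHz, with ms→sample conversion always by flooring. The three trimmed
repetitions concatenate to 8.4 s, which is segmented into 200 ms windows
advanced by 50 ms.

Two window-count conventions coexist deliberately. The closed form
`floor((L − w)/inc) + 1` gives 165 windows on the default constants; the
canonical per-movement count in this protocol family, however, is 163.
`segmentation_spec(convention = "drop_ends")` — the pipeline default —
drops the two end-aligned windows, reproducing 163 and keeping every
window strictly inside the concatenated signal's interior. The discrepancy
is encoded explicitly rather than silently reconciled: `"closed_form"`
remains available, and the property suite checks the closed form against
brute-force start-position enumeration.

The rest condition is a class of its own. Rest windows are cut from the
rest intervals by the same trim-and-window rule. The number of rest
intervals feeding that class is open: using all 24 would give the rest
class roughly eight times the windows of each movement, whereas the
classification task is designed with balanced classes (163 windows each).
`windows_from_session(rest_intervals = "balanced")` — the default —
therefore uses the first `n_repetitions` rest intervals, giving the rest
class the same 8.4 s as every movement; `"all"` is available for
imbalanced experiments.

## 3. Features and the data split

Per window and channel, four classic time-domain features: MAV
(`mean(abs(x))`), WL (`sum(abs(diff(x)))`), SSC and ZC. ZC counts sign
changes between consecutive samples whose difference exceeds a deadband
`eps`; zero-valued samples inherit the previous nonzero sign, so a sample
that touches zero exactly cannot create two crossings. SSC counts interior
local extrema with at least one adjacent difference above `eps`. The
deadband defaults to 0: thresholds are hardware-noise dependent and no
value is prescribed, so it is exposed as configuration. MAV and WL scale
linearly with amplitude; ZC and SSC at `eps = 0` are scale-invariant —
both properties are asserted in the suite.

Columns are ordered channel-major (`ch01_mav, ch01_wl, ch01_ssc, ch01_zc,
ch02_mav, …`), 64 columns for 16 channels.

Windows are assigned 40/20/40 to training/validation/test. Assignment is
random but *stratified by class* with largest-remainder rounding (163 →
65/33/65): plain unstratified assignment risks starving a class at desk
scale, and stratification changes nothing in expectation. The validation
set is produced but unused by plain LDA (it has no hyperparameters); it is
kept to honour the 40/20/40 contract and for future tuning experiments.

## 4. LDA one-vs-one

For each of the `n(n−1)/2` unordered class pairs, a linear discriminant is
fitted on the training rows of those two classes only: pooled within-class
covariance `Σ_pooled`, ridge term `λI`, weight vector
`w = (Σ_pooled + λI)⁻¹(μ_a − μ_b)` and equal-priors midpoint bias. Equal
priors are appropriate because class window counts are balanced by design.
`λ` defaults to `1e-6 · trace(Σ_pooled)/dim`: 64-dimensional features from
163 windows per class can be near-singular, and the scale-aware default
keeps the solve stable without materially biasing `w`. `λ = 0` is honoured
but errors with explicit advice if the covariance is singular.

Prediction is majority voting. Decision values of exactly zero vote the
alphabetically lower class; vote ties break by the largest sum of absolute
decision margins over the tied class's pairs, then by lowest class index.
All three rules are arbitrary but deterministic and documented — no
reference tie-breaking rule exists to match. The suite checks OVO against
direct two-class LDA on binary problems, vote conservation, permutation
consistency under relabelling, and ≥ 99 % agreement with an independent
reference implementation (`MASS::lda`) on Gaussian data.

## 5. The Motion Test

The Motion Test prompts each trained movement in seeded random order; the
classifier must accumulate `required_correct = 20` correct predictions
before a 10 s timeout, clocked from the prompt. The first prediction
becomes available after one full 200 ms window plus the processing
latency; predictions then arrive every 50 ms.

`processing_latency_ms` defaults to 11 so that the two standard floors
hold exactly: minimum selection time 0.211 s and minimum completion time
0.211 + 19 × 0.05 = 1.161 s ≈ 1.16 s. The 11 ms value is forced by the
printed floors (211 − 200), not measured; it is exposed in configuration.
Conventions fixed by those floors and by the worked example
(25 windows → 80 %):

* Selection and completion times are measured from the first non-rest
  prediction and *include* the first-window latency as a constant offset —
  an immediately correct first prediction scores exactly 0.211 s.
* The 20 correct predictions need **not** be consecutive (forced by the
  80 % example).
* The timeout clock starts at the prompt (the alternative — first
  prediction — is not distinguishable from the printed material; the
  choice is documented and tested).
* Real-time accuracy = 20 / (number of predictions from the first non-rest
  through the completing one); completion percentage counts completed
  prompts over attempted; time and accuracy aggregates are computed over
  completed trials only.

The live loop (`run_motion_test()`) synthesizes a fresh signal per prompt —
sustained contraction with the model's onset ramp — windows it at the
cadence, featurizes, predicts, and scores the stream exactly like a
scripted one. The cumulative completion curve is the empirical CDF of
completion times scaled by the completed fraction.

## 6. Comparison statistics

Exact two-sided Wilcoxon tests, with the two-sided p obtained by doubling
the smaller tail and capping at 1 (the doubling convention is adopted and
documented; summing both tails is the main alternative and differs only
under asymmetric tie patterns). Signed-rank: zero differences are dropped
(Pratt-style exclusion, warned); absolute differences get mid-ranks; the
null distribution of the positive-rank sum is enumerated via its
generating polynomial for up to 25 nonzero differences. Rank-sum: mid-ranks
on the combined sample; the permutation null of the rank sum is enumerated
by a subset-sum dynamic program for combined sizes up to 20. Beyond those
sizes both tests fall back to tie-corrected normal approximations. Two
size-6 samples with complete separation attain the exact floor
`2/C(12,6) = 0.00216` → 0.002 at three decimals.

Bonferroni correction takes an explicit family size `m` (default 5 — the
five metrics compared per configuration pair: completion percentage,
selection time, real-time accuracy, completion time, offline accuracy);
adjusted p = `min(1, m·p)`, significance at adjusted p < 0.05.

## 7. Pain outcome metrics

Each session's questionnaire yields: NRS (integer 0–10); per-descriptor
scores for the 15 SF-MPQ pain descriptors, scored 0–5 here (the canonical
SF-MPQ uses 0–3; the 0–5 scale follows the source instrument of this
protocol family and `score_max` is configurable); PRI = the plain sum of
descriptor scores (bounded by `5 × 15`); the awake-time distribution over
pain levels 0–5, accepted as proportions or percentages (normalized on
input with a message); WPD = `Σ k·p_k ∈ [0, 5]`; and hours slept.
`change_summary()` reports absolute change (first − last) and percent
change (`100·(first − last)/first`, undefined when the first value is 0)
against the last session and each follow-up. Percent changes are stored
unrounded with a rounded presentation column: reference endpoint
percentages in this literature (e.g. 68 % from 32 → 10, 57 % from
3.2 → 1.4) do not equal round-half-up of the printed endpoints (68.75 %,
56.25 %), so no machine-checked value depends on display rounding.

## 8. Evaluation design: leakage and chance level

One subtlety deserves its own section. With 200 ms windows advanced by
50 ms, adjacent windows share 75 % of their samples. A random 40/20/40
split therefore places test windows within 50 ms of training windows; each
test feature vector is correlated with its own class's training mean, and
the classifier scores far above chance *even when the classes are
statistically identical*. Empirically, within-session accuracy at
`overlap = 1` sits near 0.35 instead of the 1/9 chance level for nine
exchangeable classes. This optimism is intrinsic to within-session random
splits of overlapping windows and is one reason offline accuracy is known
to overstate real-time performance.

Consequently the chance-level and parameter-recovery checks evaluate
**cross-session**: train on one synthetic session, test on windows of an
independently generated session from the same activation model. With
independent test data, exchangeability of the classes at `overlap = 1`
makes expected accuracy exactly `1/n_classes`; the suite verifies
`overlap = 0` accuracy ≥ 0.95, `overlap = 1` accuracy within 3 standard
errors of 1/9, and monotone non-increase of accuracy in `overlap`. The
chance construction uses nine *movement* classes without rest: a rest
class is trivially separable by amplitude regardless of `overlap`, so
"all classes at chance" can only be stated among movement classes.
`offline_accuracy()` itself keeps the classic within-session split
contract.

## 9. Numerical choices and degenerate inputs

* All window arithmetic is integer, 0-based, half-open; ms→samples by
  flooring.
* IIR filtering runs as FIR convolution plus the recursive part with zero
  initial conditions; filters are applied causally once (no zero-phase
  filtering), matching a real-time front-end.
* The binary session dialect is little-endian float32: every mid-tread
  quantizer level is exactly representable in binary32, so quantized
  sessions round-trip bit-exactly; CSV writes 17 significant digits.
  Classifier JSON round-trips at 17 significant digits.
* Largest-remainder apportionment breaks ties in set order
  (training first).
* `split_sets` requires each class to have at least as many windows as
  there are nonzero proportions.
* Configuration files are JSON; `validate_config()` aggregates all
  violations with field paths instead of stopping at the first. Every
  experiment artifact records an md5 hash of the canonical config JSON.
* A single global seed derives per-stage seeds through a fixed affine map
  modulo 2³¹ − 1; identical configurations and seeds reproduce experiment
  bundles bit-for-bit.

## 10. Known limitations

* The generator's realism limits are listed in §1; in particular the
  `overlap` knob is not calibrated to any physical electrode-configuration
  difference, so simulated between-condition comparisons exercise the
  statistical machinery, not hardware claims.
* The Motion Test's simulated subject contracts immediately at prompt with
  a fixed ramp; human reaction times and hesitation are not modelled, so
  simulated selection times cluster near the floor.
* Importing externally recorded session archives (e.g. MATLAB session
  files from the reference open-source MPR software) is out of scope; the
  on-disk bundle format is this package's own.
* The exact tie-breaking and window-accounting rules of other MPR
  implementations are not public; equivalence is claimed only against this
  package's documented definitions, which the printed floors and worked
  examples pin down.
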