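---
title: "Evaluating ICM atrial fibrillation detection against Holter annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ICM atrial fibrillation detection against Holter annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmeval)
```

`icmeval` evaluates atrial fibrillation (AF) detection by an insertable
cardiac monitor (ICM) against a gold-standard multi-day Holter annotation,
on synthetic cohorts whose every error mode is controlled. This vignette is
the package's own account of the models and procedures involved: what is
assumed, which knobs matter, what the synthetic data does and does not
emulate, and where the numerical corners are.

## Timelines and the analyzable mask

Everything is a set of half-open intervals `[start, end)` in seconds on a
per-patient clock starting at 0. Half-open intervals make the algebra exact:
adjacent intervals share no time, durations add, and the four duration-based
confusion components partition the mask to machine precision (asserted at
1e-6 s in every run). The interval engine is a small hand-written module
(`iv_*`) because the times are continuous seconds; it is verified in the
test suite against a brute-force 0.1 s discretization oracle.

A Holter annotation track carries `AF`, `ATFL` (atrial tachycardia/flutter),
`UNINTERPRETABLE` and `OTHER` events. AF performance is assessed only on the
*analyzable mask*: the recording span minus uninterpretable and AT/AFL time.
The same mask is the denominator for AF burden on both axes — the natural
choice once the exclusion rule exists, though a study could also use raw
recording time; the choice is stated here because it changes burden levels
slightly whenever exclusions are non-empty.

## The three metric families

**Episode-based.** A true AF event is eligible if its *annotated* duration
is at least 2 minutes (the device's programmed detection floor); the
threshold applies to the annotation, not to what survives masking, so an
event clipped by an excluded segment keeps its identity (and an event wholly
inside excluded time drops from assessment). An ICM episode is a true
positive if it overlaps any eligible event by more than 0 s inside the mask
(a configurable minimum-overlap fraction exists but defaults to "any
positive overlap" — with ≥ 2-minute episodes on both sides, partial-overlap
ambiguity is rare); it is excluded if it lies entirely outside the mask, and
a false positive otherwise. Events and episodes keep separate denominators:
several episodes can match one event (each an independent true positive) and
one episode spanning several events is a single true positive. That
asymmetry is what lets a cohort have more true detections than true events.

**Duration-based.** Seconds of overlap inside the mask: `tp = |ICM ∩ AF|`,
`fp = |ICM \ AF|`, `fn = |AF \ ICM|`, `tn` the remainder. Cohort-level
metrics pool seconds across patients.

**Patient-based.** The 2×2 table of "any eligible true event" against "any
non-excluded detection" (after classification: any *retained* non-excluded
detection).

Zero-denominator metrics propagate as explicit `undefined` flags — never
silently as 0 or 1.

## Estimators for clustered proportions

Episode-level proportions are reported three ways: *gross* (pooled
numerator/denominator, Clopper–Pearson 95 % CI), *patient average*
(unweighted mean over patients with a defined denominator, normal CI on the
per-patient proportions), and *GEE* — an intercept-only logistic model with
exchangeable working correlation, the standard adjustment for multiple
episodes per subject. For that model the estimating equation collapses to a
weighted mean of cluster proportions with weights `n_i / (1 + (n_i − 1)α)`;
`α` comes from the moment estimator on pairwise Pearson residual products
and the two are iterated to a fixed point. The 95 % CI uses the robust
sandwich variance on the logit scale. No installed R package provides GEE,
so the estimator is implemented here and cross-checked in the tests against
an independent reference implementation on twenty seed-fixed clustered
datasets (agreement ~1e-9 on points and CIs). All-success or all-failure
data make the logit degenerate; the function then falls back to the pooled
exact binomial interval, with a warning and an explicit flag.

## Clock alignment

The ICM and Holter clocks disagree by an unknown offset (and possibly a
linear drift). Rather than matching individual beats, the package maximizes
total overlap between shifted ICM episode intervals and annotated AF over a
±120 s grid in 0.5 s steps, refined by golden-section search in the bracket
around the grid optimum; the objective is piecewise linear, so the refined
optimum is reliable. Grid ties break toward the smallest absolute offset.
Patients without annotated AF (or with an empty log) cannot be aligned and
return a flagged no-op estimate with quality 0; quality is otherwise the
overlap achieved divided by total episode time. In simulation, a 37.5 s
injected offset is recovered within the grid step, and with 2 s boundary
jitter over ~20 episodes the offset is recovered within 3 s in ≥ 95 % of
replicates.

## The synthetic cohort generator

Defaults emulate a 1-month Holter validation visit in an AF-indicated ICM
cohort: 30 patients, 3–7-day recordings (uniform), AF prevalence 0.29,
episode count per AF patient `1 + Poisson(12)`, lognormal episode durations
(`meanlog = log(1800)`, `sdlog = 1`, truncated at 120 s — the published
record reports only episode counts at duration thresholds, so the law itself
is this package's choice; the truncated lognormal reproduces the dominance
of short episodes with a heavy tail of long ones while keeping expected AF
time well inside the recording span), miss probability 0.006 per episode
(matching a ~99.4 % gross episode sensitivity), 5 s Gaussian boundary
jitter, false episodes at 0.31/day with cause mix 0.385/0.315/0.300 (sinus
arrhythmia / ectopy / noise; the published percentages 38.4/31.3/29.8 sum to
99.5 after rounding and are renormalized), short lognormal false-episode
durations (`meanlog = log(180)`, `sdlog = 0.5`, truncated at 120 s — false
detections are mostly brief, which is what makes PPV rise with duration
thresholds), 3 % uninterpretable time, 2 % AT/AFL, and a per-patient clock
offset uniform on ±60 s. Episode miss is Bernoulli and duration-independent
by default; an optional logistic model makes short episodes more likely to
be missed, as real devices do. Uninterpretable segments avoid true AF by
default so the 2-minute truth definition stays clean; a flag allows overlap
to exercise the masking rules. All event times are quantized to 1 ms, which
makes CSV serialization at 3 decimals bit-exact under write→read.

Electrograms are phenomenological, not electrophysiological: QRS-like
biphasic wavelets at RR intervals from a rhythm-dependent point process
(true AF: i.i.d. lognormal RR, CV ≈ 0.25, no periodicity; sinus arrhythmia:
0.25 Hz sinusoidal RR modulation; ectopy: premature beats with compensatory
pauses at rate 0.15/beat; noise: broadband bursts and heavy baseline wander
over a regular rhythm), plus a noise floor, sampled at 64 Hz over the
device's 30 s pre-trigger + 60 s post-trigger window. The classes are
separable by construction — RR variability alone separates AF from sinus
arrhythmia with AUROC > 0.9.

What passing tests therefore show: the metric algebra, exclusion rules,
alignment, estimators and the classifier-as-filter plumbing are correct, and
the whole pipeline is deterministic under a seed. What they do not show:
performance on real electrograms (far harder morphology), or realistic
patient-level specificity — the generator spreads false positives uniformly
across patients via a homogeneous Poisson rate, whereas in real cohorts
false-positive propensity clusters in a minority of patients (marked sinus
arrhythmia, frequent ectopy), so synthetic patient-level specificity before
filtering is pessimistic relative to published cohorts. Episode- and
duration-based metrics are unaffected by that difference.

## The false-positive classifier

The CNN follows the published architecture family — `[Conv1D → ReLU →
BatchNorm → Dropout] × 6` with filters (16, 16, 32, 32, 64, 64), kernel 9,
max-pool (window 4) every 2 blocks, global average pooling, dense (64, 16),
sigmoid output — with depth, filter counts, kernel size, sampling rate and
training sizes chosen for desk-scale CPU training (minutes on a few hundred
snippets); the reference implementation's corresponding values are
unreported. Training uses binary focal cross-entropy (γ = 2, α = 0.25) and
Adam (lr 1e-3, batch 32, 8 epochs), with snippets standardized per snippet
and a *patient-level* train/validation split so no patient leaks across
sides. Conv and pooling kernels are compiled (RcppArmadillo); batch norm,
dropout, dense layers, the loss and Adam are plain R, and backpropagation is
verified against numerical gradients in the tests.

The operating threshold uses a zero-true-positive-loss policy: reject as
many validation false episodes as possible while retaining every validation
true episode. Any threshold up to the minimum validation true score achieves
that maximum, so the threshold is placed midway between the score clouds
(half the gap down to the highest rejected false score) — the same
validation rejections, but with out-of-sample slack for true episodes from
unseen patients; if the clouds touch, a fallback margin of 1e-6 is
subtracted instead. Episodes without a stored electrogram are retained by
default with a warning: the fail-safe direction is toward sensitivity.
Classification never alters episode boundaries or truth matching — only the
retained subset — which yields the filter guarantee asserted on every run:
sensitivity bit-identical, PPV and specificity never lower.

## Numerical choices and degenerate inputs

* Intervals of zero length are dropped at construction; union merges
  touching intervals (measure-equivalent under half-open semantics).
* Millisecond quantization in the generator, `%.3f` times and `%.17g` scores
  in CSVs: write→read is the identity for every generated object.
* GEE: fixed-point iteration capped at 50 rounds, `α` clamped to
  (−0.99, 0.999); the sandwich bread is taken in absolute value because a
  negative working correlation can flip its sign.
* Alignment quality is capped at 1; empty logs warn and no-op.
* The pipeline report (`report.json`) contains no timings or other
  run-varying fields, so identical seeds give byte-identical files; timings
  go to `run.log`.
* Test problem sizes are the package's own: 100 random patients with
  2,000–20,000 s spans for the discretization oracle (the algebra is
  scale-free), 50 seeds for miss-probability recovery, 400 snippets for the
  classifier separation check, and a 30-patient evaluation cohort with a
  disjoint 12-patient training cohort for the end-to-end runs.

## Known limitations

* Clock drift is modelled as a single linear term, and the default aligner
  estimates offset only; drift must be supplied externally if present.
* The generator's homogeneous false-positive rate understates patient-level
  specificity relative to real cohorts (see above).
* Synthetic electrograms make the classifier's task easier than real
  device-stored snippets; its near-perfect synthetic rejection rates are a
  property of the simulation, not a clinical claim.
* Patient-average CIs use a normal approximation on per-patient proportions,
  which is crude for small cohorts; the GEE estimator is preferred there.
* Time-to-first-detection and longitudinal burden trends are out of scope.
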