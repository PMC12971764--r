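---
title: "Classifying surgical skill from fused EEG and eye-tracking signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying surgical skill from fused EEG and eye-tracking signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Robot-assisted vesico-urethral anastomosis (VUA) is one of the most
demanding steps of radical prostatectomy, and assessing a trainee's skill
at it still relies on manual Likert-scale scoring of video by expert
raters (the RACE instrument: needle positioning, needle entry, needle
driving and tissue trauma, suture placement, tissue approximation).
`skillfuse` implements an objective alternative: a subject-independent
classifier that maps synchronized electroencephalography (EEG, 512 Hz, up
to 116 usable channels) and eye tracking (50 Hz, 20 exported signals)
recorded *during* the task to a three-level skill label (inexperienced,
competent, experienced), with the rater consensus serving as ground truth.

Because the underlying human recordings are not publicly deposited, the
package pairs the analysis pipeline with a first-class synthetic cohort
generator, so that every stage — preprocessing, windowing, model,
evaluation — is testable end to end from a seed.

## The synthetic cohort generator

`generate_cohort()` draws a skill class per participant (defaults: 23
participants with proportions 11/7/5, matching a pool of pre-medical
students and scientists, residents and fellows, and surgeons; each
performs two anastomoses). Every trial holds both subtask segments,
delimited by trigger events, as:

* **EEG**: per-channel 1/f ("pink") background noise at 10 µV RMS, plus
  stochastic narrow-band activity — theta (4–8 Hz) on frontal channels
  and alpha (8–13 Hz) on occipital channels — plus a shared-phase 60 Hz
  mains component (default 5 µV). Band activity is band-limited Gaussian
  noise rather than a fixed sinusoid: real cortical rhythms are
  stochastic narrow-band processes, and a constant-frequency tone would
  hand a classifier a spurious per-trial fingerprint unrelated to band
  power.
* **Class structure**: frontal theta amplitude scales as
  `exp(+0.4 · effect_size · (class − 2))` and occipital alpha as the
  reciprocal, so experienced participants show stronger frontal theta
  and weaker occipital alpha. `effect_size = 0` makes the EEG and gaze
  streams byte-identical across classes under a fixed sub-seed (the
  exchangeable null).
* **Gaze**: an alternating fixation/saccade regime over a 1920×1080
  screen; mean fixation duration scales as
  `0.25 · exp(0.35 · effect_size · (class − 2))` s (experienced
  participants fixate longer and saccade less). The 20 exported signals
  are the screen gaze point, 3-D gaze point, left/right gaze direction,
  left/right 3-D pupil position, both pupil diameters, and a categorical
  eye-movement-type index (1 fixation, 2 saccade, 3 missing). A
  configurable fraction of samples (default 5%) is dropped to missing.
* **Ratings**: three raters score all five domains of every segment; a
  rater's Likert score is the class-mapped ideal (1.8, 3.0, 4.2) plus
  Gaussian noise (default SD 0.5 Likert units), rounded and clipped to
  1–5. At that default the generated tables give multi-rater kappa in
  the 0.6–0.8 range, comparable to published inter-rater agreement for
  this instrument.

Trial durations are uniform per class — defaults (30, 70) s,
(15, 45) s, (4, 25) s for classes 1–3 — chosen once as plausible VUA
segment durations; the experienced range deliberately extends below the
5 s window so the zero-padding path is always exercised. No published
duration distributions exist, so these are free parameters surfaced in
the configuration.

The montage is synthetic: usable channels are placed on a unit disc by a
golden-angle arrangement plus the eight named poor-quality channels (F8,
POz, AF4, AF8, F6, FC3, M1, M2) at fixed coordinates; frontal and
occipital groups are defined by the y coordinate. No real montage file is
required, but the layout drives both the neighbor graph of the surface
Laplacian and the ocular template of artifact cleaning.

What the generator does **not** emulate: volume-conducted source mixing,
realistic saccade kinematics and ocular artifacts in the EEG,
non-stationary drifts, inter-channel correlation structure of real caps.
A pipeline that passes on this cohort is therefore validated for its
*mechanics* (synchronization, leakage control, masking, statistics), not
for clinical performance claims.

## Preprocessing

The chain fixed by the analysis, in order: exclusion of the eight named
channels (116 remain on the default cap) → zero-phase 60 Hz notch
(second-order IIR biquad, Q = 30, applied forward–backward) → zero-phase
band-pass 0.2–250 Hz (fourth-order, i.e. 24 dB/octave, Butterworth
high- and low-pass cascade; 250 Hz sits below the 256 Hz Nyquist limit at
512 Hz) → common average reference → artifact removal → surface (Hjorth)
Laplacian over a k-nearest-neighbour graph (k = 4) of the 2-D layout.
Zero-phase (filtfilt) realizations were chosen to avoid phase distortion
between modalities; the stated rolloff fixes the filter order.

Artifact removal in the original analysis was an interactive
vendor-software procedure (blind source separation plus topographical
PCA) that cannot be reproduced programmatically. `clean_artifacts()` is a
transparent stand-in: principal components whose scalp loadings correlate
with a frontal ocular template (|r| > 0.9) or that individually exceed a
variance fraction (default 0.25) are projected out. It has an exact
no-op mode (`mode = "off"`), which the desk-scale profiles use, both for
speed and because the synthetic cohort injects no ocular artifacts.

Gaze is smoothed with a centred 3-point moving average (shrinking window
at the edges: `[1,2,3,4]` → `[1.5, 2, 3, 3.5]`) after mean imputation of
missing samples; the categorical type index is never averaged — missing
becomes 3, then a majority-of-3 smoother runs (ties keep the centre).
`align_modalities()` slices both streams to the event-delimited segment
and resamples each continuous gaze signal onto the 512 Hz EEG timeline
with a cubic smoothing spline (smoothing chosen per signal by
generalized cross-validation; constants and straight lines are
reproduced exactly, which the tests assert). The categorical index is
carried by previous-value hold — a spline would invent non-integer
categories. The fused segment stacks 116 EEG rows then 20 gaze rows
(136 features).

## Windowing and tensorization

Segments are cut into label-preserving sliding windows of L ∈ {3, 5, 10}
s with 50% overlap; a segment shorter than one window yields a single
window rather than being dropped. Windows are zero-padded at the end to
`L × 512` samples and subdivided into T = 10 temporal steps; a step is
masked out only when it contains padding alone. The nominal step length
`L × 51.2` is non-integer for L = 3; the realized step is
`round(L × 51.2)` samples with the remainder absorbed by (and the step
axis zero-filled in) the final step — at L = 5 the shape is exactly
(10, 256, 136) per window.

Channel-wise z-scoring statistics are computed on *training participants
only*, over real (non-padded) samples, and then applied to validation and
test batches; padded samples stay exactly zero so that masked attention
and normalization interact cleanly. Majority-class windows can be
randomly downsampled to the minority count (`balance_downsample()`,
seeded); the class-weighted loss handles residual imbalance.

## The classifier

A CNN-LSTM with masked additive attention, implemented in-package as
dense linear algebra with analytic gradients (verified against numerical
differentiation in the test suite):

1. per-timestep 1-D convolution (im2col + BLAS; filters/kernel from the
   configuration), ReLU, L2 penalty on the kernel;
2. per-timestep max pooling (width 2) and flattening;
3. a single LSTM layer over the 10 steps (L2 on both kernels,
   forget-gate bias initialized at 1);
4. additive attention `score_t = v·tanh(W h_t + b)` over the step
   outputs, with masked steps excluded from the softmax (their scores are
   −∞, hence weight exactly 0) — because padding is always at the end
   and the LSTM is causal, perturbing data inside masked steps provably
   cannot change the output, which an acceptance test asserts;
5. dropout → dense ReLU → dropout → softmax over the three classes.

Training minimizes class-weighted categorical cross-entropy
(`w_c = n/(3 n_c)`, the inverse-frequency convention) with Adam
(default rate 1e-3), early stopping on the unweighted validation loss of
held-out participants (patience 10 by default, best weights restored).
Everything is seeded: initialization (Glorot), batch partition, dropout.
Mini-batches are drawn once per run and kept fixed across epochs (the
processing order is reshuffled each epoch); this lets the convolution's
im2col matrices be precomputed per batch and reused by every forward and
backward pass, which dominates the speed of the whole pipeline. The
cache is capped by `options(skillfuse.im2col_budget = …)` (default
1.6 GB) and falls back to on-the-fly construction beyond it.

Hyperparameter values searched in the original analysis — LSTM units
{50, 100, 150, 200}, filters {32, 64, 128}, kernel {3, 5}, dropout
{0.5, 0.6, 0.8}, L2 {0.1, 0.01, 0.001}, epochs {50, 100}, batch
{64, 128, 256} — are all accepted by `model_config()`; the attention
width, dense width, pooling width (2) and optimizer were not specified
and are configuration defaults.

## Evaluation

`make_split_plan()` draws repeated random partitions into training and
held-out test participants (defaults 16/7 over 23, 10 repeats) with
grouped k-fold (k = 4) inner folds over the training participants; no
participant's windows ever cross a train/validation/test boundary, and
`audit_leakage()` re-checks every pair explicitly. An optional `strata`
argument interleaves classes across selections and folds, which small
cohorts need for every subset to contain all classes; the plain random
partition remains the default. `grid_search()` scores each configuration
by mean inner-fold weighted F1 with deterministic lexicographic
tie-breaking; `run_experiment()` retrains the selected configuration
(early-stopped on the first inner fold's participants) and evaluates once
per repeat on the held-out participants, reporting per-run metrics and
the pooled confusion over all repeats — both pooled metrics and per-run
mean ± SD are available, since summary tables in this literature report
the latter.

Metrics follow the standard confusion-matrix definitions; a class never
predicted gets precision 0 with a warning. Weighted F1 is the
support-weighted mean of per-class F1. Modality comparisons use
two-tailed paired t-tests across matched runs with Holm–Bonferroni
step-down correction over the comparison family; all-zero difference
vectors give p = 1 exactly, and a Wilcoxon signed-rank alternative is
provided for small run counts.

Inter-rater agreement: Fleiss' kappa from the item-by-category count
table, with a seeded item-level percentile bootstrap CI (2000 resamples;
no analytic CI was specified for this statistic), and the single-measure
two-way random-effects absolute-agreement ICC(2,1) from ANOVA mean
squares with F-distribution confidence bounds; an average-measure
variant sits behind a flag. Both statistics match independent
direct-formula/ANOVA oracles to 1e-10 in the tests, and both return an
explicit degenerate flag when expected agreement is 1 or total variance
is 0. RACE-score class thresholds are not published; the default is the
tertile cut (7/3, 11/3) of the 1–5 scale, surfaced in every label table.
Labels default to per-segment granularity (a participant-level mode
exists, since the original description is ambiguous between the two).

## Desk-scale profiles and what the validation runs show

The package's own validation (`smoke_profile()`, used by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) runs the
complete pipeline at a reduced but non-trivial scale chosen to fit
minutes of single-core CPU: 24 participants (balanced classes,
stratified), 2 trials each, segment durations (12–24) s / (8–18) s /
(4–14) s, strong class separation (`effect_size = 5`), the 5 s window,
combined modality (136 features), a single-point grid (16 filters,
kernel 3, 16 LSTM units, dropout 0.6, L2 0.1, 50 epochs, batch 16), and
2 repeats of a stratified 16/8 split with 4 inner folds, pooling test
predictions across repeats as the original evaluation does. Each repeat
trains a seed ensemble of 2 models and averages their softmax
probabilities: at this sample size single runs vary by several accuracy
points with initialization (the study's own motivation for repeated
runs), and probability averaging is the standard desk-scale
stabilization; `ensemble = 1` recovers the single-model estimator. Window-level
downsampling is off in this preset — with ~200 windows total, discarding
majority-class windows costs more than the class-weighted loss gains —
and PCA artifact cleaning is off because the generator injects no
artifacts. The zero-effect arm of the acceptance run uses one repeat and a single
model: a chance-level check needs neither pooling nor ensembling.

Two scale caveats follow from the design, and one more from
development experience: across cohort realizations (master seeds), the
smoke run's pooled held-out accuracy varied from roughly 0.65 to 0.94 in
development — the small model sometimes fails to find the cross-subject
amplitude features that an oracle classifier on hand-crafted band-power
and saccade-rate summaries recovers at the label-noise ceiling
(~0.93-0.95) on the same cohorts. The packaged validation therefore
fixes the seed, reports the pooled quantity, and pairs it with the
zero-effect null arm; single-seed success demonstrates the pipeline's
mechanics, not a uniform performance guarantee over cohorts.

Two scale caveats follow from the design. First, rater noise (SD 0.5)
caps achievable held-out accuracy near 0.9: roughly 7% of segment labels
disagree with the generating class, in training and in measurement
alike. Second, with 8 test participants per repeat, single-repeat
accuracy fluctuates by several points; pooling across repeats is part of
the reported quantity, not a cosmetic choice.

A micro profile (9 participants, 8-channel montage, gaze modality) backs
the property tests: pipeline plumbing, report writing, and the
monotonicity of held-out accuracy in effect size (0, 2, 5 under fixed
seeds).

## Known limitations

* The synthetic cohort's class structure lives in band power and
  fixation dynamics by construction; success on it does not transfer to
  claims about real operating-room recordings.
* The artifact-cleaning stand-in is far simpler than interactive
  BSS/topographic-PCA review and is validated only on injected
  template artifacts.
* The paired t-test across 10 runs inherits the usual small-n normality
  caveat; the Wilcoxon alternative is provided but not the default.
* Fleiss' kappa's bootstrap CI resamples items, not raters; with 3
  raters there is no meaningful rater-level resampling.
* Training is deliberately deterministic per seed; on hardware with a
  different BLAS the trajectories (and hence early-stopping epochs) can
  differ in the last float digits.
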