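---
title: "Decoding movement intention from functional ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement intention from functional ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusbmi)
```

# The problem

Functional ultrasound (fUS) neuroimaging streams 2 Hz power-Doppler images
of cerebral blood volume at ~100 μm in-plane resolution across a wide,
deep field of view. During the memory period of a delayed-response task
(memory-guided saccades or reaches), posterior parietal cortex carries a
plan for the upcoming movement, and the hemodynamic signature of that plan
is decodable on single trials. `fusbmi` implements a closed-loop
brain-machine-interface pipeline around that signal: streaming
preprocessing, linear decoders, an online training protocol with
cross-session pretraining, rigid image alignment, chance-envelope
statistics, and searchlight information mapping — exercised end to end on
a synthetic session generator so that no animal data are required.

# The synthetic session generator

The generator is first-class, tested code: it defines the study conditions
under which every end-to-end claim in this package is evaluated.

**Anatomy.** A phantom is a strictly positive baseline image with smoothed
curvilinear vessel-like structures, emulating a mean power-Doppler
vascular map. The default grid is 128 × 160 voxels (12.8 × 16 mm at
0.1 mm).

**Tuned patches.** Direction information lives in compact voxel patches
(by default two: one preferring leftward movements, one upward, each ~1%
of the field of view). A patch's response to a cue at angle $\varphi$ is a
von Mises tuning curve normalized to 1 at the preferred direction,

$$g(\varphi) = \exp\{\kappa[\cos(\varphi - \varphi_{\text{pref}}) - 1]\},$$

with concentration $\kappa = 2$ by default — broad tuning, so neighboring
directions evoke similar responses (the premise of the multicoder). The
fractional CBV increase is `amplitude` × the cue-plus-memory boxcar
convolved with a gamma-variate response function. No reference response
function exists for this preparation, so we use a unit-area gamma kernel
with ~1.5 s time to peak and ~2 s FWHM and no undershoot — seconds-scale
mesoscopic neurovascular coupling — with all parameters configurable. The
default peak amplitude is 10% of baseline, a deliberately strong,
desk-scale effect: passing signal-detection tests under these conditions
shows the pipeline is correct, not that real cortical effect sizes are
this large.

**Noise.** Voxel noise is multiplicative (power-Doppler intensities are
positive and their variance scales with signal), 2% of baseline per frame.
A global gain random walk (0.2% per frame) models slow drift, and a 0.3 Hz
sinusoidal gain (1%) stands in for aliased cardiac pulsatility. Real fUS
noise spectra are not reproduced; in particular there is no speckle, no
motion, and no spatially correlated physiological noise. Tests passing on
this generator therefore validate the algorithmic contracts (and
qualitative claims such as "pretraining reaches significance sooner"), not
clinical performance levels.

**Task timing.** Trials follow the memory-guided task: fixation 5 ± 1 s,
peripheral cue 400 ms at 20° eccentricity, memory 5 ± 1 s, hold
1.5 ± 0.5 s, intertrial interval 8 ± 2 s, all jitter uniform. Cue order is
balanced pseudo-random: shuffled blocks in which every direction appears
once, so any n-trial prefix is balanced to within one trial. Sessions are
bit-deterministic given the seed.

**Inter-session change.** `perturb_for_next_session()` applies a rigid
in-plane rotation/translation (and optional global gain) to the anatomy
and the patch masks, emulating the brain shifting under the transducer
between days; the true transform is attached for use as an oracle.
Out-of-plane shifts are not modeled.

**Doppler formation.** `svd_clutter_filter()` demonstrates the upstream
power-Doppler step: an SVD of the slow-time Casorati matrix, discarding
the `floor(0.3 N)` largest components (tissue clutter) and averaging the
squared residual (blood signal power). It is a self-contained
demonstration, not an acoustic simulator.

# Streaming preprocessing

Frames enter a rolling 60-frame (30 s) buffer. Each frame is z-scored
voxel-wise against the buffer (sample sd, `ddof = 1`; zero-variance voxels
map to 0 to avoid NaN propagation) and then smoothed with a pillbox
(disk) filter of radius 2 voxels — z-score first, then smoothing. The
default kernel weights pixels by the area of their overlap with the disk;
a binary-disk dialect (13 equal weights at radius 2) is also provided.
Boundaries are zero-padded.

A trial's feature vector is the last three preprocessed frames of the
memory period (1.5 s), flattened, giving $D = 3HW$ features. Each decode
frame is z-scored against the buffer state at its own arrival (the
streaming-causal choice); a variant that uses the buffer state at the
final frame's arrival is available via `zscore_scope = "final"`.

One invariant is load-bearing enough to call out: the batch
(`preprocess_session()`) and streaming (`rolling_buffer()` +
`rolling_zscore()`) paths are **bit-identical**. Both accumulate the same
running sums with plain double additions in arrival order (base `cumsum`
would accumulate in extended precision and break this), which is what
makes post hoc replay of a recorded session reproduce the online
prediction sequence exactly.

# Decoders

**Two classes: cPCA + LDA.** Class-wise PCA computes, per class, the
principal axes retaining ≥ 95% of that class's variance; features are
projected onto the orthonormalized (QR) union of the two class bases, and
LDA is fit on the projections. The class-wise variant keeps within-class
structure that pooled PCA can average away. The literature admits several
cPCA realizations (e.g., per-class subspaces with model selection); this
one is isolated behind the decoder interface so alternatives can be
swapped without touching the protocol.

**Eight directions: the multicoder.** Each peripheral direction decomposes
into a vertical component (UP/MID/DOWN) and a horizontal component
(LEFT/MID/RIGHT). Two independent pooled-PCA (95% variance) + three-class
LDA models predict the components from the same feature vector, and the
argmaxes are recombined — possibly into CENTER, which is never a cue and
is scored as always-wrong. The factorization encodes the prior that
neighboring directions have similar neural responses: an error in one
component usually lands on a neighboring direction rather than an
arbitrary one.

**Numerical choices.** Early in training $n \ll D$ even after reduction,
so the pooled LDA covariance is shrunk toward its diagonal with a small
fixed coefficient (0.1 by default; configurable). A tiny ridge
($10^{-8}$ of the mean diagonal) guards exactly singular cases. Ties in
discriminant scores are broken by a fixed class order (R before L; UP
before MID before DOWN) for determinism. Class priors are empirical.
"95% variance" means the smallest leading set of eigenvalues whose
cumulative sum reaches 95% of the total; zero eigenvalues are never
retained. When $D > 2n$ the class PCA is computed from the $n \times n$
Gram matrix — the same subspace at a fraction of the cost of a direct
SVD. Models serialize to JSON at full floating-point precision; a
reloaded model makes identical predictions (scores agree to ~1e-14;
decimal serialization is not bit-lossless).

# The closed-loop protocol

A session starts in the **training phase**: the subject performs
instructed movements, a trial succeeds iff the movement was correct, and
every successful trial's features are added to the training set, with the
decoder refit between trials (its shadow predictions are recorded for
evaluation but invisible to behavior). After 100 successful training
trials the protocol switches — exactly once — to **BMI mode**, where the
decoder's prediction drives the task and a trial succeeds iff the
prediction matches the cue and fixation is maintained until reward.

Training-set policies: `realtime` (append only successful trials — the
online rule) and `replay` (append every trial that reached the end of the
memory period, right or wrong — the post hoc simulation rule, which keeps
the training set class-balanced when early predictions are poor).
Retraining can be disabled to freeze a pretrained model.

**Pretraining.** `pretrain_from_previous()` applies a rigid alignment
transform to every frame of a previous session, re-runs preprocessing on
the transformed frames, and imports all valid trials (provenance
`previous`) so a model exists before the current session's first trial;
retraining then continues per policy.

**Label withholding.** The in-progress trial's cue is never visible to the
decoding path until after the trial ends: the prediction is computed from
the feature vector alone before the label is consulted, and a test
verifies that rewriting the cues of trials ≥ j leaves all predictions
≤ j unchanged.

**Evaluation.** Shadow evaluation starts at trial 20 by default
(`min_eval_trial`), matching how cumulative-accuracy curves are
conventionally drawn; the pretraining comparison sets it to 1, since the
point of pretraining is performance from the first trial. Refitting is
attempted as soon as every class (or component class) has ≥ 2 samples.

# Cross-session alignment

`register_rigid()` minimizes the mean squared intensity difference
between the transformed previous-session anatomy and the current
anatomy over rotation and translation (no scaling — brain size does not
change between sessions; rotation is about the image centre, any other
pivot being absorbed by translation). The optimizer is a regular-step
gradient descent: central-difference gradients, steps along the
normalized descent direction, halving the step on failure, which makes
the final MSE provably ≤ the initial MSE. A 3-level multi-resolution
pyramid provides capture range up to ~10 px; beyond that,
`manual_adjust()` supplies a rough initial guess (the programmatic
analogue of an interactive nudge). An 8% border margin is excluded from
the metric so out-of-view zeros do not bias the fit. On default phantoms
with 2% noise, transforms up to 5° / 10 px are recovered to well under
0.25° / 0.5 px.

# Performance statistics

Two printed metrics: cumulative percent correct
(correct predictions / total predictions) and, for eight-target tasks,
the cumulative mean absolute angular error
$\frac{1}{n}\sum_i |\text{err}_i|$, with errors on the
$\{0, 45, 90, 135, 180\}°$ lattice (CENTER scores 180°, a conservative
convention the source protocol leaves unspecified).

The accuracy chance envelope is the exact binomial 90% band: lower bound
= largest $k$ with $F(k-1) \le 0.05$, upper = smallest $k$ with
$F(k) \ge 0.95$, as fractions of $n$; "significant" means strictly above
the upper bound (one-sided at $\alpha = 0.05$). The angular-error
envelope is a permutation null with $10^5$ replicates: uniform random
directions, cumulative mean error per $n$, 5th/95th quantiles. Because
the null error distribution is discrete
($\{0,\ldots,4\}\times 45°$ with weights $(1,2,2,2,1)/8$; mean 90°),
replicate means are tabulated exactly on the $45/n$ lattice, so quantiles
come from exact counts at bounded memory, and the tests can check the
Monte Carlo envelope against an exact discrete-convolution oracle. The
"last non-significant trial" is the largest evaluated trial whose
statistic is not beyond the envelope; a single crossing is not required
to be sustained before it, matching how the red marker on cumulative
curves is conventionally defined. Trials-to-significance is that trial
plus one, and NA if the trace does not end significant.

Confusion matrices are row-normalized percentages (rows = cued class,
summing to 100); eight-target matrices carry a CENTER column. A cued
class with no predictions yields a flagged NA row, never a silent zero.

# Searchlight mapping

A circular ROI of radius 2 voxels (200 μm; the 13-voxel binary disk
lattice) slides over every voxel whose full ROI fits in the grid. At each
centre, the task-appropriate decoder is run on the ROI's voxels (all
three feature frames, 39 features at the default radius) under seeded
stratified 10-fold cross-validation, and the mean fold performance is
assigned to the centre voxel. Significance is an artifact choice — the
source protocol reports q-value thresholds without stating the test — so
we document it prominently: one-sided exact binomial tails for accuracy
maps, permutation-null lower tails (on the exact lattice) for
angular-error maps, and Benjamini–Hochberg q-values over the scored
voxels. The overlay mask is the top 10% of scored voxels
(`ceiling(0.10 n)`), ties broken by p-value then scan order. The map is
deterministic given the fold seed and identical regardless of evaluation
order.

# Problem sizes used in the tests

The test and acceptance suites run at desk scale, chosen once: unit tests
use 8×10 to 32×40 grids; closed-loop signal-detection runs use 24×30
grids with 180-trial sessions (20 seeds per condition); the pretraining
comparison uses 10 matched 100-trial session pairs with inter-session
perturbations up to 2° / 3 px (small enough that both tuned patches stay
within the reduced field of view); alignment recovery uses the full
128×160 default phantom over 100 seeded transforms; the searchlight
localization runs on a 64×80 grid with one 450-voxel patch and 80 trials.
Generator noise, amplitude, tuning and task timing stay at their
defaults throughout.

One statistical point about the zero-amplitude control: a 90% envelope
leaves each null session roughly a 5% chance per tail of ending outside
by chance, so across 20 null sessions about one excursion is expected;
the suite therefore allows up to 4 of 20 (beyond which the binomial
probability drops below 1%) rather than demanding all 20 inside — a
criterion that an exactly calibrated null would still fail about a third
of the time.

# Known limitations

- The generator's hemodynamics, noise and tuning are idealized; absolute
  accuracies on synthetic sessions (often near 100% at default SNR) say
  nothing about attainable in vivo performance.
- Decoders are linear by design; no neural-network decoders are provided.
- Alignment is 2D rigid; out-of-plane shifts are unmodeled and would
  violate the pixel-to-voxel correspondence the linear decoders assume.
- The acquisition stack (beamforming, plane-wave sequences, real-time
  transport) is out of scope; `svd_clutter_filter()` is the only nod to
  image formation.
- Wall-clock latency of retraining is not modeled; retraining happens
  synchronously between trials.

# A minimal end-to-end example

```{r example, eval = FALSE}
phantom <- make_phantom(dims = c(24, 30), seed = 1)
session <- generate_session(phantom, task_config(n_targets = 2),
                            n_trials = 180, seed = 2)
res <- run_closed_loop(session, closed_loop_config(n_targets = 2))
res
tail(tibble::as_tibble(res$trace), 1)
autoplot(res$trace)
confusion_matrix(res$predictions, n_targets = 2)
```
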