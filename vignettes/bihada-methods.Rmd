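---
title: "Bi-hemispheric adversarial domain adaptation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-hemispheric adversarial domain adaptation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bihada)
```

## The problem

EEG emotion decoders trained on one person rarely work on another: electrode
impedances, cortical folding and idiosyncratic emotional responses shift the
feature distribution between subjects (and, more mildly, between recording
sessions of the same subject). **bihada** implements an unsupervised
adversarial domain-adaptation pipeline for this setting: labeled *source*
recordings (other subjects, or other sessions) plus unlabeled *target*
recordings are used to train a classifier that transfers to the target.

Two ideas distinguish the model from a plain domain-adversarial network
(DANN):

1. **A class-informed (C+1) domain discriminator.** A binary source/target
   discriminator aligns only the marginal feature distributions
   $P_s(f) \approx P_t(f)$. Emotional EEG features are class-conditionally
   multimodal, and marginal-only alignment can pull target samples onto the
   *wrong* source class. The discriminator here classifies every sample into
   $C+1$ classes: source samples carry their emotion label $y_i \in 1..C$,
   every target sample carries the extra class $C+1$. Fooling this
   discriminator requires target features to land on *specific source class
   modes*, encouraging class-conditional alignment
   $P_s(f \mid y) \approx P_t(f \mid y)$.

2. **Two hemisphere branches fused by perplexity.** Emotional processing is
   lateralized, so the 62-channel montage is split at the sagittal midline
   (8 z-electrodes dropped; 27 electrodes per hemisphere), and an independent
   branch (extractor $G_f^h$, classifier $G_y^h$, discriminator $G_d^h$) is
   trained per hemisphere $h \in \{l, r\}$. At prediction time each branch's
   discriminator output $z$ on a target sample yields a *perplexity*
   $$P_h(z) = -\log \frac{e^{z_{C+1}}}{\sum_{i=1}^{C+1} e^{z_i}},$$
   the negative log-softmax mass on the target-domain class. A branch whose
   discriminator can no longer confidently call its target samples "target"
   is well aligned, so a **higher** perplexity signals a more trustworthy
   branch. The classifiers are fused as the convex combination
   $W_l \, G_y^l + W_r \, G_y^r$ with $W_h = P_h / (P_l + P_r)$.

## Model and losses

Each branch is an MLP on flattened differential-entropy features
(27 channels × 5 bands = 135 inputs per hemisphere):

* extractor 135 → 128 → 64, each linear layer followed by batch
  normalization and LeakyReLU (slope 0.01), so the 64-dimensional
  representation is itself normalized and rectified;
* classifier 64 → 32 → C and discriminator 64 → 32 → C+1, both ending in
  log-softmax.

Training minimizes, per branch,
$$\mathcal{L} = \frac{1}{n_s}\sum_{i \in S} \ell_{ce}\big(G_y(G_f(x_i)), y_i\big)
  \; + \; \frac{\lambda}{n_s + n_t}\sum_{i \in S \cup T}
  \ell_{ce}\big(G_d(G_f(x_i)), d_i\big),$$
with $d_i = y_i$ on source and $d_i = C+1$ on target, a single Adam step per
batch on all parameters, and a gradient reversal layer between extractor and
discriminator. Every step draws one source batch and one target batch of
equal size (32 by default), cycling and reshuffling the shorter stream;
steps per epoch is `ceil(max(n_s, n_t) / batch_size)`. Batch normalization
uses the statistics of the mixed source+target batch during training and
running estimates at evaluation, so prediction is deterministic.

### Gradient-reversal routing

A design question the loss above leaves open is *which rows'* adversarial
gradient is reversed into the extractor. The classic DANN recipe reverses
the whole combined batch, which is coherent for a binary discriminator: the
domain label carries no class information, so "fool the discriminator
everywhere" is exactly marginal alignment. For the class-informed
discriminator the same routing has a destructive side effect: reversing the
*source* rows' class-CE pushes the extractor to hide the source class
structure, in direct opposition to the classification loss. In our
experiments on the synthetic task, full reversal makes the class-informed
model consistently *worse* than its own binary ablation, inverting the
method's central claim.

The package therefore reverses only the **target rows'** adversarial
gradient in the class-informed branches — the extractor learns to make
target features deceive the discriminator (land on source class modes),
while the source rows train the discriminator's class structure without
back-pressure on the extractor. The binary-discriminator ablation keeps the
classic full-batch reversal, its standard formulation. Both routings are
implemented (`nn_branch_grads(reversal =)`).

### Hyperparameters

| parameter | default | notes |
|---|---|---|
| `lambda` | 0.5 | adversarial weight; the useful range is 0.5–1, larger values destabilize the game at this learning rate |
| `learning_rate` | 0.01 | Adam, fixed (no schedule) |
| `batch_size` | 32 | per domain, so mixed batches hold 64 samples |
| `epochs` | 200 | fixed; no early stopping |
| GRL coefficient | 1 | the adversarial strength is carried entirely by `lambda` |
| LeakyReLU slope | 0.01 | |
| BN momentum / eps | 0.1 / 1e-5 | running stats use the unbiased batch variance |
| initialization | uniform fan-in | deterministic given `seed` |

Weight fusion is computed `per_sample` by default (the perplexity is defined
per target sample); `per_batch` mode, which applies batch-mean perplexities
to consecutive 32-sample batches, is provided because hemisphere-weight
trajectories are naturally inspected per batch. When $P_l + P_r < 10^{-12}$
the weights fall back to $(\tfrac12, \tfrac12)$; `no_perplexity` fixes them
there, and fusion always mixes probability vectors (exponentiated
log-softmax) — a convex mixture is the only combination that keeps the
output a distribution.

## Signal features

Raw EEG is resampled to 200 Hz (polyphase), band-pass filtered per band with
a zero-phase 5th-order Butterworth filter applied to the whole recording
(so filter transients never sit at window edges), segmented into 1-s
non-overlapping windows, and summarized per window, channel and band by the
Gaussian differential entropy in nats,
$$\mathrm{DE} = \tfrac12 \ln(2\pi e\, \sigma^2),$$
with $\sigma^2$ the within-window sample variance of the band-limited
signal. The five standard bands are delta 1–3, theta 4–7, alpha 8–13, beta
14–30 and gamma 31–50 Hz. A variance floor of $10^{-12}$ guards degenerate
(constant) windows against $-\infty$. The time-domain Gaussian form is used
throughout; whether published DE feature sets use a short-time-spectral
variance instead is not resolved here, and the closed form is what the test
suite validates against.

Normalization is a per-block z-score: each feature dimension is centred and
scaled within one subject (or one subject-session pair, the default) only.
No statistics are pooled across blocks and labels are never touched, so
source and target can be normalized without leakage.

## Evaluation protocols

`make_splits()` builds leave-one-subject-out plans (per session, each
subject in turn is the target; sessions × subjects experiments) and
cross-session plans (per subject, each session in turn is the target;
subjects × sessions experiments). For 15 subjects × 3 sessions both yield
45 experiments. `run_protocol()` re-initializes the model per experiment
from a derived seed (`seed + experiment index`), and supports band-subset
restriction, uniform source subsampling (20–100%) and Gaussian feature-noise
injection for robustness sweeps. Paired comparisons between variants use a
two-sided Wilcoxon signed-rank test by default (a paired t-test is the
alternative); the test statistic is not prescribed by the protocol
definition, and the signed-rank default was chosen as the robust choice for
small paired accuracy samples. All p-value families are Holm–Bonferroni
adjusted via `stats::p.adjust`.

## The synthetic generator

Licensed EEG emotion datasets cannot ship with the package, so every
end-to-end property is exercised on a synthetic population
(`generate_population()`) designed to emulate the statistical structure the
method targets:

* **class-conditional multimodality** — per hemisphere, C class means on a
  randomly rotated simplex with equal pairwise distance `class_separation`
  (default 3) in units of the within-class standard deviation (1);
* **per-subject domain shift** — each subject carries an additive offset
  drawn $N(0, \texttt{subject\_shift\_scale}^2 I)$ per dimension (default 2)
  plus a mild multiplicative per-dimension scale jitter (log-sd
  $0.05 \times$ the shift scale; a literal log-sd of 2 would scale features
  by $e^{\pm 2}$, which no EEG normalization regime resembles);
* **session shift** — a smaller per-session offset (sd = half the subject
  shift), so cross-session transfer is easier than cross-subject transfer,
  matching what the protocols are meant to show;
* **lateralization** — the right hemisphere's class separation is multiplied
  by `asymmetry_factor` (default 2);
* **confusion-biased shifts** (`shift_mode = "class_confusion"`) — the
  offset points along the mean difference of a random class pair at ~0.4 of
  the between-class distance. The magnitude matters: at 0.4 each class's own
  mode is still its nearest mode, so the crossed alignment is identifiably
  wrong, yet the marginal pull toward the confused solution is strong enough
  to mislead a binary discriminator. At magnitudes ≥ 0.5 the crossing
  becomes the nearest-mode solution and no unsupervised method can recover
  it.

Defaults are 10 subjects × 3 sessions × 3 classes × 40 samples per class and
session, 27 channels × 5 bands per hemisphere (the 135-dimensional input the
model is sized for). Generation is a pure function of the spec (including
its seed).

What the generator does *not* emulate: temporal autocorrelation within
sessions, non-Gaussian class shapes, volume-conduction correlation between
channels, and — importantly — domain shifts that survive per-block
z-scoring. The affine shift model is exactly removed by per-subject
normalization, so the adaptation experiments below run on raw generated
features; passing them shows the adversarial machinery recovers an affine
shift, not that it handles every real-world shift.

## What the end-to-end experiments show

The acceptance-style experiments (also run by `scripts/acceptance.R`) use
the generator defaults, lambda 0.5 and 200 epochs:

* **Adaptation recovery** — single-branch training with the class-informed
  discriminator vs. the identical run with the adversarial term disabled,
  target = one held-out subject. Under the test suite's fixed training seeds
  the adversarial term recovers ~18 accuracy points on average over the five
  populations. The estimate is noisy in *both* of its inputs: a random
  subject offset may or may not intersect the class-discriminative subspace
  (population luck), and the no-adaptation baseline's target accuracy swings
  by ±15 points with initialization alone — its mixed-batch batch-norm
  statistics already absorb target data (an implicit AdaBN-style
  adaptation), and the orientation of the learned boundary in the
  unconstrained offset direction is pure init luck. Across independent
  training-seed sets the five-population mean gain ranged from +2 to +18
  points (mean ≈ +10) in our runs; the acceptance script reports whatever
  its `--seed` produces.
* **Class-informed vs. binary** — under confusion-biased shifts the C+1
  discriminator matches or beats the binary one on most populations, the
  regime the class-informed design argues for.
* **Lateralized fusion** — with asymmetry 2, the right hemisphere carries
  the stronger class structure. That does not make its *branch* better: a
  strongly structured hemisphere also hands its discriminator an easier job,
  and when the discriminator wins the adversarial game outright (its loss
  saturates near zero) the reversed gradient vanishes — the branch stops
  aligning, its target accuracy stays near the unadapted baseline, and its
  perplexity collapses toward zero. On the default generator this dominance
  regime is the rule for the right branch, so the left branch (which aligns
  to its perfect-alignment perplexity ceiling of $\log 2$) ends up both
  better transferred and more heavily weighted: the perplexity mechanism
  correctly routes weight to the better-*aligned* branch, but the premise
  that the more separable hemisphere is also the better-aligned one does not
  hold under an affine shift of equal magnitude in both hemispheres. The
  mean right-hemisphere weight the acceptance script reports is therefore
  far below one half — the opposite of the directional pattern seen on real
  recordings, where cross-subject variability itself is lateralized. The
  discriminator-dominance failure mode is a known property of
  fixed-weight saturating adversarial games (the formulation here uses a
  fixed lambda, no ramp, and the reversed — hence saturating — objective)
  and is reported honestly rather than patched around.

## Numerical choices and degenerate inputs

* log-sum-exp is max-shifted everywhere; both heads emit normalized
  log-probabilities (row log-sum-exp = 0 within 1e-6).
* Argmax ties break to the lowest class index, deterministically.
* A zero-variance DE window hits the 1e-12 variance floor; a zero-variance
  normalization dimension is centred but left unscaled; a single-sample
  normalization block is an error.
* Non-finite training losses abort with a diagnostic rather than propagate.
* `lambda = 0` is bit-identical to source-only training under the same seed
  (the test suite asserts this), because the mixed batch still flows through
  batch normalization identically.
* An empty target degrades to source-only training with a warning.

## Problem sizes in the test suite

Unit tests run on toy geometries (a few channels, a few epochs). The
end-to-end experiments use the default population (3,600 samples per
hemisphere, 135 dimensions) with one held-out-subject experiment per seed
and five seeds per claim — about 10–15 minutes of single-core compute for
the full suite, the package's chosen trade-off between statistical
resolution and a test suite contributors will actually run.

## Known limitations

* The adversarial game uses a fixed lambda with no ramp; branches with very
  strong domain separability can reach discriminator dominance (see above).
* The perplexity weight is a proxy for alignment quality, not a calibrated
  probability; its failure mode is exactly the dominance regime.
* The generator's affine shift understates real cross-subject EEG
  variability; results on it bound what the pipeline can show.
* Raw-EEG ingestion expects numeric channel × time matrices; vendor format
  parsing is out of scope.
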