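---
title: "Adversarial cross-subject EEG emotion decoding with tddann"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial cross-subject EEG emotion decoding with tddann}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tddann)
```

## The problem

EEG responses to the same emotional stimulus differ markedly between people:
a classifier trained on a group of subjects degrades, often severely, on a
new subject. `tddann` implements a two-discriminator domain adversarial
network (TD-DANN) for decoding emotion classes from per-segment
differential-entropy (DE) features laid out as channels x frequency bands
(62 x 5 in the SEED datasets). A labeled *source* domain and an unlabeled
*target* domain (held-out trials of the same subject, or a held-out subject)
are trained jointly: the feature extractor learns representations that
classify source emotions well while discriminators, coupled through gradient
reversal, remove domain- and subject-specific structure.

## Model

**Graph-convolutional extractor.** Channels are nodes of a learned graph.
The adjacency $A$ is a free symmetric parameter, initialized uniform on
$(-1/\sqrt{N}, 1/\sqrt{N})$ and updated by backpropagation; no electrode
geometry is used. At every forward pass the propagation operator is rebuilt
from the live parameter:

$$A' = \mathrm{ReLU}(A), \quad D_{ii} = \sum_j A'_{ij}, \quad
  L = D^{-1/2} A' D^{-1/2},$$

and a Chebyshev filter bank $T_0 = I$, $T_1 = L$,
$T_k = 2 L T_{k-1} - T_{k-2}$ feeds the convolution
$Z = \sum_{k=0}^{K-1} T_k(L)\, X W_k$, followed by a Leaky ReLU. The
rectification keeps edge weights nonnegative; the symmetric normalization
bounds the spectrum of $L$ in $[-1, 1]$, so the recursion cannot blow up.
Symmetry of $A$ is enforced structurally — the stored parameter is
unconstrained and $(A + A^\top)/2$ is used everywhere — so no projection
step is needed after optimizer updates.

**Heads.** The emotion classifier is a linear layer on the flattened
extractor output. Two adversarial heads see the concatenated source and
target features: a binary *domain discriminator* (source vs target) and a
multi-class *individual discriminator* over subject identity. Both are
two-layer perceptrons (`d_feat -> 128 -> out`); the architecture is the
smallest standard shape that fits the adversarial games, and widths are
configurable.

**Gradient reversal and its schedule.** Each discriminator is attached
through a gradient reversal layer: identity forward, gradient scaled by
$-\mathrm{coeff}$ backward. The strength ramps along a sigmoid in the
iteration count,

$$\mathrm{coeff} = \frac{2(hi - lo)}{1 + e^{-\alpha\,\mathrm{iter}/\mathrm{max\_iters}}}
  - (hi - lo) + lo,$$

from exactly $lo$ at iteration 0 toward (never reaching) $hi$, with
defaults $hi = 0.9$, $lo = 0.5$, $\alpha = 10$. Early training therefore
favors learning usable features; adversarial pressure grows later.

**Objective.**
$$L_{total} = L_{cls} + L_{domain} + L_{individual} + \lambda\, L_{cluster}$$

* $L_{cls}$: one-vs-all binary cross-entropy of per-class sigmoid scores
  against one-hot source labels, averaged over rows and classes. This is the
  literal reading of the published objective for a 3/4-class problem; the
  conventional softmax cross-entropy is available via
  `cls_head = "softmax_ce"`.
* $L_{domain} = \tfrac12[\mathrm{BCE}(d_S, 1) + \mathrm{BCE}(d_t, 0)]$, the
  symmetric domain game. Batches are balanced 50/50 source/target to match
  this symmetry.
* $L_{individual} = \mathrm{CE}(p, id)$ over subject identity, for all rows
  of the batch.
* $L_{cluster}$: confident target rows (maximum class probability at least
  $\tau = 0.9$ by default, or a top-fraction rule) have their domain
  probability pushed toward the source label 1, compacting the target
  representation on the source side of the decision boundary.
  $N_{selected} = 0$ simply drops the term for that batch.

Probabilities inside logs are clamped to $[10^{-7}, 1 - 10^{-7}]$.

## Design choices on genuinely open points

* **Cluster-term routing.** The cluster loss is computed from the same
  domain-discriminator outputs as the domain game, but its gradient reaches
  the extractor *without* reversal. Reversing it would push selected target
  features away from the source side — the opposite of its stated purpose
  (decision-space compactness). The discriminator's own parameters receive
  the cluster gradient as part of the total objective. No third
  "target discriminator" network exists.
* **Individual-branch reversal strength.** The role of the individual
  discriminator is to balance domain alignment against the loss of
  subject-specific emotion patterns; full reversal at domain strength
  suppresses exactly the structure the branch is meant to preserve, and the
  two readings (adversarial vs cooperative) cannot both be taken literally.
  Both are implemented: `individual_hi` / `individual_lo` give the branch
  its own schedule — positive values reverse, 0 detaches the branch from
  the extractor, and negative values make it cooperative. On the bundled
  synthetic benchmark a weak reversal was the most favorable setting and is
  the package default (`individual_hi = 0.3`, `individual_lo = 0.1`);
  sharing the domain schedule is a one-line config change.
* **Xavier bound.** The published adjacency-initialization bound is typeset
  ambiguously; it is read as $1/\sqrt{N}$ (the Xavier-uniform bound for a
  square matrix), with `adjacency_bound` as an override.
* **Depth vs order.** The Chebyshev order is the only printed structural
  constant ($K = 3$). The number of stacked graph-conv layers and the
  per-channel width are not stated; the defaults are one layer with
  $F_{out} = 32$ (so `d_feat` $= N \times 32$), both configurable. The
  reported sweep over "layer number K" is interpretable as either the order
  or the depth; both are runnable via `cheb_order` and `gcn_layers`.
* **Accuracy reporting.** The final-epoch target accuracy is reported (the
  best epoch is also tracked when `record_best = TRUE`), since the choice
  between best- and final-epoch is not stated.
* **Input scaling.** Each (channel, band) feature is z-scored using the
  pooled source + target segments of the split (`normalize_features`,
  label-free and standard for DE features). Without it the discriminators
  saturate on raw feature scales and the adversarial gradients vanish.
* **Optimizer.** RMSprop with learning rate 5e-4 and L2 weight decay 1e-4
  on every learnable parameter, the adjacency included (the published
  regularization statement does not restrict its scope). Smoothing constant
  0.99 and stabilizer 1e-8 are the conventional library defaults. The
  reversal iteration counter advances once per optimizer step, against
  `max_iters = steps_per_epoch * epochs`.

## Protocols

* **Subject-dependent:** per (subject, session), ordered trials are split
  9/6 (15-trial, 3-class layout) or 16/8 (24-trial, 4-class layout) into
  source/target. With a single subject the individual discriminator is
  disabled automatically — one-class subject cross-entropy is degenerate.
* **Leave-one-subject-out (LOSO):** each subject in turn is the unlabeled
  target; all others are the source. Accuracy is summarized as mean and
  sample standard deviation (n - 1; the aggregation denominator is not
  stated in the protocol definitions) across splits, with confusion
  matrices pooled over splits before row normalization.

Target emotion labels never contribute to any gradient; the test suite
corrupts them and asserts bit-identical training.

## The synthetic benchmark

Real SEED-style recordings are registration-gated, so the package ships a
generator that reproduces the statistical structure the method assumes,
with a known ground truth:

* **class structure** — each class has a latent mean over channels x bands
  built from channel *communities* (channels in a community share band
  profiles), centered across classes;
* **graph-structured correlations** — community-level noise shared by the
  channels of a community, giving higher within- than between-community
  correlation;
* **subject shift** — each subject observes the latent signals through a
  near-identity channel-mixing matrix $G_s = I + s\,\mathcal N(0, 1/N)$
  plus a small offset: class geometry is distorted per subject (hurting
  cross-subject transfer) while feature means stay roughly aligned, and the
  distortion is linearly correctable — matching what a channel-mixing graph
  filter can undo;
* **trial-to-trial nonstationarity** — every trial re-jitters the mixing
  matrix from the same family, so each domain spans a cloud of mixing
  conditions that overlaps the others. Without this overlap the
  discriminators separate the domains perfectly within an epoch and the
  reversed gradients vanish; with it the adversarial game stays active, as
  it does on real nonstationary EEG.

Default scales (`class_separation = 0.6`, `subject_shift = 1.0`,
`trial_jitter = 0.8`, unit noise, 6 subjects x 15 trials x 25 segments,
16 channels x 5 bands, 3 classes) were calibrated once so that a
source-only classifier shows a clear cross-subject drop and the adversarial
variants have headroom to close part of it on a laptop CPU in minutes;
they are the package's standing benchmark conditions, not tuning knobs.
At much larger per-subject sample sizes the source-only baseline catches
up and the headroom closes — the adaptation problem the benchmark poses is
deliberately in the scarce-data regime where transfer matters.
What passing this benchmark shows is that the adversarial machinery works
end to end under the assumed statistical structure; it does not certify
accuracy on real EEG, which has richer artifacts (volume conduction,
1/f spectra, electrode drift) that the generator deliberately omits.

Benchmark runs in the test suite use 40 epochs, 5 paired seeds and one
rotating LOSO fold per seed — sizes chosen so the whole suite stays a
desk-scale run; the full protocol (1000 epochs, all folds) is a config
change, not a code change.

## Numerical notes

* All forward/backward passes are explicit matrix algebra; every gradient
  path (adjacency normalization, Chebyshev recursion, reversal layers,
  losses) is finite-difference-checked in the tests to 1e-4 or better.
* Zero-degree channels (possible early in training, when rectification
  isolates a node) are guarded by `max(D_ii, 1e-8)` and produce exact zero
  rows in $L$ with zero gradient through the dead branch.
* Determinism: every parameter draw and every epoch's shuffling derives
  from the master seed; identical configs reproduce loss histories
  bit-for-bit.
* Degenerate inputs: empty confident-target selections contribute zero
  loss; partial final batches are allowed (the larger domain keeps filling
  batches after the smaller is exhausted); single-subject splits disable
  the individual branch.

## Known limitations

* The similarity-matrix phrasing for target-sample selection is not
  formulated in the source description; only the high-confidence reading is
  implemented (threshold and top-fraction rules).
* The MAT reader covers numeric arrays in the v5/v7 dialects plus
  HDF5-based files; cell arrays and structs (present in some raw-EEG
  releases, not in extracted-feature files) are rejected with a clear
  error.
* The 2-D feature embedding for inspection is PCA, a deterministic linear
  map, rather than a stochastic neighbor embedding.
* Training is CPU-bound R matrix algebra: fine for the benchmark scale,
  slow for 1000-epoch runs over 45 real-data splits.
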