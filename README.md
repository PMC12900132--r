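# tddann

Cross-subject emotion decoding from non-invasive EEG with a
**two-discriminator domain adversarial network** (TD-DANN), in pure R.

EEG emotion decoders degrade badly on people they were not trained on:
brain responses to the same stimulus differ per subject, and the
relationships between the 62 recording channels are themselves informative
and subject-dependent. `tddann` addresses both problems at once:

* a **spectral graph convolution feature extractor** over a *learnable*
  channel adjacency `A` — normalized as `L = D^{-1/2} ReLU(A) D^{-1/2}` and
  expanded in Chebyshev polynomials `T_k(L)` (order `K = 3`) — models
  inter-channel structure without any electrode-geometry prior;
* a **domain discriminator** (source vs target) and an **individual
  discriminator** (which subject produced a segment), each behind a
  **gradient reversal layer** whose strength ramps along a sigmoid schedule
  `coeff = 2(hi-lo)/(1+e^{-α·iter/max_iters}) - (hi-lo) + lo` from `lo = 0.5`
  toward `hi = 0.9`, shape adversarial training so that learned features
  transfer across subjects;
* a **confidence-selected target cluster loss** pushes confidently
  classified, unlabeled target segments toward the source side of the
  domain decision boundary, compacting the target representation.

The total objective is
`L_total = L_cls + L_domain + L_individual + λ·L_cluster`, minimized with
RMSprop (lr 5e-4, L2 1e-4, batch 96 split 50/50 source/target).

The package reads SEED / SEED-IV–style extracted differential-entropy
feature MAT files (v5, v7 and HDF5 dialects), implements the
subject-dependent (9/6 and 16/8 trial splits) and leave-one-subject-out
protocols, and ships a synthetic multi-subject generator with class
structure, per-subject channel-mixing shift and graph-structured channel
correlations, so the entire pipeline runs with no downloads. All
forward/backward passes are explicit, finite-difference-verified matrix
algebra — no deep-learning framework is required.

## Worked example

Generate a six-subject benchmark, hold out subject 1, and train the full
adversarial model against a source-only baseline:

```r
library(tddann)

gen   <- synth_generate(synth_spec(seed = 11))
split <- make_loso_splits(gen$data)[[1]]
split
#> <protocol_split> loso: 1875 source / 375 target segments (subject 1 held out as target)

cfg <- train_config(epochs = 40, seed = 11)   # reduced from the 1000-epoch protocol
fit <- train_model(split, cfg)
fit
#> <tddann_fit> 40 epochs; final target accuracy 0.616, total loss 0.5288

base <- train_config(epochs = 40, seed = 11, use_domain = FALSE,
                     use_individual = FALSE, lambda_cluster = 0)
tail(train_model(split, base)$history$target_accuracy, 1)
#> [1] 0.608

evaluate_model(fit, split$target)$confusion
#>     pred
#> true  0  1  2
#>    0 73 30 22
#>    1 17 98 10
#>    2 42 29 54
```

On this single fold the adversarial model edges out the plain source
classifier by under a point; the interesting comparison is the paired one
across seeds, where the full model consistently sits above its ablations
(the confusion matrix above also shows the typical structure of the
remaining errors — here classes 0 and 2 bleed into each other). The paired
ablation benchmark is one call:

```r
bench <- run_synthetic_benchmark(seeds = 1:5,
                                 variants = c("full", "no_individual",
                                              "no_gcn", "source_only"))
summarize_benchmark(bench)
```

A thin command-line wrapper covers the same ground
(`exec/tddann synth|train|ablate --help`), and `load_seed_features()` plugs
the real registration-gated datasets into the identical machinery.

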