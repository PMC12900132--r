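Package: tddann
Title: Two-Discriminator Domain Adversarial Networks for EEG Emotion Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decodes emotion classes from multichannel electroencephalography
    (EEG) differential-entropy features with a two-discriminator domain
    adversarial neural network (TD-DANN). The feature extractor is a spectral
    graph convolution over a learnable, symmetrically normalized channel
    adjacency using Chebyshev polynomial filters; a domain discriminator and an
    individual (subject) discriminator sit behind gradient reversal layers with
    a sigmoid-scheduled reversal strength, and a confidence-selected target
    clustering loss compacts unlabeled target-domain representations in
    decision space. Includes readers for SEED-style extracted-feature MAT
    files, subject-dependent and leave-one-subject-out evaluation protocols,
    a multi-subject synthetic data generator with class structure, per-subject
    distribution shift and graph-structured channel correlations, and
    reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
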