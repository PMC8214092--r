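Package: modalprobe
Title: Hebbian Modality Probes and Bit-Injection Experiments for Bimodal
    Convolutional Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether the sensory modality of an input
    (image versus sound) is implicitly represented in the hidden layers of a
    convolutional classifier trained on a bimodal corpus, and whether feeding
    that decoded one-bit signal back into a second network changes its
    learning. Provides a synthetic bimodal corpus generator with the full
    sound-to-image preprocessing pipeline (Mel spectrogram, zero-padding, max
    pooling to 28x28), supervised Hebbian probes that decode modality from
    sign-binarized dense-layer pre-activations, a small convolutional network
    stack in four variants (baseline, experimental bit-injection, expanded
    base and constant-input controls), a seeded experiment runner implementing
    the pretrain/freeze protocol, and a nonparametric comparison battery
    (Kruskal-Wallis, Conover post hoc with Holm correction, Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
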