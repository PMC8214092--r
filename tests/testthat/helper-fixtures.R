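## Small shared fixtures, generated in code.

## tiny corpus configuration: fast to assemble, still bimodal + stratified
tinyCorpus <- function(seed = 1L, nClasses = 2L, perClass = 10L) {
    corpusConfig(nImageClasses = nClasses, nSoundClasses = nClasses,
                 samplesPerClass = perClass, seed = seed)
}

## training configuration small enough for unit tests
tinyTraining <- function(...) {
    deskTrainingConfig(batchSize = 32L, epochs = 2L, stepsPerEpoch = 5L,
                       runs = 2L, ...)
}

## deterministic fake "pre-activation" set whose sign patterns are
## modality-separable in one coordinate
separablePreacts <- function(n = 20, width = 6) {
    lab <- rep(c(1, -1), length.out = n)
    x <- matrix(rnorm(width * n, sd = 0.3), width, n)
    x[1, ] <- lab * (1 + abs(x[1, ]))   # coordinate 1 carries the modality
    list(preact = x, label = lab)
}
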