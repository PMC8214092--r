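cfgSmall <- tinyCorpus(seed = 4, nClasses = 3, perClass = 10)

test_that("synthetic image templates are deterministic and distinct", {
    a <- synthImage(0, cfgSmall, noise = 0)
    b <- synthImage(0, cfgSmall, noise = 0)
    expect_identical(a, b)
    expect_equal(dim(a), c(28L, 28L))
    expect_true(min(a) >= 0 && max(a) <= 1)
    expect_true(any(synthImage(1, cfgSmall, noise = 0) != a))
    expect_error(synthImage(3, cfgSmall), "range")
    ## noisy samples stay in range and are reproducible under a fixed seed
    set.seed(1); n1 <- synthImage(2, cfgSmall)
    set.seed(1); n2 <- synthImage(2, cfgSmall)
    expect_identical(n1, n2)
    expect_true(min(n1) >= 0 && max(n1) <= 1)
})

test_that("image templates are linearly separable across classes", {
    ## train a multinomial linear separator (one-vs-rest least squares on
    ## pixels) as an independent oracle of separability
    cfg <- corpusConfig(nImageClasses = 4, nSoundClasses = 4,
                        samplesPerClass = 200, seed = 99)
    set.seed(99)
    n <- 4 * 200
    X <- matrix(0, n, 784); y <- integer(n)
    for (i in seq_len(n)) {
        y[i] <- (i - 1L) %% 4L
        X[i, ] <- as.vector(synthImage(y[i], cfg))
    }
    holdout <- sample(n, 160)
    Y <- sapply(0:3, function(k) as.numeric(y == k))
    Xtr <- cbind(1, X[-holdout, ])
    beta <- solve(crossprod(Xtr) + diag(1e-2, 785),
                  crossprod(Xtr, Y[-holdout, ]))
    pred <- max.col(cbind(1, X[holdout, ]) %*% beta) - 1L
    expect_gt(mean(pred == y[holdout]), 0.9)
})

test_that("synthetic waveforms have the configured length and distinct peaks", {
    w <- synthWaveform(0, cfgSmall, noise = 0)
    expect_equal(length(w), 22050L)
    expect_true(all(abs(w@samples) <= 1))
    expect_identical(w@samples, synthWaveform(0, cfgSmall, noise = 0)@samples)
    ## dominant DFT peak differs between classes (discrete transform oracle)
    peak <- function(s) which.max(Mod(fft(s))[1:11025])
    expect_false(peak(synthWaveform(0, cfgSmall, noise = 0)@samples) ==
                 peak(synthWaveform(1, cfgSmall, noise = 0)@samples))
    expect_error(synthWaveform(5, cfgSmall), "range")
})

test_that("mel spectrogram has the documented 128 x 44 shape", {
    w <- synthWaveform(1, cfgSmall, noise = 0)
    m <- melSpectrogram(w, cfgSmall)
    expect_equal(dim(m), c(128L, 44L))
    expect_true(all(m >= 0))
    ## frame count formula: floor(len / hop) + 1
    expect_equal(ncol(m), 22050L %/% 512L + 1L)
    ## all-zero waveform gives an all-zero power spectrogram
    z <- new("Waveform", samples = numeric(22050), rate = 22050)
    expect_equal(max(abs(melSpectrogram(z, cfgSmall))), 0)
    expect_error(melSpectrogram(numeric(0), cfgSmall), "empty")
})

test_that("pad-and-pool reduces 128 x 44 to 28 x 28 without inventing values", {
    w <- synthWaveform(2, cfgSmall, noise = 0)
    m <- melSpectrogram(w, cfgSmall)
    p <- poolToImageShape(m)
    expect_equal(dim(p), c(28L, 28L))
    expect_equal(max(p), max(m))       # pooling preserves the global max
    expect_true(all(p %in% c(0, m)))   # every output value exists in input
    expect_equal(poolToImageShape(matrix(0, 128, 44)), matrix(0, 28, 28))
    ## a single nonzero cell at (1,1) survives at (1,1)
    m1 <- matrix(0, 128, 44); m1[1, 1] <- 5
    p1 <- poolToImageShape(m1)
    expect_equal(p1[1, 1], 5)
    expect_equal(sum(p1 != 0), 1L)
    expect_error(poolToImageShape(matrix(0, 100, 44)), "128 x 44")
})

test_that("min-max normalization maps and reuses training statistics", {
    out <- normalizeSamples(matrix(c(0, 5, 10, 2), 2))
    expect_equal(out$stats, c(0, 10))
    expect_equal(out$samples[2, 1], 0.5)
    ## already-[0,1] data with full range is unchanged
    x <- matrix(c(0, 0.25, 1, 0.5), 2)
    expect_equal(normalizeSamples(x)$samples, x)
    ## validation values above the training max are clipped to 1
    val <- normalizeSamples(matrix(c(12, 5), 1), stats = c(0, 10))
    expect_equal(as.vector(val$samples), c(1, 0.5))
    expect_warning(constant <- normalizeSamples(matrix(3, 2, 2)), "constant")
    expect_equal(as.vector(constant$samples), rep(0, 4))
})

test_that("entity and concept assembly produce the documented label spaces", {
    ds <- assembleEntity(cfgSmall)
    expect_s4_class(ds, "BimodalDataset")
    expect_equal(nLabels(ds), 6L)   # 3 image + 3 sound classes
    cd <- SummarizedExperiment::colData(ds)
    ## disjoint label blocks per modality
    expect_equal(sort(unique(cd$label[cd$modality == -1L])), 0:2)
    expect_equal(sort(unique(cd$label[cd$modality == 1L])), 3:5)
    expect_true(all(pixelMatrix(ds) >= 0 & pixelMatrix(ds) <= 1))

    dc <- assembleConcept(cfgSmall)
    expect_equal(nLabels(dc), 3L)
    pm <- pairMap(dc)
    expect_equal(sort(pm$soundClass), 0:2)
    expect_false(anyDuplicated(pm$imageClass) > 0)  # bijection
    ## paired classes share a label; modality tag retained
    cdc <- SummarizedExperiment::colData(dc)
    expect_equal(sort(unique(cdc$label)), 0:2)
    expect_equal(sort(unique(cdc$modality)), c(-1L, 1L))

    expect_error(assembleConcept(corpusConfig(nImageClasses = 2,
                                              nSoundClasses = 3,
                                              samplesPerClass = 2)),
                 "equal")
})

test_that("assembly is reproducible bit-for-bit from its seed", {
    a <- assembleEntity(tinyCorpus(seed = 21))
    b <- assembleEntity(tinyCorpus(seed = 21))
    expect_identical(pixelMatrix(a), pixelMatrix(b))
    expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                     as.data.frame(SummarizedExperiment::colData(b)))
    c <- assembleEntity(tinyCorpus(seed = 22))
    expect_false(identical(pixelMatrix(a), pixelMatrix(c)))
})

test_that("stratified split reserves the configured fraction per class", {
    set.seed(3)
    cls <- rep(0:4, each = 200)
    isVal <- splitValidation(cls, 0.2)
    expect_equal(sum(isVal), 200L)                # 20% of 1000
    expect_true(all(tapply(isVal, cls, sum) == 40))
    ## partitions are disjoint and cover the input by construction;
    ## small-sample rounding stays within +-1 per class
    small <- splitValidation(rep(0L, 10), 0.2)
    expect_equal(sum(small), 2L)
    expect_error(splitValidation(cls, 1.2), "between 0 and 1")
})

test_that("batch sampling balances modalities via a fair coin", {
    ds <- assembleEntity(tinyCorpus(seed = 8, nClasses = 2, perClass = 30))
    set.seed(101)
    b <- sampleBatch(ds, 128L)
    expect_equal(ncol(b$pixels), 128L)
    expect_equal(length(b$label), 128L)
    ## reproducible under the same RNG state
    set.seed(101)
    b2 <- sampleBatch(ds, 128L)
    expect_identical(b$pixels, b2$pixels)
    ## sound fraction over many draws within 3 binomial standard errors
    set.seed(55)
    n <- 10000L
    got <- sampleBatch(ds, n)
    frac <- mean(got$modality == 1L)
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
    ## batches only ever draw from the training partition
    expect_true(all(got$label %in% 0:3))
})

test_that("corpus export and import round-trip", {
    ds <- assembleConcept(tinyCorpus(seed = 13))
    dir <- tempfile("corpus")
    exportCorpus(ds, dir)
    back <- importCorpus(dir)
    expect_equal(pixelMatrix(back), pixelMatrix(ds))
    expect_equal(taskType(back), "concept")
    expect_equal(nLabels(back), nLabels(ds))
    expect_equal(pairMap(back), pairMap(ds))
    expect_equal(back$modality, ds$modality)
    unlink(dir, recursive = TRUE)
})
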