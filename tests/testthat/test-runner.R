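dsTiny <- assembleEntity(tinyCorpus(seed = 40, nClasses = 2, perClass = 20))

test_that("probe updates never modify the host network", {
    cfg <- tinyTraining(seed = 2)
    m1 <- buildModel(entityArchitecture(), "baseline", nLabels(dsTiny),
                     seed = 50)
    m2 <- buildModel(entityArchitecture(), "baseline", nLabels(dsTiny),
                     seed = 50)
    probes <- list(hebbianProbe(512), hebbianProbe(288))
    set.seed(60)
    withProbes <- trainEpoch(m1, dsTiny, cfg, probes = probes)
    set.seed(60)
    without <- trainEpoch(m2, dsTiny, cfg)
    ## identical batches, one with probe updates: weights bit-identical
    expect_identical(m1@state$params, m2@state$params)
    expect_equal(withProbes$record$val_loss, without$record$val_loss)
    ## probes actually learned something
    expect_gt(withProbes$probes[[1]]@updatesSeen, 0L)
})

test_that("a zero-step epoch reports the untrained model's metrics", {
    cfg <- tinyTraining(stepsPerEpoch = 0L, seed = 2)
    m <- buildModel(entityArchitecture(), "baseline", nLabels(dsTiny),
                    seed = 51)
    da <- modalprobe:::datasetArrays(dsTiny)
    before <- evaluateModel(m, da$valPixels, da$valLabel)
    out <- trainEpoch(m, dsTiny, cfg)
    expect_equal(out$record$val_loss, before$loss)
    expect_equal(out$record$val_acc, before$accuracy)
})

test_that("label-count mismatches are rejected", {
    m <- buildModel(entityArchitecture(), "baseline", 33, seed = 1)
    expect_error(trainEpoch(m, dsTiny, tinyTraining()), "labels")
})

test_that("pretraining freezes model and best probe on the synthetic corpus", {
    cfg <- deskTrainingConfig(batchSize = 64L, stepsPerEpoch = 40L,
                              maxPretrainEpochs = 4L, seed = 3)
    m <- buildModel(entityArchitecture(), "baseline", nLabels(dsTiny),
                    seed = 52)
    set.seed(70)
    fp <- pretrainAndFreeze(m, dsTiny, cfg)
    expect_true(isFrozen(fp$model))
    expect_gt(fp$accuracy, cfg@freezeThreshold)
    expect_true(fp$layer %in% 1:2)
    expect_lte(fp$epochsUsed, 4L)
    ## probe weights are zero at each epoch start, so the frozen probe's
    ## update count covers exactly the epochs' steps
    expect_equal(fp$probe@updatesSeen, 64L * 40L)
    expect_error(pretrainAndFreeze(
        buildModel(entityArchitecture(), "experimental",
                   nLabels(dsTiny), seed = 1), dsTiny, cfg), "baseline")
})

test_that("the freeze criterion signals when taps carry no modality", {
    ## a dataset whose two modalities have identical pixels cannot be
    ## decoded from any tap
    ds <- dsTiny
    px <- pixelMatrix(ds)
    half <- ds$modality == 1L
    ## copy image pixels onto the sound samples, class-matched
    for (cl in unique(ds$classId)) {
        src <- which(!half & ds$classId == cl)
        dst <- which(half & ds$classId == cl)
        px[, dst] <- px[, src[seq_along(dst)]]
    }
    SummarizedExperiment::assay(ds, "pixels") <- px
    ds$label[half] <- ds$label[!half][1]  # keep labels valid
    cfg <- tinyTraining(maxPretrainEpochs = 2L, seed = 4)
    m <- buildModel(entityArchitecture(), "baseline", nLabels(ds),
                    seed = 53)
    set.seed(71)
    err <- tryCatch(pretrainAndFreeze(m, ds, cfg), condition = identity)
    expect_s3_class(err, "modalprobe_criterion_not_met")
    expect_length(err$bestAccuracies, 2L)
    expect_true(all(err$bestAccuracies < 0.99))
})

test_that("experimental training leaves frozen components bit-identical", {
    cfg <- deskTrainingConfig(batchSize = 64L, stepsPerEpoch = 40L,
                              epochs = 2L, maxPretrainEpochs = 4L, seed = 5)
    base <- buildModel(entityArchitecture(), "baseline", nLabels(dsTiny),
                       seed = 54)
    set.seed(72)
    fp <- pretrainAndFreeze(base, dsTiny, cfg)
    frozenW <- lapply(fp$model@state$params, function(p) p + 0)
    frozenProbe <- probeWeights(fp$probe)
    exp <- buildModel(entityArchitecture(), "experimental",
                      nLabels(dsTiny), seed = 55)
    rec <- trainVariant(exp, dsTiny, cfg, frozenPair = fp)
    expect_identical(fp$model@state$params, frozenW)
    expect_identical(probeWeights(fp$probe), frozenProbe)
    expect_equal(nrow(rec), 2L)
    expect_true(all(rec$val_loss >= 0))

    ## a perfectly accurate probe delivers the true modality label
    da <- modalprobe:::datasetArrays(dsTiny)
    bitFun <- modalprobe:::variantBitFun("experimental", fp)
    bits <- bitFun(da$valPixels)
    expect_equal(mean(bits == da$valModality), fp$accuracy,
                 tolerance = 0.05)

    ## unfrozen donor is rejected
    fake <- list(model = buildModel(entityArchitecture(), "baseline",
                                    nLabels(dsTiny), seed = 56),
                 probe = fp$probe, layer = 1L)
    expect_error(trainVariant(exp, dsTiny, cfg, frozenPair = fake),
                 "unfrozen")

    ## the constant-input variant trains through the same loop on bit 1
    const <- buildModel(entityArchitecture(), "constant_input",
                        nLabels(dsTiny), seed = 57)
    recC <- trainVariant(const, dsTiny, cfg, frozenPair = fp)
    expect_equal(nrow(recC), 2L)
})

test_that("run summaries take the first minimum, 1-based", {
    expect_equal(runSummary(c(0.5, 0.3, 0.4)),
                 list(minValLoss = 0.3, epochOfMin = 2L))
    expect_equal(runSummary(c(0.3, 0.3))$epochOfMin, 1L)
})

test_that("conditionSpec mirrors the four-condition design table", {
    c1 <- conditionSpec(1)
    expect_equal(c1@dataset, "entity")
    expect_equal(c1@modelSpec, "entity")
    expect_setequal(c1@variants, modelVariantNames())
    c3 <- conditionSpec(3)
    expect_equal(c3@dataset, "entity")
    expect_equal(c3@modelSpec, "concept")
    expect_equal(conditionSpec(4)@dataset, "concept")
    expect_error(conditionSpec(5), "1, 2, 3 or 4")
})

test_that("runCondition is reproducible and resumable", {
    corpus <- tinyCorpus(seed = 44, nClasses = 2, perClass = 20)
    cfg <- tinyTraining(runs = 2L, epochs = 2L, stepsPerEpoch = 8L,
                        maxPretrainEpochs = 3L, seed = 6)
    spec <- new("ConditionSpec", conditionId = 1L, dataset = "entity",
                modelSpec = "entity",
                variants = c("baseline", "expanded_base"))
    r1 <- runCondition(spec, corpus, cfg)
    expect_s4_class(r1, "ConditionResult")
    expect_equal(nrow(r1@summary), 4L)  # 2 runs x 2 variants
    expect_true(all(r1@summary$epoch_of_min <= 2L))
    ## identical master seed reproduces the result exactly
    r2 <- runCondition(spec, corpus, cfg)
    expect_equal(r1@summary, r2@summary)
    ## resuming from persisted runs reloads rather than recomputes
    dir <- tempfile("cond")
    r3 <- runCondition(spec, corpus, cfg, outDir = dir)
    expect_true(file.exists(file.path(dir, "condition1_run01.done")))
    r4 <- runCondition(spec, corpus, cfg, outDir = dir)
    expect_equal(r3@summary$min_val_loss, r4@summary$min_val_loss)
    unlink(dir, recursive = TRUE)
})
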