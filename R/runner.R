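#' Training configuration
#'
#' Defaults reproduce the full published protocol: Adam at learning rate
#' 0.0005, batches of 128 drawn uniformly between modalities, 500 epochs of
#' 1000 steps, 30 independent runs, probes reset each epoch, baseline
#' pretraining frozen once a probe exceeds 99% validation accuracy.
#'
#' @slot learningRate Adam learning rate.
#' @slot batchSize examples per step.
#' @slot epochs epochs per training run.
#' @slot stepsPerEpoch optimizer steps per epoch.
#' @slot runs independent repetitions per variant.
#' @slot freezeThreshold probe validation accuracy needed to freeze.
#' @slot maxPretrainEpochs bound on pretraining before declaring the
#'   criterion unmet (the published protocol usually needs one epoch).
#' @slot seed master seed; every run derives its own streams from it.
#' @export
setClass("TrainingConfig", slots = c(
    learningRate = "numeric", batchSize = "integer", epochs = "integer",
    stepsPerEpoch = "integer", runs = "integer", freezeThreshold = "numeric",
    maxPretrainEpochs = "integer", seed = "integer"))

setValidity("TrainingConfig", function(object) {
    vals <- c(object@learningRate, object@batchSize, object@epochs,
              object@runs, object@freezeThreshold,
              object@maxPretrainEpochs)
    if (any(vals <= 0)) return("all training parameters must be positive")
    if (object@stepsPerEpoch < 0) return("stepsPerEpoch must be >= 0")
    if (object@freezeThreshold >= 1)
        return("freezeThreshold must be below 1")
    TRUE
})

#' @param learningRate,batchSize,epochs,stepsPerEpoch,runs,freezeThreshold,maxPretrainEpochs,seed
#'   see the corresponding slots.
#' @return A [TrainingConfig-class].
#' @rdname TrainingConfig-class
#' @export
trainingConfig <- function(learningRate = 5e-4, batchSize = 128L,
                           epochs = 500L, stepsPerEpoch = 1000L,
                           runs = 30L, freezeThreshold = 0.99,
                           maxPretrainEpochs = 10L, seed = 1L) {
    new("TrainingConfig", learningRate = learningRate,
        batchSize = as.integer(batchSize), epochs = as.integer(epochs),
        stepsPerEpoch = as.integer(stepsPerEpoch), runs = as.integer(runs),
        freezeThreshold = freezeThreshold,
        maxPretrainEpochs = as.integer(maxPretrainEpochs),
        seed = as.integer(seed))
}

#' Desk-scale training configuration
#'
#' Reduced protocol (5 runs of 20 epochs x 100 steps) for running the whole
#' experiment pipeline on one CPU in minutes; all structural properties of
#' the full protocol are preserved.
#'
#' @param seed master seed.
#' @param ... overrides passed to [trainingConfig()].
#' @return A [TrainingConfig-class].
#' @export
deskTrainingConfig <- function(seed = 1L, ...) {
    args <- list(epochs = 20L, stepsPerEpoch = 100L, runs = 5L, seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(trainingConfig, args)
}

setMethod("show", "TrainingConfig", function(object) {
    cat(sprintf(paste0("TrainingConfig: %d runs x %d epochs x %d steps, ",
                       "batch %d, Adam lr %g\n"),
                object@runs, object@epochs, object@stepsPerEpoch,
                object@batchSize, object@learningRate))
    cat(sprintf("  freeze threshold %g (max %d pretrain epochs), seed %d\n",
                object@freezeThreshold, object@maxPretrainEpochs,
                object@seed))
})

#' Experimental condition description
#'
#' The four dataset/model combinations of the study design: 1 = entity data
#' with entity models (all four variants), 2 = concept data with concept
#' models, 3 = entity data with concept models, 4 = concept data with
#' entity models (baseline and experimental only for 2-4).
#'
#' @slot conditionId integer 1-4.
#' @slot dataset `"entity"` or `"concept"` (which corpus assembly to use).
#' @slot modelSpec `"entity"` or `"concept"` (which architecture to build).
#' @slot variants character vector of variant roles to train.
#' @export
setClass("ConditionSpec", slots = c(conditionId = "integer",
                                    dataset = "character",
                                    modelSpec = "character",
                                    variants = "character"))

#' @param conditionId integer 1-4.
#' @return A [ConditionSpec-class] matching the study's condition table.
#' @rdname ConditionSpec-class
#' @export
conditionSpec <- function(conditionId) {
    conditionId <- as.integer(conditionId)
    switch(conditionId,
        new("ConditionSpec", conditionId = 1L, dataset = "entity",
            modelSpec = "entity", variants = modelVariants),
        new("ConditionSpec", conditionId = 2L, dataset = "concept",
            modelSpec = "concept",
            variants = c("baseline", "experimental")),
        new("ConditionSpec", conditionId = 3L, dataset = "entity",
            modelSpec = "concept",
            variants = c("baseline", "experimental")),
        new("ConditionSpec", conditionId = 4L, dataset = "concept",
            modelSpec = "entity",
            variants = c("baseline", "experimental")),
        stop("conditionId must be 1, 2, 3 or 4"))
}

setMethod("show", "ConditionSpec", function(object) {
    cat(sprintf("Condition %d: %s data, %s models [%s]\n",
                object@conditionId, object@dataset, object@modelSpec,
                paste(object@variants, collapse = ", ")))
})

archFor <- function(name) {
    switch(name, entity = entityArchitecture(),
           concept = conceptArchitecture(),
           stop("unknown architecture '", name, "'"))
}

datasetFor <- function(name, cfg) {
    switch(name, entity = assembleEntity(cfg),
           concept = assembleConcept(cfg),
           stop("unknown dataset task '", name, "'"))
}

## Pre-extract plain arrays from a BimodalDataset once per run; the
## training loop only touches these.
datasetArrays <- function(ds) {
    tr <- ds$partition == "train"
    px <- pixelMatrix(ds)
    list(trainPixels = px[, tr, drop = FALSE],
         trainLabel = ds$label[tr],
         trainModality = ds$modality[tr],
         poolImg = which(ds$modality[tr] == -1L),
         poolSnd = which(ds$modality[tr] == 1L),
         valPixels = px[, !tr, drop = FALSE],
         valLabel = ds$label[!tr],
         valModality = ds$modality[!tr])
}

## bitFun(pixels) -> per-example bits, or NULL for no-bit variants
trainEpochArrays <- function(model, da, cfg, probes = NULL, bitFun = NULL) {
    model@state$lr <- cfg@learningRate
    lossSum <- 0; accSum <- 0
    steps <- cfg@stepsPerEpoch
    if (steps > 0) for (s in seq_len(steps)) {
        idx <- sampleBatchIdx(da$poolImg, da$poolSnd, cfg@batchSize)
        x <- da$trainPixels[, idx, drop = FALSE]
        bits <- if (is.null(bitFun)) NULL else bitFun(x)
        out <- trainStepInternal(model, x, da$trainLabel[idx], bits)
        if (!is.null(probes)) {
            m <- da$trainModality[idx]
            probes[[1]] <- probeUpdate(probes[[1]], binarize(out$tap1), m)
            probes[[2]] <- probeUpdate(probes[[2]], binarize(out$tap2), m)
        }
        lossSum <- lossSum + out$loss
        accSum <- accSum + out$accuracy
    }
    valBits <- if (is.null(bitFun)) NULL else bitFun(da$valPixels)
    val <- evaluateModel(model, da$valPixels, da$valLabel, valBits)
    rec <- data.frame(
        train_loss = if (steps > 0) lossSum / steps else NA_real_,
        train_acc = if (steps > 0) accSum / steps else NA_real_,
        val_loss = val$loss, val_acc = val$accuracy,
        probe1_acc = NA_real_, probe2_acc = NA_real_)
    if (!is.null(probes)) {
        taps <- forwardTaps(model, da$valPixels)
        rec$probe1_acc <- probeAccuracy(probes[[1]], taps$tap1,
                                        da$valModality)
        rec$probe2_acc <- probeAccuracy(probes[[2]], taps$tap2,
                                        da$valModality)
    }
    list(record = rec, probes = probes)
}

#' Train one epoch
#'
#' Runs `cfg@stepsPerEpoch` optimizer steps on modality-balanced batches,
#' optionally updating a pair of Hebbian probes from the binarized dense
#' taps of every batch (probe updates never modify the host network), then
#' evaluates on the validation partition. With probes attached, their
#' validation accuracy at epoch end is recorded too; callers are expected
#' to reset probes at epoch start.
#'
#' @param model a [ConvNet-class].
#' @param dataset a [BimodalDataset-class].
#' @param cfg a [TrainingConfig-class].
#' @param probes optional list of two [HebbianProbe-class] objects matching
#'   the model's [tapWidths()].
#' @param bitFun optional function(pixel batch) returning per-example bits
#'   for bit-input variants.
#' @return A list with `record` (one-row data.frame: train_loss, train_acc,
#'   val_loss, val_acc, probe1_acc, probe2_acc) and `probes` (updated).
#' @export
trainEpoch <- function(model, dataset, cfg, probes = NULL, bitFun = NULL) {
    if (nLabels(dataset) != model@nOutputs)
        stop("dataset has ", nLabels(dataset),
             " labels but model expects ", model@nOutputs)
    trainEpochArrays(model, datasetArrays(dataset), cfg, probes, bitFun)
}

criterionNotMet <- function(accs) {
    structure(class = c("modalprobe_criterion_not_met", "error",
                        "condition"),
              list(message = sprintf(
                  paste0("no probe exceeded the freeze threshold; best ",
                         "validation accuracies: layer1 %.4f, layer2 %.4f"),
                  accs[1], accs[2]),
                  call = NULL, bestAccuracies = accs))
}

#' Pretrain a baseline and freeze it with its best probe
#'
#' Trains the baseline with both probes attached (probes reset at the start
#' of every epoch) until at least one probe's validation accuracy exceeds
#' `cfg@freezeThreshold`, then freezes the model weights together with the
#' more accurate of the two probes (ties go to layer 1). Raises a
#' `modalprobe_criterion_not_met` condition — carrying both probes' best
#' accuracies — if the bound `cfg@maxPretrainEpochs` is hit first, so the
#' caller can fall back to a donor model (as condition 4 requires).
#'
#' @param model a baseline-variant [ConvNet-class].
#' @param dataset a [BimodalDataset-class].
#' @param cfg a [TrainingConfig-class].
#' @return list with `model` (frozen), `probe` (frozen winner), `layer`
#'   (1 or 2), `epochsUsed`, `accuracy` (the winning probe's validation
#'   accuracy) and `history` (per-epoch records).
#' @export
pretrainAndFreeze <- function(model, dataset, cfg) {
    if (model@variant != "baseline")
        stop("probes pretrain on the baseline variant")
    da <- datasetArrays(dataset)
    tw <- tapWidths(model)
    probes <- list(hebbianProbe(tw[1]), hebbianProbe(tw[2]))
    history <- NULL
    best <- c(0, 0)
    for (ep in seq_len(cfg@maxPretrainEpochs)) {
        probes <- lapply(probes, probeReset)
        out <- trainEpochArrays(model, da, cfg, probes = probes)
        probes <- out$probes
        history <- rbind(history, out$record)
        accs <- c(out$record$probe1_acc, out$record$probe2_acc)
        best <- pmax(best, accs)
        if (max(accs) > cfg@freezeThreshold) {
            layer <- if (accs[1] >= accs[2]) 1L else 2L
            return(list(model = freezeModel(model),
                        probe = probes[[layer]], layer = layer,
                        epochsUsed = ep, accuracy = accs[layer],
                        history = history))
        }
    }
    stop(criterionNotMet(best))
}

## Build the bit function for a variant, given a frozen donor pair.
variantBitFun <- function(variant, frozenPair) {
    if (variant == "experimental") {
        if (is.null(frozenPair)) stop("experimental variant needs a ",
                                      "frozen baseline + probe pair")
        if (!isFrozen(frozenPair$model)) stop("unfrozen donor model")
        donor <- frozenPair$model
        probe <- frozenPair$probe
        layer <- frozenPair$layer
        function(x) {
            taps <- forwardTaps(donor, x)
            probePredict(probe, binarize(if (layer == 1L) taps$tap1
                                         else taps$tap2))
        }
    } else if (variant == "constant_input") {
        function(x) rep(1, ncol(x))
    } else NULL
}

#' Train a variant for a full run
#'
#' Trains `model` for `cfg@epochs` epochs. For the `experimental` variant
#' each batch is first passed through the frozen baseline; the frozen
#' probe's +1/-1 prediction is the bit concatenated onto the experimental
#' model's flattened convolutional features. `constant_input` receives the
#' constant 1; `baseline` and `expanded_base` receive nothing. Frozen
#' components are never modified.
#'
#' @param model the variant [ConvNet-class] to train (not frozen).
#' @param dataset a [BimodalDataset-class].
#' @param cfg a [TrainingConfig-class].
#' @param frozenPair result of [pretrainAndFreeze()] (required for
#'   `experimental`).
#' @return A run record: data.frame with one row per epoch (epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
trainVariant <- function(model, dataset, cfg, frozenPair = NULL) {
    da <- datasetArrays(dataset)
    bitFun <- variantBitFun(model@variant, frozenPair)
    recs <- vector("list", cfg@epochs)
    for (ep in seq_len(cfg@epochs)) {
        out <- trainEpochArrays(model, da, cfg, bitFun = bitFun)
        recs[[ep]] <- out$record
    }
    rec <- do.call(rbind, recs)
    rec$epoch <- seq_len(cfg@epochs)
    rec[, c("epoch", "train_loss", "train_acc", "val_loss", "val_acc")]
}

#' Per-run summary of a validation-loss sequence
#'
#' @param valLoss numeric vector of per-epoch validation losses.
#' @return list with `minValLoss` and `epochOfMin` (1-based, first
#'   occurrence on ties).
#' @export
runSummary <- function(valLoss) {
    list(minValLoss = min(valLoss), epochOfMin = which.min(valLoss))
}

#' Result of one experimental condition
#'
#' @slot conditionId integer 1-4.
#' @slot summary data.frame with one row per (run, variant): min_val_loss
#'   and epoch_of_min.
#' @slot records named list of per-epoch run records.
#' @slot seeds integer per-run seeds derived from the master seed.
#' @export
setClass("ConditionResult", slots = c(conditionId = "integer",
                                      summary = "data.frame",
                                      records = "list",
                                      seeds = "integer"))

setMethod("show", "ConditionResult", function(object) {
    cat(sprintf("ConditionResult (condition %d): %d runs x %d variants\n",
                object@conditionId,
                length(unique(object@summary$run)),
                length(unique(object@summary$variant))))
    agg <- aggregate(cbind(min_val_loss, epoch_of_min) ~ variant,
                     object@summary, mean)
    names(agg) <- c("variant", "mean_min_val_loss", "mean_epoch_of_min")
    print(agg, row.names = FALSE)
})

#' Run one full experimental condition
#'
#' Generates the condition's dataset, then executes `cfg@runs` independent
#' repetitions: each run pretrains and freezes a baseline + probe pair
#' (falling back to a donor pair pretrained on the concept task with the
#' concept architecture if the freeze criterion is never met, as happens
#' for condition 4), then trains every requested variant from a fresh
#' seeded initialization, recording per-epoch metrics and the per-run
#' (minimum validation loss, epoch of minimum) summary.
#'
#' When `outDir` is given, per-run records are written as CSV as they
#' complete together with a `.done` marker, and already-completed runs are
#' picked up instead of recomputed, so an interrupted condition resumes.
#'
#' @param spec a [ConditionSpec-class] (or integer 1-4).
#' @param corpusCfg a [CorpusConfig-class] for dataset generation.
#' @param cfg a [TrainingConfig-class].
#' @param outDir optional directory for per-run CSV records, summary CSV
#'   and a JSON manifest of seeds.
#' @param verbose print per-run progress.
#' @return A [ConditionResult-class].
#' @export
runCondition <- function(spec, corpusCfg, cfg, outDir = NULL,
                         verbose = FALSE) {
    if (is.numeric(spec)) spec <- conditionSpec(spec)
    set.seed(cfg@seed)
    runSeeds <- sample.int(.Machine$integer.max, cfg@runs)
    dataset <- datasetFor(spec@dataset, corpusCfg)
    arch <- archFor(spec@modelSpec)
    nOut <- nLabels(dataset)
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    summary <- NULL
    records <- list()
    for (r in seq_len(cfg@runs)) {
        markName <- sprintf("condition%d_run%02d", spec@conditionId, r)
        if (!is.null(outDir) &&
            file.exists(file.path(outDir, paste0(markName, ".done")))) {
            done <- read.csv(file.path(outDir, paste0(markName, ".csv")))
            for (v in unique(done$variant)) {
                rv <- done[done$variant == v, ]
                records[[paste0(markName, "_", v)]] <- rv
                s <- runSummary(rv$val_loss)
                summary <- rbind(summary, data.frame(
                    run = r, variant = v, min_val_loss = s$minValLoss,
                    epoch_of_min = s$epochOfMin))
            }
            next
        }
        set.seed(runSeeds[r])
        needsBit <- any(spec@variants %in%
                        c("experimental", "constant_input"))
        frozenPair <- NULL
        if (needsBit) {
            base <- buildModel(arch, "baseline", nOut,
                               seed = runSeeds[r] %% 1000003L)
            frozenPair <- tryCatch(
                pretrainAndFreeze(base, dataset, cfg),
                modalprobe_criterion_not_met = function(e) {
                    ## donor fallback: a concept-task pair provides the bits
                    donorData <- assembleConcept(corpusCfg)
                    donor <- buildModel(conceptArchitecture(), "baseline",
                                        nLabels(donorData),
                                        seed = runSeeds[r] %% 1000033L)
                    pretrainAndFreeze(donor, donorData, cfg)
                })
        }
        runRows <- NULL
        for (v in spec@variants) {
            model <- buildModel(arch, v, nOut,
                                seed = (runSeeds[r] + match(v, modelVariants))
                                       %% 1000003L)
            rec <- trainVariant(model, dataset, cfg,
                                frozenPair = frozenPair)
            records[[paste0(markName, "_", v)]] <- rec
            s <- runSummary(rec$val_loss)
            summary <- rbind(summary, data.frame(
                run = r, variant = v, min_val_loss = s$minValLoss,
                epoch_of_min = s$epochOfMin))
            rec$variant <- v
            rec$run <- r
            runRows <- rbind(runRows, rec)
            if (verbose)
                message(sprintf("run %d %s: min val loss %.4f @ epoch %d",
                                r, v, s$minValLoss, s$epochOfMin))
        }
        if (!is.null(outDir)) {
            write.csv(runRows, file.path(outDir, paste0(markName, ".csv")),
                      row.names = FALSE)
            file.create(file.path(outDir, paste0(markName, ".done")))
        }
    }
    res <- new("ConditionResult", conditionId = spec@conditionId,
               summary = summary, records = records,
               seeds = as.integer(runSeeds %% .Machine$integer.max))
    if (!is.null(outDir)) {
        write.csv(summary,
                  file.path(outDir,
                            sprintf("condition%d_summary.csv",
                                    spec@conditionId)),
                  row.names = FALSE)
        jsonlite::write_json(
            list(conditionId = spec@conditionId, seeds = runSeeds,
                 masterSeed = cfg@seed),
            file.path(outDir, sprintf("condition%d_manifest.json",
                                      spec@conditionId)),
            auto_unbox = TRUE)
    }
    res
}

#' @importFrom stats aggregate
NULL
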