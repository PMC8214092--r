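#' Bimodal dataset container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' flattened-pixel assay (784 rows, one column per example) with per-sample
#' metadata: `modality` (+1 = sound, -1 = image), `classId` (0-based index
#' within the modality), `label` (0-based task label) and `partition`
#' (`"train"` or `"validation"`).
#'
#' Under the entity task the two modalities get disjoint label blocks
#' (images `0..nImage-1`, sounds `nImage..nImage+nSound-1`); under the
#' concept task each sound class shares the label of its paired image class
#' and `pairMap` records the bijection.
#'
#' @slot task `"entity"` or `"concept"`.
#' @slot nLabels integer number of classification labels.
#' @slot pairMap data.frame with columns `soundClass`, `imageClass`
#'   (zero rows for entity tasks).
#' @export
setClass("BimodalDataset",
         contains = "SummarizedExperiment",
         slots = c(task = "character", nLabels = "integer",
                   pairMap = "data.frame"))

setValidity("BimodalDataset", function(object) {
    msg <- character()
    if (!object@task %in% c("entity", "concept"))
        msg <- c(msg, "task must be 'entity' or 'concept'")
    if (!"pixels" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'pixels' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("modality", "classId", "label", "partition")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain:",
                            paste(need, collapse = ", ")))
    else {
        if (!all(cd$modality %in% c(-1L, 1L)))
            msg <- c(msg, "modality must be +1 (sound) or -1 (image)")
        if (!all(cd$partition %in% c("train", "validation")))
            msg <- c(msg, "partition must be 'train' or 'validation'")
        if (any(cd$label < 0L) || any(cd$label >= object@nLabels))
            msg <- c(msg, "labels must lie in [0, nLabels)")
    }
    px <- SummarizedExperiment::assay(object, "pixels")
    if (nrow(px) != 784L) msg <- c(msg, "pixels assay must have 784 rows")
    if (length(px) && (min(px) < 0 || max(px) > 1))
        msg <- c(msg, "pixel values must lie in [0, 1]")
    if (object@task == "concept" && nrow(object@pairMap) > 0) {
        if (anyDuplicated(object@pairMap$soundClass) ||
            anyDuplicated(object@pairMap$imageClass))
            msg <- c(msg, "pairMap must be a bijection")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname nLabels
#' @export
setMethod("nLabels", "BimodalDataset", function(x) x@nLabels)

#' @rdname taskType
#' @export
setMethod("taskType", "BimodalDataset", function(x) x@task)

#' @rdname pairMap
#' @export
setMethod("pairMap", "BimodalDataset", function(x) x@pairMap)

#' @export
setMethod("show", "BimodalDataset", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("BimodalDataset (%s task): %d samples, %d labels\n",
                object@task, ncol(object), object@nLabels))
    cat(sprintf("  image: %d, sound: %d; train: %d, validation: %d\n",
                sum(cd$modality == -1L), sum(cd$modality == 1L),
                sum(cd$partition == "train"),
                sum(cd$partition == "validation")))
})

#' Training / validation partitions
#'
#' @param ds a [BimodalDataset-class].
#' @return The subset of `ds` in the requested partition (still a
#'   `BimodalDataset`).
#' @export
trainingSet <- function(ds) ds[, ds$partition == "train"]

#' @rdname trainingSet
#' @export
validationSet <- function(ds) ds[, ds$partition == "validation"]

#' Pixel matrix of a dataset
#'
#' @param ds a [BimodalDataset-class].
#' @return The 784-by-n pixel assay matrix.
#' @export
pixelMatrix <- function(ds) SummarizedExperiment::assay(ds, "pixels")

#' Stratified validation split
#'
#' Assigns `round(fraction * n)` examples of each class (so within one of
#' the exact overall count per class) to the validation partition,
#' uniformly at random from the current RNG stream. Partitions are disjoint
#' and cover the input.
#'
#' @param classIds vector of class identifiers, one per example.
#' @param fraction validation fraction, strictly between 0 and 1.
#' @return Logical vector, `TRUE` where the example is validation.
#' @examples
#' set.seed(1)
#' table(splitValidation(rep(0:4, each = 200), 0.2))
#' @export
splitValidation <- function(classIds, fraction = 0.2) {
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must lie strictly between 0 and 1")
    isVal <- logical(length(classIds))
    for (cl in unique(classIds)) {
        idx <- which(classIds == cl)
        nVal <- round(fraction * length(idx))
        if (nVal > 0) isVal[sample(idx, nVal)] <- TRUE
    }
    isVal
}

## Generate one modality's raw (unnormalized) sample matrix.
## Returns list(pixels = 784 x n matrix, classId = integer vector).
generateModality <- function(cfg, modality) {
    nClasses <- if (modality == 1L) cfg@nSoundClasses else cfg@nImageClasses
    n <- nClasses * cfg@samplesPerClass
    px <- matrix(0, 784L, n)
    classId <- integer(n)
    i <- 0L
    for (cl in seq_len(nClasses) - 1L) {
        for (s in seq_len(cfg@samplesPerClass)) {
            i <- i + 1L
            classId[i] <- cl
            px[, i] <- if (modality == 1L)
                as.vector(soundToImage(synthWaveform(cl, cfg), cfg))
            else as.vector(synthImage(cl, cfg))
        }
    }
    list(pixels = px, classId = classId)
}

assembleModality <- function(cfg, modality) {
    raw <- generateModality(cfg, modality)
    isVal <- splitValidation(raw$classId, cfg@valFraction)
    ## min-max statistics from the training portion only; the same affine
    ## map is reused (with clipping) for validation data
    trainNorm <- normalizeSamples(raw$pixels[, !isVal, drop = FALSE])
    valNorm <- normalizeSamples(raw$pixels[, isVal, drop = FALSE],
                                stats = trainNorm$stats)
    px <- matrix(0, 784L, ncol(raw$pixels))
    px[, !isVal] <- trainNorm$samples
    px[, isVal] <- valNorm$samples
    list(pixels = px, classId = raw$classId,
         partition = ifelse(isVal, "validation", "train"))
}

makeBimodal <- function(cfg, task) {
    if (task == "concept" && cfg@nImageClasses != cfg@nSoundClasses)
        stop("concept task requires equal image and sound class counts")
    set.seed(cfg@seed)
    img <- assembleModality(cfg, -1L)
    snd <- assembleModality(cfg, 1L)
    if (task == "entity") {
        labels <- c(img$classId, cfg@nImageClasses + snd$classId)
        nLab <- cfg@nImageClasses + cfg@nSoundClasses
        pm <- data.frame(soundClass = integer(), imageClass = integer())
    } else {
        ## sorted class lists paired by index: sound k <-> image k
        labels <- c(img$classId, snd$classId)
        nLab <- cfg@nImageClasses
        pm <- data.frame(soundClass = seq_len(cfg@nSoundClasses) - 1L,
                         imageClass = seq_len(cfg@nImageClasses) - 1L)
    }
    px <- cbind(img$pixels, snd$pixels)
    n <- ncol(px)
    rownames(px) <- sprintf("px%03d", seq_len(784L))
    colnames(px) <- sprintf("s%05d", seq_len(n))
    cd <- S4Vectors::DataFrame(
        modality = c(rep(-1L, ncol(img$pixels)), rep(1L, ncol(snd$pixels))),
        classId = c(img$classId, snd$classId),
        label = as.integer(labels),
        partition = c(img$partition, snd$partition),
        row.names = colnames(px))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(pixels = px), colData = cd)
    new("BimodalDataset", se, task = task, nLabels = as.integer(nLab),
        pairMap = pm)
}

#' Assemble the synthetic entity dataset
#'
#' Generates both modalities from `cfg@seed`, runs the sound branch through
#' the Mel-spectrogram pipeline, min-max normalizes each modality on its
#' training portion, applies a stratified validation split, and labels the
#' result as one task: under `assembleEntity` every class of either
#' modality is its own label (e.g. 30 image + 30 sound classes = 60
#' labels); under `assembleConcept` each sound class shares the label of
#' its index-paired image class (30 labels).
#'
#' @param cfg a [CorpusConfig-class].
#' @return A [BimodalDataset-class].
#' @examples
#' ds <- assembleEntity(corpusConfig(nImageClasses = 2, nSoundClasses = 2,
#'                                   samplesPerClass = 10, seed = 7))
#' nLabels(ds)  # 4
#' @export
assembleEntity <- function(cfg) makeBimodal(cfg, "entity")

#' @rdname assembleEntity
#' @export
assembleConcept <- function(cfg) makeBimodal(cfg, "concept")

#' Sample a modality-balanced training batch
#'
#' Each element is drawn by a fair coin on modality and then uniformly
#' within that modality's training pool, matching a training protocol that
#' samples uniformly between image and sound examples.
#'
#' @param ds a [BimodalDataset-class] with both modalities present in its
#'   training partition.
#' @param batchSize number of examples (default 128).
#' @return A list with `pixels` (784 x batchSize), `label` (0-based task
#'   labels) and `modality` (+1/-1).
#' @export
sampleBatch <- function(ds, batchSize = 128L) {
    tr <- ds$partition == "train"
    poolImg <- which(tr & ds$modality == -1L)
    poolSnd <- which(tr & ds$modality == 1L)
    if (!length(poolImg) || !length(poolSnd))
        stop("both modalities must be present in the training partition")
    idx <- sampleBatchIdx(poolImg, poolSnd, batchSize)
    list(pixels = pixelMatrix(ds)[, idx, drop = FALSE],
         label = ds$label[idx], modality = ds$modality[idx])
}

## index-level batch sampler shared with the fast training loop
sampleBatchIdx <- function(poolImg, poolSnd, batchSize) {
    coin <- runif(batchSize) < 0.5
    idx <- integer(batchSize)
    nSnd <- sum(coin)
    if (nSnd > 0) idx[coin] <- poolSnd[sample.int(length(poolSnd), nSnd,
                                                  replace = TRUE)]
    if (nSnd < batchSize)
        idx[!coin] <- poolImg[sample.int(length(poolImg), batchSize - nSnd,
                                         replace = TRUE)]
    idx
}
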