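#' @import methods
#' @importFrom stats fft mvfft rnorm runif sd quantile setNames
#' @importFrom utils head read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib modalprobe, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Number of task labels in a bimodal dataset
#'
#' @param x a [BimodalDataset-class] object.
#' @return Integer count of classification labels (60 for the default entity
#'   task, 30 for the default concept task).
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' Task type of a bimodal dataset
#'
#' @param x a [BimodalDataset-class] object.
#' @return `"entity"` or `"concept"`.
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' Sound-to-image class pairing of a concept dataset
#'
#' @param x a [BimodalDataset-class] object.
#' @return A data.frame with columns `soundClass` and `imageClass` (empty for
#'   entity tasks), a bijection between the two class lists.
#' @export
setGeneric("pairMap", function(x) standardGeneric("pairMap"))

#' Count trainable parameters of a model
#'
#' @param model a [ConvNet-class] object.
#' @return Integer total of trainable scalar parameters; 0 for a frozen model.
#' @export
setGeneric("countParams", function(model) standardGeneric("countParams"))

#' Is a model frozen?
#'
#' @param model a [ConvNet-class] object.
#' @return Logical scalar.
#' @export
setGeneric("isFrozen", function(model) standardGeneric("isFrozen"))

#' Hebbian probe weight vector
#'
#' @param probe a [HebbianProbe-class] object.
#' @return Numeric weight vector, one entry per unit of the attached layer.
#' @export
setGeneric("probeWeights", function(probe) standardGeneric("probeWeights"))

#' Reset a Hebbian probe to its zero state
#'
#' Zeroes every weight and the update counter. Probes are reset at the start
#' of each training epoch so that per-epoch accuracy reflects how decodable
#' the current layer representation is, not accumulated history.
#'
#' @param probe a [HebbianProbe-class] object.
#' @return The reset probe (all-zero weights, `updatesSeen = 0`).
#' @export
setGeneric("probeReset", function(probe) standardGeneric("probeReset"))

#' Apply one supervised Hebbian update (or a summed batch of them)
#'
#' @param probe a [HebbianProbe-class] object.
#' @param xbin sign-binarized pre-activations: a vector of +1/-1 values, or a
#'   width-by-batch matrix of them.
#' @param label modality label(s) in `{+1, -1}` (+1 = sound, -1 = image); one
#'   per column of `xbin`.
#' @return The updated probe: `weights + learningRate * sum_i label_i * xbin_i`.
#' @export
setGeneric("probeUpdate",
           function(probe, xbin, label) standardGeneric("probeUpdate"))

#' Predict modality from binarized pre-activations
#'
#' @param probe a [HebbianProbe-class] object.
#' @param xbin +1/-1 vector or width-by-batch matrix.
#' @return +1/-1 per example: the sign of the inner product of the probe
#'   weights with `xbin`; an exact zero inner product yields +1 (but is
#'   scored as incorrect by [probeAccuracy()]).
#' @export
setGeneric("probePredict",
           function(probe, xbin) standardGeneric("probePredict"))

#' Probe classification accuracy on an evaluation set
#'
#' @param probe a [HebbianProbe-class] object.
#' @param preact raw (not yet binarized) pre-activation matrix,
#'   width-by-examples.
#' @param label +1/-1 modality labels, one per column.
#' @return Fraction in `[0, 1]` of examples whose predicted modality matches
#'   `label`. Zero inner products count as errors, so a freshly reset probe
#'   scores exactly 0.
#' @export
setGeneric("probeAccuracy",
           function(probe, preact, label) standardGeneric("probeAccuracy"))
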