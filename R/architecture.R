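#' Convolutional architecture description
#'
#' Three 3x3 convolution stages (each followed by 2x2 max pooling), two
#' dense hidden layers, and a softmax output layer. Filter/node counts and
#' activations are the tunable parts; kernel and pool sizes are fixed.
#'
#' @slot name architecture name (`"entity"` or `"concept"` for the built-in
#'   specs).
#' @slot conv list of 3 `list(filters =, activation =)` entries.
#' @slot dense list of 2 `list(nodes =, activation =)` entries.
#' @export
setClass("ArchitectureSpec",
         slots = c(name = "character", conv = "list", dense = "list"))

validActs <- c("relu", "tanh", "sigmoid")

setValidity("ArchitectureSpec", function(object) {
    msg <- character()
    if (length(object@conv) != 3L)
        msg <- c(msg, "exactly 3 convolution stages required")
    if (length(object@dense) != 2L)
        msg <- c(msg, "exactly 2 dense hidden layers required")
    for (l in c(object@conv, object@dense)) {
        if (!is.list(l) || is.null(l$activation) ||
            !l$activation %in% validActs) {
            msg <- c(msg, "layer activations must be relu/tanh/sigmoid")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Built-in architectures
#'
#' The two tuned architectures of the study. Entity (for the 60-label
#' task): conv filters 32 relu / 64 tanh / 16 sigmoid, dense 512 relu and
#' 288 tanh. Concept (for the 30-label task): conv 16 tanh / 16 relu /
#' 32 relu, dense 320 relu and 448 sigmoid. Both use 3x3 kernels, 2x2
#' pooling and a softmax output.
#'
#' @return An [ArchitectureSpec-class].
#' @examples
#' entityArchitecture()
#' @export
entityArchitecture <- function() {
    new("ArchitectureSpec", name = "entity",
        conv = list(list(filters = 32L, activation = "relu"),
                    list(filters = 64L, activation = "tanh"),
                    list(filters = 16L, activation = "sigmoid")),
        dense = list(list(nodes = 512L, activation = "relu"),
                     list(nodes = 288L, activation = "tanh")))
}

#' @rdname entityArchitecture
#' @export
conceptArchitecture <- function() {
    new("ArchitectureSpec", name = "concept",
        conv = list(list(filters = 16L, activation = "tanh"),
                    list(filters = 16L, activation = "relu"),
                    list(filters = 32L, activation = "relu")),
        dense = list(list(nodes = 320L, activation = "relu"),
                     list(nodes = 448L, activation = "sigmoid")))
}

#' @export
setMethod("show", "ArchitectureSpec", function(object) {
    cat(sprintf("ArchitectureSpec '%s'\n", object@name))
    for (i in 1:3)
        cat(sprintf("  conv%d: %d filters 3x3 %s + maxpool 2x2\n", i,
                    object@conv[[i]]$filters, object@conv[[i]]$activation))
    for (i in 1:2)
        cat(sprintf("  dense%d: %d nodes %s\n", i,
                    object@dense[[i]]$nodes, object@dense[[i]]$activation))
    cat("  output: softmax\n")
})

modelVariants <- c("baseline", "experimental", "expanded_base",
                   "constant_input")

#' Model variant roles
#'
#' The four roles a network can play in the bit-injection experiment:
#' `baseline` (plain classifier, hosts the probes), `experimental` (one
#' extra scalar input at the dense stage carrying the probe's decoded +1/-1
#' modality bit), `expanded_base` (baseline plus one extra node in dense
#' layer 1, matching parameter count inflation without extra information)
#' and `constant_input` (identical in structure to experimental but always
#' fed the constant 1, equalizing its parameter count with experimental).
#'
#' @return Character vector of the valid variant names.
#' @export
modelVariantNames <- function() modelVariants
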