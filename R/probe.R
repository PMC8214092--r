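#' Supervised Hebbian modality probe
#'
#' A linear decoder attached to one dense hidden layer of a host network.
#' It reads the layer's non-activated (pre-activation) outputs, binarizes
#' them to +1/-1 by sign, and learns with the plain supervised Hebb rule
#' `w <- w + eta * label * xbin` to predict whether the host's input was a
#' sound (+1) or an image (-1). Training the probe never touches the host
#' network's weights.
#'
#' @slot weights numeric vector, one weight per unit of the attached layer.
#' @slot updatesSeen integer count of examples the probe has been updated
#'   with since the last reset.
#' @slot learningRate positive scalar `eta` (default 1; the sign-based
#'   prediction rule makes its value irrelevant).
#' @export
setClass("HebbianProbe", slots = c(weights = "numeric",
                                   updatesSeen = "integer",
                                   learningRate = "numeric"))

setValidity("HebbianProbe", function(object) {
    msg <- character()
    if (length(object@weights) < 1L) msg <- c(msg, "probe width must be >= 1")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@updatesSeen < 0L) msg <- c(msg, "updatesSeen must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Create a Hebbian probe
#'
#' @param width width of the dense layer the probe attaches to.
#' @param learningRate Hebbian step size (default 1).
#' @return A zero-initialized [HebbianProbe-class].
#' @examples
#' p <- hebbianProbe(4)
#' p <- probeUpdate(p, c(1, 1, -1, 1), label = -1)
#' probeWeights(p)
#' @export
hebbianProbe <- function(width, learningRate = 1) {
    new("HebbianProbe", weights = numeric(width), updatesSeen = 0L,
        learningRate = learningRate)
}

#' @rdname probeWeights
#' @export
setMethod("probeWeights", "HebbianProbe", function(probe) probe@weights)

#' @export
setMethod("show", "HebbianProbe", function(object) {
    cat(sprintf("HebbianProbe: width %d, %d updates seen, eta = %g\n",
                length(object@weights), object@updatesSeen,
                object@learningRate))
})

#' Sign-binarize pre-activations
#'
#' Divides each value by its absolute value, mapping everything to +1 or
#' -1; an exact zero (where that division is undefined) maps to +1 by
#' convention.
#'
#' @param preact numeric vector or matrix of finite pre-activation values.
#' @return Object of the same shape with every element +1 or -1.
#'   Idempotent: `binarize(binarize(x))` equals `binarize(x)`.
#' @export
binarize <- function(preact) {
    if (!all(is.finite(preact))) stop("non-finite pre-activation values")
    out <- ifelse(preact >= 0, 1, -1)
    if (!is.null(dim(preact))) dim(out) <- dim(preact)
    out
}

checkBin <- function(xbin) {
    if (!all(abs(xbin) == 1))
        stop("xbin must be sign-binarized (+1/-1); call binarize() first")
}

#' @rdname probeUpdate
#' @export
setMethod("probeUpdate", "HebbianProbe", function(probe, xbin, label) {
    checkBin(xbin)
    if (!all(label %in% c(-1, 1))) stop("labels must be +1 or -1")
    if (is.matrix(xbin)) {
        if (length(label) != ncol(xbin))
            stop("one label per column of xbin required")
        if (nrow(xbin) != length(probe@weights))
            stop("xbin width does not match probe width")
        probe@weights <- probe@weights +
            probe@learningRate * as.vector(xbin %*% label)
        probe@updatesSeen <- probe@updatesSeen + ncol(xbin)
    } else {
        if (length(xbin) != length(probe@weights))
            stop("xbin width does not match probe width")
        if (length(label) != 1L) stop("a single example takes a single label")
        probe@weights <- probe@weights + probe@learningRate * label * xbin
        probe@updatesSeen <- probe@updatesSeen + 1L
    }
    probe
})

#' @rdname probePredict
#' @export
setMethod("probePredict", "HebbianProbe", function(probe, xbin) {
    checkBin(xbin)
    if (is.matrix(xbin)) {
        if (nrow(xbin) != length(probe@weights))
            stop("xbin width does not match probe width")
        s <- as.vector(crossprod(xbin, probe@weights))
    } else {
        if (length(xbin) != length(probe@weights))
            stop("xbin width does not match probe width")
        s <- sum(xbin * probe@weights)
    }
    ifelse(s >= 0, 1, -1)
})

#' @rdname probeAccuracy
#' @export
setMethod("probeAccuracy", "HebbianProbe", function(probe, preact, label) {
    xbin <- binarize(preact)
    if (!is.matrix(xbin)) xbin <- matrix(xbin, ncol = 1)
    if (ncol(xbin) < 1L) stop("empty evaluation set")
    if (length(label) != ncol(xbin)) stop("one label per example required")
    s <- as.vector(crossprod(xbin, probe@weights))
    pred <- ifelse(s >= 0, 1, -1)
    mean(s != 0 & pred == label)
})

#' @rdname probeReset
#' @export
setMethod("probeReset", "HebbianProbe", function(probe) {
    probe@weights <- numeric(length(probe@weights))
    probe@updatesSeen <- 0L
    probe
})
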