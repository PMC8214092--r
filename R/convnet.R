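## The network implementation: Glorot-initialized conv/pool/dense stack with
## taps on the dense pre-activations, softmax + cross-entropy training with
## Adam, and an optional scalar bit input appended to the flattened
## convolutional features. Convolution and pooling kernels live in compiled
## code (im2col + GEMM); dense algebra is plain matrix arithmetic.

actKind <- function(act) {
    k <- match(act, c("relu", "tanh", "sigmoid"))
    if (is.na(k)) stop("unknown activation ", act)
    k
}

actFun <- function(z, act) .act_forward(z, actKind(act))

## gradient wrt pre-activation: da * act'(z), given both z and a = act(z)
actBackward <- function(da, z, a, act) .act_backward(da, z, a, actKind(act))

softmaxCols <- function(z) {
    z <- sweep(z, 2, apply(z, 2, max))
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
}

glorot <- function(dims, fanIn, fanOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    array(runif(prod(dims), -lim, lim), dims)
}

#' Convolutional network handle
#'
#' Mutable model state (weights and optimizer moments live in an
#' environment slot so training updates in place). Build with
#' [buildModel()]; run with [forwardTaps()]; train with [trainStep()].
#'
#' @slot arch the [ArchitectureSpec-class] the model was built from.
#' @slot variant one of [modelVariantNames()].
#' @slot nOutputs number of softmax outputs.
#' @slot state environment holding `params`, Adam state and the frozen flag.
#' @export
setClass("ConvNet",
         slots = c(arch = "ArchitectureSpec", variant = "character",
                   nOutputs = "integer", state = "environment"))

#' Build a model variant
#'
#' Constructs the conv/dense stack described by `arch` for a 28x28
#' single-channel input. Convolutions are valid (unpadded) 3x3, each
#' followed by 2x2 max pooling, so the spatial map shrinks
#' 28 - 26 - 13 - 11 - 5 - 3 - 1 and the flattened feature width equals the
#' third stage's filter count. For the `experimental` and `constant_input`
#' variants the flattened features gain one extra scalar input (the
#' modality bit); for `expanded_base` dense layer 1 gains one extra node.
#' Weights are Glorot-uniform, drawn from a private RNG stream seeded by
#' `seed`, so identical calls build identical models.
#'
#' @param arch an [ArchitectureSpec-class].
#' @param variant one of [modelVariantNames()].
#' @param nOutputs number of output classes.
#' @param seed integer seed for weight initialization.
#' @return A [ConvNet-class] handle.
#' @examples
#' m <- buildModel(entityArchitecture(), "baseline", nOutputs = 60, seed = 1)
#' countParams(m)
#' @export
buildModel <- function(arch, variant = "baseline", nOutputs, seed = 1L) {
    if (!variant %in% modelVariants)
        stop("unknown variant '", variant, "'; expected one of ",
             paste(modelVariants, collapse = ", "))
    nOutputs <- as.integer(nOutputs)
    if (nOutputs < 2L) stop("nOutputs must be >= 2")
    hasBit <- variant %in% c("experimental", "constant_input")
    ## spatial bookkeeping for the fixed 28x28x1 input
    dims <- list(c(28L, 28L, 1L))
    for (i in 1:3) {
        h <- dims[[i]][1] - 2L
        dims[[i + 1]] <- c(h %/% 2L, h %/% 2L, arch@conv[[i]]$filters)
        dims[[i]] <- c(dims[[i]], conv = h)  # conv output side before pool
    }
    flatW <- prod(dims[[4]])
    d1in <- flatW + as.integer(hasBit)
    d1n <- arch@dense[[1]]$nodes + as.integer(variant == "expanded_base")
    d2n <- arch@dense[[2]]$nodes

    state <- new.env(parent = emptyenv())
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    cin <- 1L
    params <- list()
    for (i in 1:3) {
        f <- arch@conv[[i]]$filters
        params[[paste0("Wc", i)]] <- glorot(c(3L, 3L, cin, f),
                                            9 * cin, 9 * f)
        params[[paste0("bc", i)]] <- numeric(f)
        cin <- f
    }
    params$W1 <- matrix(glorot(c(d1n, d1in), d1in, d1n), d1n, d1in)
    params$b1 <- numeric(d1n)
    params$W2 <- matrix(glorot(c(d2n, d1n), d1n, d2n), d2n, d1n)
    params$b2 <- numeric(d2n)
    params$Wo <- matrix(glorot(c(nOutputs, d2n), d2n, nOutputs),
                        nOutputs, d2n)
    params$bo <- numeric(nOutputs)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())

    state$params <- params
    state$adamM <- lapply(params, function(p) p * 0)
    state$adamV <- lapply(params, function(p) p * 0)
    state$adamT <- 0L
    state$frozen <- FALSE
    state$flatW <- flatW
    state$hasBit <- hasBit
    state$denseActs <- vapply(arch@dense, `[[`, "", "activation")
    state$convActs <- vapply(arch@conv, `[[`, "", "activation")
    new("ConvNet", arch = arch, variant = variant, nOutputs = nOutputs,
        state = state)
}

#' Dense tap widths of a model
#'
#' @param model a [ConvNet-class].
#' @return Integer vector of length 2: the widths of the two dense hidden
#'   layers whose pre-activations the taps expose.
#' @export
tapWidths <- function(model) {
    c(nrow(model@state$params$W1), nrow(model@state$params$W2))
}

#' @rdname countParams
#' @export
setMethod("countParams", "ConvNet", function(model) {
    if (model@state$frozen) return(0L)
    as.integer(sum(vapply(model@state$params, length, 0L)))
})

#' @rdname isFrozen
#' @export
setMethod("isFrozen", "ConvNet", function(model) model@state$frozen)

#' Freeze a model
#'
#' Marks the model untrainable: [trainStep()] refuses to update it and
#' [countParams()] reports 0 trainable parameters. Forward passes still
#' work, which is exactly what the pretrained baseline + probe pair needs
#' while feeding bits to an experimental model.
#'
#' @param model a [ConvNet-class].
#' @return The model, frozen.
#' @export
freezeModel <- function(model) {
    model@state$frozen <- TRUE
    model
}

#' @export
setMethod("show", "ConvNet", function(object) {
    cat(sprintf("ConvNet: '%s' architecture, variant '%s', %d outputs\n",
                object@arch@name, object@variant, object@nOutputs))
    tw <- tapWidths(object)
    cat(sprintf("  dense taps: %d, %d; trainable parameters: %d%s\n",
                tw[1], tw[2], countParams(object),
                if (object@state$frozen) " (frozen)" else ""))
})

asInputArray <- function(x) {
    if (is.matrix(x)) {
        if (nrow(x) != 784L) stop("input matrix must have 784 rows")
        dim(x) <- c(28L, 28L, 1L, ncol(x))
    } else if (length(dim(x)) != 4L) {
        stop("input must be a 784 x n matrix or 28 x 28 x 1 x n array")
    }
    x
}

checkBits <- function(model, bits, n) {
    st <- model@state
    if (!st$hasBit) {
        if (!is.null(bits))
            stop("variant '", model@variant, "' takes no bit input")
        return(NULL)
    }
    if (is.null(bits))
        stop("variant '", model@variant, "' requires a bit input")
    if (length(bits) == 1L) bits <- rep(bits, n)
    if (length(bits) != n) stop("one bit per example required")
    if (model@variant == "experimental" && !all(bits %in% c(-1, 1)))
        stop("experimental bit values must be +1 or -1")
    if (model@variant == "constant_input" && !all(bits == 1))
        stop("constant_input variant takes the constant bit 1")
    bits
}

forwardInternal <- function(model, x, bits, keepCache = FALSE) {
    st <- model@state
    p <- st$params
    x <- asInputArray(x)
    n <- dim(x)[4]
    bits <- checkBits(model, bits, n)
    cache <- if (keepCache) list(x = x, bits = bits) else NULL
    a <- x
    for (i in 1:3) {
        z <- .conv2d_forward(a, p[[paste0("Wc", i)]], p[[paste0("bc", i)]])
        act <- actFun(z, st$convActs[i])
        pool <- .maxpool2_forward(act)
        if (keepCache) {
            cache[[paste0("cin", i)]] <- a
            cache[[paste0("cz", i)]] <- z
            cache[[paste0("ca", i)]] <- act
            cache[[paste0("cpool", i)]] <- pool
        }
        a <- pool$y
    }
    flat <- matrix(a, st$flatW, n)
    f <- if (st$hasBit) rbind(flat, bits) else flat
    z1 <- p$W1 %*% f + p$b1
    a1 <- actFun(z1, st$denseActs[1])
    z2 <- p$W2 %*% a1 + p$b2
    a2 <- actFun(z2, st$denseActs[2])
    zo <- p$Wo %*% a2 + p$bo
    probs <- softmaxCols(zo)
    if (keepCache) {
        cache$f <- f; cache$z1 <- z1; cache$a1 <- a1
        cache$z2 <- z2; cache$a2 <- a2
    }
    list(probs = probs, tap1 = z1, tap2 = z2, cache = cache)
}

#' Forward pass with dense-layer taps
#'
#' Runs a batch through the network and returns the softmax probabilities
#' together with the non-activated (pre-activation) outputs of both dense
#' hidden layers — the signals the Hebbian probes read.
#'
#' @param model a [ConvNet-class].
#' @param x 784-by-n pixel matrix (or 28x28x1xn array), values in `[0, 1]`.
#' @param bits optional modality bits for the bit-input variants: a scalar
#'   or length-n vector of +1/-1 (`experimental`) or 1 (`constant_input`).
#' @return A list with `probs` (nOutputs x n, columns summing to 1),
#'   `tap1` and `tap2` (dense pre-activation matrices).
#' @export
forwardTaps <- function(model, x, bits = NULL) {
    out <- forwardInternal(model, x, bits, keepCache = FALSE)
    out["cache"] <- NULL
    out
}

#' Forward pass with an injected modality bit
#'
#' Appends one scalar per example to the flattened convolutional features,
#' widening dense layer 1's input by exactly one, and runs the augmented
#' forward pass. Only the `experimental` (bit in +1/-1) and
#' `constant_input` (bit = 1) variants accept an injected bit.
#'
#' @inheritParams forwardTaps
#' @param bits +1/-1 per example (`experimental`) or 1 (`constant_input`).
#' @return As [forwardTaps()].
#' @export
injectBit <- function(model, x, bits) {
    if (!model@state$hasBit)
        stop("variant '", model@variant, "' has no bit injection point")
    forwardTaps(model, x, bits = bits)
}

## Forward + backward on a batch without touching the weights; returns
## loss/accuracy, taps and the gradient list. labels are 0-based integers.
trainStepGradients <- function(model, x, labels, bits = NULL) {
    st <- model@state
    p <- st$params
    fw <- forwardInternal(model, x, bits, keepCache = TRUE)
    cc <- fw$cache
    n <- ncol(fw$probs)
    if (max(labels) >= model@nOutputs || min(labels) < 0)
        stop("labels must lie in [0, nOutputs)")
    ii <- cbind(labels + 1L, seq_len(n))
    loss <- -mean(log(pmax(fw$probs[ii], 1e-12)))
    acc <- mean(max.col(t(fw$probs)) == labels + 1L)

    ## backward
    g <- list()
    dzo <- fw$probs
    dzo[ii] <- dzo[ii] - 1
    dzo <- dzo / n
    g$Wo <- dzo %*% t(cc$a2)
    g$bo <- rowSums(dzo)
    da2 <- crossprod(p$Wo, dzo)
    dz2 <- actBackward(da2, cc$z2, cc$a2, st$denseActs[2])
    g$W2 <- dz2 %*% t(cc$a1)
    g$b2 <- rowSums(dz2)
    da1 <- crossprod(p$W2, dz2)
    dz1 <- actBackward(da1, cc$z1, cc$a1, st$denseActs[1])
    g$W1 <- dz1 %*% t(cc$f)
    g$b1 <- rowSums(dz1)
    df <- crossprod(p$W1, dz1)
    if (st$hasBit) df <- df[-nrow(df), , drop = FALSE]
    dpool <- df
    dim(dpool) <- dim(cc$cpool3$y)
    for (i in 3:1) {
        pool <- cc[[paste0("cpool", i)]]
        da <- .maxpool2_backward(pool$idx, dpool,
                                 dim(cc[[paste0("ca", i)]]))
        dz <- actBackward(da, cc[[paste0("cz", i)]], cc[[paste0("ca", i)]],
                          st$convActs[i])
        bk <- .conv2d_backward(cc[[paste0("cin", i)]],
                               p[[paste0("Wc", i)]], dz)
        g[[paste0("Wc", i)]] <- bk$dw
        g[[paste0("bc", i)]] <- bk$db
        if (i > 1L) dpool <- bk$dx
    }
    list(loss = loss, accuracy = acc, tap1 = fw$tap1, tap2 = fw$tap2,
         grads = g)
}

## One optimizer step on a batch; returns loss/accuracy and the taps.
trainStepInternal <- function(model, x, labels, bits = NULL) {
    st <- model@state
    if (st$frozen) stop("model is frozen and cannot be trained")
    out <- trainStepGradients(model, x, labels, bits)
    g <- out$grads

    ## Adam (beta1 0.9, beta2 0.999, eps 1e-7)
    st$adamT <- st$adamT + 1L
    corr <- sqrt(1 - 0.999^st$adamT) / (1 - 0.9^st$adamT)
    lr <- st$lr * corr
    for (nm in names(g)) {
        st$adamM[[nm]] <- 0.9 * st$adamM[[nm]] + 0.1 * g[[nm]]
        st$adamV[[nm]] <- 0.999 * st$adamV[[nm]] + 0.001 * g[[nm]]^2
        st$params[[nm]] <- st$params[[nm]] -
            lr * st$adamM[[nm]] / (sqrt(st$adamV[[nm]]) + 1e-7)
    }
    out["grads"] <- NULL
    out
}

#' One training step
#'
#' A single Adam update minimizing multiclass cross-entropy on integer
#' labels (sparse categorical cross-entropy) for one batch. Returns the
#' batch loss/accuracy and the dense taps computed before the update, so
#' probes can learn from the very same forward pass.
#'
#' @param model a [ConvNet-class] (must not be frozen).
#' @param x 784-by-n pixel batch.
#' @param labels 0-based integer class labels, one per column.
#' @param bits optional modality bits (see [forwardTaps()]).
#' @param learningRate Adam learning rate (default 0.0005).
#' @return list with `loss`, `accuracy`, `tap1`, `tap2`.
#' @export
trainStep <- function(model, x, labels, bits = NULL, learningRate = 5e-4) {
    model@state$lr <- learningRate
    trainStepInternal(model, x, labels, bits)
}

#' Evaluate a model on labelled data
#'
#' Computes mean cross-entropy loss and accuracy over a set, in chunks so
#' memory stays bounded.
#'
#' @inheritParams trainStep
#' @param chunk examples per forward chunk.
#' @return list with `loss` and `accuracy`.
#' @export
evaluateModel <- function(model, x, labels, bits = NULL, chunk = 512L) {
    n <- ncol(x)
    tot <- 0; hits <- 0
    for (st in seq(1L, n, by = chunk)) {
        en <- min(st + chunk - 1L, n)
        b <- if (is.null(bits)) NULL
             else if (length(bits) == 1L) bits else bits[st:en]
        fw <- forwardInternal(model, x[, st:en, drop = FALSE], b)
        ii <- cbind(labels[st:en] + 1L, seq_len(en - st + 1L))
        tot <- tot + sum(-log(pmax(fw$probs[ii], 1e-12)))
        hits <- hits + sum(max.col(t(fw$probs)) == labels[st:en] + 1L)
    }
    list(loss = tot / n, accuracy = hits / n)
}

## Snapshot of all weights, for immutability assertions in tests.
paramSnapshot <- function(model) model@state$params
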