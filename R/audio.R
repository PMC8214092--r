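## Mel spectrogram pipeline: centered Hann-windowed short-time transform,
## power spectrum, triangular Mel filterbank (HTK scale), then the fixed
## pad-and-pool step down to the 28x28 image format.

hzToMel <- function(f) 2595 * log10(1 + f / 700)
melToHz <- function(m) 700 * (10^(m / 2595) - 1)

.fbCache <- new.env(parent = emptyenv())

## nMels triangular filters over FFT bin frequencies, fmin = 0,
## fmax = rate / 2. Rows = mel bands, cols = nFft/2 + 1 FFT bins.
## Memoized: the filterbank depends only on (nMels, nFft, rate).
melFilterbank <- function(nMels, nFft, rate) {
    key <- paste(nMels, nFft, rate, sep = "_")
    if (!is.null(.fbCache[[key]])) return(.fbCache[[key]])
    .fbCache[[key]] <- melFilterbankBuild(nMels, nFft, rate)
    .fbCache[[key]]
}

melFilterbankBuild <- function(nMels, nFft, rate) {
    nBins <- nFft %/% 2 + 1
    fftFreq <- (seq_len(nBins) - 1) * rate / nFft
    melPts <- melToHz(seq(hzToMel(0), hzToMel(rate / 2),
                          length.out = nMels + 2L))
    fb <- matrix(0, nMels, nBins)
    for (m in seq_len(nMels)) {
        lo <- melPts[m]; ctr <- melPts[m + 1]; hi <- melPts[m + 2]
        up <- (fftFreq - lo) / (ctr - lo)
        down <- (hi - fftFreq) / (hi - ctr)
        fb[m, ] <- pmax(0, pmin(up, down))
    }
    fb
}

#' Mel power spectrogram of a waveform
#'
#' Centered framing: the signal is reflect-padded by `nFft/2` on both sides,
#' cut into Hann-windowed frames every `hop` samples, transformed, and the
#' one-sided power spectrum is projected onto a triangular Mel filterbank.
#' The frame count is `floor(length / hop) + 1`, so a 1-second clip at
#' 22050 samples/s with hop 512 yields exactly 44 frames; with the default
#' 128 Mel bands the result is the 128-by-44 matrix the rest of the
#' pipeline expects.
#'
#' @param w a [Waveform-class] (or numeric vector, taken at
#'   `cfg@sampleRate`); padded/truncated to `cfg@durationS` first.
#' @param cfg a [CorpusConfig-class]; `w@rate` must equal `cfg@sampleRate`.
#' @return A non-negative `cfg@nMels`-by-T power matrix.
#' @examples
#' cfg <- corpusConfig(nImageClasses = 2, nSoundClasses = 2)
#' m <- melSpectrogram(synthWaveform(0, cfg, noise = 0), cfg)
#' dim(m)  # 128 44
#' @export
melSpectrogram <- function(w, cfg = corpusConfig()) {
    if (is.numeric(w)) w <- new("Waveform", samples = w, rate = cfg@sampleRate)
    if (length(w@samples) == 0) stop("empty waveform")
    if (w@rate != cfg@sampleRate)
        stop("waveform rate ", w@rate, " does not match config rate ",
             cfg@sampleRate)
    w <- fixDuration(w, cfg@durationS)
    s <- w@samples
    n <- length(s)
    nFft <- cfg@nFft; hop <- cfg@hop
    half <- nFft %/% 2
    padded <- c(rev(s[2:(half + 1)]), s, rev(s[(n - half):(n - 1)]))
    nFrames <- n %/% hop + 1L
    starts <- (seq_len(nFrames) - 1L) * hop
    frames <- vapply(starts, function(st) padded[(st + 1):(st + nFft)],
                     numeric(nFft))
    win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nFft) - 1) / nFft)  # periodic Hann
    spec <- Mod(mvfft(frames * win))^2
    spec <- spec[seq_len(half + 1), , drop = FALSE]
    melFilterbank(cfg@nMels, nFft, cfg@sampleRate) %*% spec
}

#' Reduce a 128-by-44 spectrogram to the 28-by-28 image format
#'
#' Zero-pads the matrix to 140-by-56 (rows appended below, columns appended
#' right) and applies non-overlapping 5-by-2 max pooling, matching the
#' published conversion of Mel spectrograms to the image datasets'
#' 28-by-28 shape. Pooling never invents values: the output maximum equals
#' the input maximum and every output cell is the max of one input block.
#'
#' @param spec a 128-by-44 numeric matrix (error otherwise).
#' @return A 28-by-28 matrix.
#' @export
poolToImageShape <- function(spec) {
    if (!is.matrix(spec) || !all(dim(spec) == c(128L, 44L)))
        stop("expected a 128 x 44 matrix, got ",
             paste(dim(spec), collapse = " x "))
    padded <- matrix(0, 140, 56)
    padded[1:128, 1:44] <- spec
    blocks <- array(padded, c(5L, 28L, 2L, 28L))
    apply(blocks, c(2L, 4L), max)
}

#' Convert a waveform to a normalized-ready 28-by-28 sample
#'
#' The full sound branch of the preprocessing chain:
#' [melSpectrogram()] then [poolToImageShape()].
#'
#' @inheritParams melSpectrogram
#' @return A 28-by-28 non-negative matrix (not yet min-max normalized).
#' @export
soundToImage <- function(w, cfg = corpusConfig()) {
    poolToImageShape(melSpectrogram(w, cfg))
}

#' Min-max normalize a collection of samples
#'
#' Rescales affinely to `[0, 1]` using the minimum and maximum over the
#' whole collection, or using precomputed statistics (as when the map fit
#' on training data is reused for validation data, avoiding leakage).
#' Values falling outside `[0, 1]` under a reused map are clipped.
#'
#' @param samples a numeric array/matrix, or a list of matrices.
#' @param stats optional `c(min, max)` from a previous call.
#' @return A list with `samples` (same shape as the input) and `stats`.
#'   A constant-valued collection maps to all zeros, with a warning.
#' @export
normalizeSamples <- function(samples, stats = NULL) {
    isList <- is.list(samples)
    x <- if (isList) do.call(cbind, lapply(samples, as.vector))
         else samples
    if (length(x) == 0) stop("empty collection")
    if (is.null(stats)) stats <- c(min(x), max(x))
    lo <- stats[1]; hi <- stats[2]
    if (hi <= lo) {
        warning("constant-valued collection; returning zeros")
        scaled <- x * 0
    } else {
        scaled <- clip01((x - lo) / (hi - lo))
    }
    if (isList) {
        d <- dim(samples[[1]])
        out <- lapply(seq_along(samples),
                      function(i) matrix(scaled[, i], d[1], d[2]))
        names(out) <- names(samples)
    } else {
        out <- scaled
    }
    list(samples = out, stats = stats)
}
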