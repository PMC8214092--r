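#' Waveform container
#'
#' A mono audio clip: an amplitude sequence plus its sampling rate.
#'
#' @slot samples numeric amplitude vector, bounded in `[-1, 1]` for
#'   generated clips.
#' @slot rate sampling rate in samples/s (> 0).
#' @export
setClass("Waveform", slots = c(samples = "numeric", rate = "numeric"))

setValidity("Waveform", function(object) {
    if (object@rate <= 0) return("rate must be positive")
    TRUE
})

#' @export
setMethod("show", "Waveform", function(object) {
    cat(sprintf("Waveform: %d samples @ %g samples/s (%.3f s)\n",
                length(object@samples), object@rate,
                length(object@samples) / object@rate))
})

#' Length of a waveform in samples
#' @param x a [Waveform-class].
#' @export
setMethod("length", "Waveform", function(x) length(x@samples))

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Synthetic image sample
#'
#' Deterministic class templates — an oriented bright bar through the image
#' centre plus a class-indexed gaussian blob on a dark background — with
#' additive gaussian pixel noise drawn from the current RNG stream. The
#' templates stand in for handwritten-character images: sparse bright
#' strokes, mostly-dark ground, and are linearly separable by construction
#' so that downstream decodability is a property of the pipeline, not of
#' lucky data.
#'
#' @param classId 0-based class index, must be `< cfg@nImageClasses`.
#' @param cfg a [CorpusConfig-class].
#' @param noise sd of additive gaussian noise (defaults to
#'   `cfg@imageNoise`); 0 gives the bare template.
#' @return A 28-by-28 matrix with values in `[0, 1]`.
#' @examples
#' img <- synthImage(0, corpusConfig(nImageClasses = 4, nSoundClasses = 4))
#' dim(img)
#' @export
synthImage <- function(classId, cfg = corpusConfig(), noise = cfg@imageNoise) {
    if (classId < 0 || classId >= cfg@nImageClasses)
        stop("classId out of range [0, ", cfg@nImageClasses - 1L, "]")
    n <- 28L
    xy <- seq_len(n) - (n + 1) / 2          # centred coordinates
    gx <- matrix(xy, n, n)                   # row coordinate
    gy <- matrix(xy, n, n, byrow = TRUE)     # column coordinate
    theta <- (classId * 2.399963) %% pi      # golden-angle spacing
    # distance from the line through the centre at angle theta
    d <- abs(gx * cos(theta) + gy * sin(theta))
    bar <- exp(-d^2 / (2 * 1.5^2))
    phi <- classId * 1.7 + 0.4
    cx <- 8 * cos(phi); cy <- 8 * sin(phi)
    blob <- 0.8 * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * 2^2))
    template <- clip01(bar + blob)
    if (noise > 0)
        template <- clip01(template + matrix(rnorm(n * n, sd = noise), n, n))
    template
}

#' Synthetic sound sample
#'
#' Class-indexed harmonic stacks: fundamental `180 * 2^(classId/8)` Hz with
#' three harmonics at fixed decaying amplitudes, plus white noise. The
#' geometric fundamental spacing keeps every class's dominant spectral peak
#' distinct while the third harmonic of the highest default class stays
#' below the Nyquist frequency at 22050 samples/s.
#'
#' @param classId 0-based class index, must be `< cfg@nSoundClasses`.
#' @param cfg a [CorpusConfig-class].
#' @param noise white-noise amplitude (defaults to `cfg@soundNoise`); 0
#'   gives the bare harmonic template.
#' @return A [Waveform-class] of exactly `cfg@durationS * cfg@sampleRate`
#'   samples (22050 by default), amplitudes in `[-1, 1]`.
#' @examples
#' w <- synthWaveform(0, corpusConfig(nImageClasses = 4, nSoundClasses = 4))
#' length(w)
#' @export
synthWaveform <- function(classId, cfg = corpusConfig(),
                          noise = cfg@soundNoise) {
    if (classId < 0 || classId >= cfg@nSoundClasses)
        stop("classId out of range [0, ", cfg@nSoundClasses - 1L, "]")
    nSamp <- round(cfg@durationS * cfg@sampleRate)
    t <- (seq_len(nSamp) - 1) / cfg@sampleRate
    f0 <- 180 * 2^(classId / 8)
    phase <- classId * 0.61
    amp <- c(1, 0.5, 0.25)
    s <- amp[1] * sin(2 * pi * f0 * t + phase) +
         amp[2] * sin(2 * pi * 2 * f0 * t + 2 * phase) +
         amp[3] * sin(2 * pi * 3 * f0 * t)
    s <- s / (sum(amp) + 4 * noise)          # headroom for the noise term
    if (noise > 0) s <- s + noise * rnorm(nSamp) / (sum(amp) + 4 * noise)
    s <- pmin(pmax(s, -1), 1)
    new("Waveform", samples = s, rate = cfg@sampleRate)
}

#' Pad or truncate a waveform to a fixed duration
#'
#' Clips shorter than the target are zero-padded at the end; longer ones are
#' truncated. Guarantees the fixed frame count the downstream spectrogram
#' shape depends on.
#'
#' @param w a [Waveform-class].
#' @param durationS target duration in seconds.
#' @return A [Waveform-class] of exactly `round(durationS * w@rate)` samples.
#' @export
fixDuration <- function(w, durationS = 1.0) {
    nTarget <- round(durationS * w@rate)
    s <- w@samples
    if (length(s) >= nTarget) s <- s[seq_len(nTarget)]
    else s <- c(s, numeric(nTarget - length(s)))
    new("Waveform", samples = s, rate = w@rate)
}
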