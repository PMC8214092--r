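#' Corpus configuration
#'
#' Parameters controlling synthetic bimodal corpus generation and the
#' sound-to-image preprocessing pipeline. The defaults reproduce the
#' published pipeline: 1-second clips at 22050 samples/s converted to a
#' 128-by-44 Mel power spectrogram (n_fft = 2048, hop = 512, centered
#' frames), zero-padded to 140-by-56 and max-pooled 5-by-2 down to the
#' 28-by-28 image format, with 20% of each class reserved for validation.
#'
#' @slot nImageClasses integer, number of image classes.
#' @slot nSoundClasses integer, number of sound classes.
#' @slot samplesPerClass integer, generated examples per class and modality.
#' @slot valFraction fraction in (0, 1) held out for validation (default 0.2).
#' @slot durationS clip duration in seconds (default 1).
#' @slot sampleRate audio sampling rate in samples/s (default 22050).
#' @slot nMels number of Mel filterbank bands (default 128).
#' @slot nFft FFT window length in samples (default 2048).
#' @slot hop frame hop in samples (default 512).
#' @slot imageNoise sd of additive gaussian pixel noise (default 0.05).
#' @slot soundNoise amplitude of additive white noise (default 0.02).
#' @slot seed integer seed for corpus generation.
#' @export
setClass("CorpusConfig", slots = c(
    nImageClasses = "integer",
    nSoundClasses = "integer",
    samplesPerClass = "integer",
    valFraction = "numeric",
    durationS = "numeric",
    sampleRate = "numeric",
    nMels = "integer",
    nFft = "integer",
    hop = "integer",
    imageNoise = "numeric",
    soundNoise = "numeric",
    seed = "integer"
))

setValidity("CorpusConfig", function(object) {
    msg <- character()
    if (object@nImageClasses < 1L) msg <- c(msg, "nImageClasses must be >= 1")
    if (object@nSoundClasses < 1L) msg <- c(msg, "nSoundClasses must be >= 1")
    if (object@samplesPerClass < 1L)
        msg <- c(msg, "samplesPerClass must be >= 1")
    if (object@valFraction <= 0 || object@valFraction >= 1)
        msg <- c(msg, "valFraction must lie strictly between 0 and 1")
    if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
    if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
    if (object@nMels < 1L) msg <- c(msg, "nMels must be >= 1")
    if (object@nFft < 2L) msg <- c(msg, "nFft must be >= 2")
    if (object@hop < 1L) msg <- c(msg, "hop must be >= 1")
    if (object@imageNoise < 0 || object@soundNoise < 0)
        msg <- c(msg, "noise amplitudes must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Create a corpus configuration
#'
#' @param nImageClasses,nSoundClasses class counts per modality; the concept
#'   task requires them to be equal.
#' @param samplesPerClass generated examples per class and modality.
#' @param valFraction validation fraction in (0, 1); default 0.2.
#' @param durationS clip duration in seconds.
#' @param sampleRate audio sampling rate in samples/s.
#' @param nMels,nFft,hop Mel spectrogram parameters.
#' @param imageNoise,soundNoise additive noise amplitudes for the two
#'   generators (sd of gaussian pixel noise; amplitude of white audio noise).
#' @param seed integer seed; the whole corpus is reproducible from it.
#' @return A validated [CorpusConfig-class] object.
#' @examples
#' cfg <- corpusConfig(nImageClasses = 6, nSoundClasses = 6,
#'                     samplesPerClass = 20, seed = 1)
#' cfg
#' @export
corpusConfig <- function(nImageClasses = 30L, nSoundClasses = 30L,
                         samplesPerClass = 200L, valFraction = 0.2,
                         durationS = 1.0, sampleRate = 22050,
                         nMels = 128L, nFft = 2048L, hop = 512L,
                         imageNoise = 0.05, soundNoise = 0.02,
                         seed = 1L) {
    new("CorpusConfig",
        nImageClasses = as.integer(nImageClasses),
        nSoundClasses = as.integer(nSoundClasses),
        samplesPerClass = as.integer(samplesPerClass),
        valFraction = valFraction, durationS = durationS,
        sampleRate = sampleRate, nMels = as.integer(nMels),
        nFft = as.integer(nFft), hop = as.integer(hop),
        imageNoise = imageNoise, soundNoise = soundNoise,
        seed = as.integer(seed))
}

#' Desk-scale corpus configuration
#'
#' A reduced configuration (6 image + 6 sound classes, 200 samples per
#' class) sized so that the full pretrain-and-probe pipeline runs in minutes
#' on one CPU while preserving every structural property of the full-size
#' corpus.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [corpusConfig()].
#' @return A [CorpusConfig-class] object.
#' @export
deskCorpusConfig <- function(seed = 1L, ...) {
    args <- list(nImageClasses = 6L, nSoundClasses = 6L,
                 samplesPerClass = 200L, seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(corpusConfig, args)
}

setMethod("show", "CorpusConfig", function(object) {
    cat("CorpusConfig\n")
    cat(sprintf("  classes: %d image + %d sound, %d samples/class\n",
                object@nImageClasses, object@nSoundClasses,
                object@samplesPerClass))
    cat(sprintf("  audio: %.2f s @ %g samples/s; mel %d x (nFft %d, hop %d)\n",
                object@durationS, object@sampleRate, object@nMels,
                object@nFft, object@hop))
    cat(sprintf("  validation fraction: %g; seed: %d\n",
                object@valFraction, object@seed))
})
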