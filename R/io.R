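## Corpus export/import and the optional real-data readers (EMNIST-style
## IDX files; 16-bit PCM WAV speech clips resampled on load).

#' Export / import a bimodal corpus
#'
#' Writes the pixel matrix as gzip-compressed CSV plus a JSON manifest of
#' the per-sample metadata, task, label count and class pairing, so a
#' generated corpus can be archived and reloaded bit-for-bit.
#'
#' @param ds a [BimodalDataset-class].
#' @param dir output directory (created if missing).
#' @return `exportCorpus` returns `dir` invisibly; `importCorpus` returns
#'   the reconstructed [BimodalDataset-class].
#' @export
exportCorpus <- function(ds, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    px <- pixelMatrix(ds)
    con <- gzfile(file.path(dir, "pixels.csv.gz"), "w")
    write.csv(as.data.frame(px), con, row.names = FALSE)
    close(con)
    cd <- as.data.frame(SummarizedExperiment::colData(ds))
    manifest <- list(task = taskType(ds), nLabels = nLabels(ds),
                     pairMap = pairMap(ds), samples = cd,
                     sampleNames = colnames(ds))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname exportCorpus
#' @export
importCorpus <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    con <- gzfile(file.path(dir, "pixels.csv.gz"))
    px <- as.matrix(read.csv(con, check.names = FALSE))
    rownames(px) <- sprintf("px%03d", seq_len(nrow(px)))
    colnames(px) <- manifest$sampleNames
    cd <- S4Vectors::DataFrame(manifest$samples,
                               row.names = manifest$sampleNames)
    cd$modality <- as.integer(cd$modality)
    cd$classId <- as.integer(cd$classId)
    cd$label <- as.integer(cd$label)
    pm <- as.data.frame(manifest$pairMap)
    if (!nrow(pm)) pm <- data.frame(soundClass = integer(),
                                    imageClass = integer())
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(pixels = px), colData = cd)
    new("BimodalDataset", se, task = manifest$task,
        nLabels = as.integer(manifest$nLabels), pairMap = pm)
}

#' Read an IDX-format array file
#'
#' Reader for the big-endian IDX format the EMNIST distribution uses
#' (magic number, dimension sizes, then unsigned-byte data). Transparently
#' handles gzip-compressed files.
#'
#' @param path path to an `.idx`/`.gz` file.
#' @return For a rank-1 file, an integer vector (labels); for rank 3, a
#'   `c(n, rows, cols)` integer array of pixel values in 0-255.
#' @export
readIDX <- function(path) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "integer", 1, size = 4, endian = "big")
    rank <- magic %% 256L
    if (magic %/% 256L %% 256L != 8L)
        stop("only unsigned-byte IDX files are supported")
    dims <- readBin(con, "integer", rank, size = 4, endian = "big")
    data <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
    if (rank == 1L) return(data)
    ## IDX stores row-major: fill the last dimension fastest
    array(data, rev(dims))  # dims become (cols, rows, n) column-major
}

#' Load the first classes of an EMNIST-style IDX pair
#'
#' @param imagesPath,labelsPath IDX image and label files.
#' @param nClasses keep only labels `0..nClasses-1` (default 30).
#' @return list with `pixels` (784 x n matrix scaled to `[0, 1]`) and
#'   `labels` (0-based integers).
#' @export
readEMNIST <- function(imagesPath, labelsPath, nClasses = 30L) {
    labels <- readIDX(labelsPath)
    imgs <- readIDX(imagesPath)          # (cols, rows, n)
    keep <- which(labels < nClasses)
    px <- vapply(keep, function(i) as.numeric(t(imgs[, , i])) / 255,
                 numeric(784L))
    list(pixels = px, labels = as.integer(labels[keep]))
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE reader for the speech-clip format (PCM, 16-bit).
#' Multi-channel files are averaged to mono.
#'
#' @param path path to a `.wav` file.
#' @return A [Waveform-class] with amplitudes in `[-1, 1]`.
#' @export
readWavePCM <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    riff <- readChar(con, 4)
    if (!identical(riff, "RIFF")) stop("not a RIFF file")
    readBin(con, "integer", 1, 4, endian = "little")
    if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
    rate <- NULL; nChan <- NULL; bits <- NULL; samples <- NULL
    repeat {
        id <- readChar(con, 4)
        if (length(id) == 0 || nchar(id) < 4) break
        size <- readBin(con, "integer", 1, 4, endian = "little")
        if (id == "fmt ") {
            fmt <- readBin(con, "integer", 2, 2, endian = "little")
            nChan <- fmt[2]
            rate <- readBin(con, "integer", 1, 4, endian = "little")
            readBin(con, "integer", 1, 4, endian = "little")
            blk <- readBin(con, "integer", 2, 2, endian = "little")
            bits <- blk[2]
            if (size > 16) readBin(con, "raw", size - 16)
        } else if (id == "data") {
            if (is.null(bits)) stop("malformed WAV: data before fmt")
            if (bits != 16L) stop("only 16-bit PCM is supported")
            samples <- readBin(con, "integer", size %/% 2, 2,
                               endian = "little")
            break
        } else {
            readBin(con, "raw", size)
        }
    }
    if (is.null(samples)) stop("no data chunk found")
    if (nChan > 1)
        samples <- colMeans(matrix(samples, nChan))
    new("Waveform", samples = samples / 32768, rate = rate)
}

#' Resample a waveform by linear interpolation
#'
#' @param w a [Waveform-class].
#' @param rate target rate in samples/s.
#' @return A [Waveform-class] at the new rate.
#' @export
resampleWaveform <- function(w, rate = 22050) {
    if (w@rate == rate) return(w)
    nOut <- round(length(w@samples) * rate / w@rate)
    tOld <- (seq_along(w@samples) - 1) / w@rate
    tNew <- (seq_len(nOut) - 1) / rate
    s <- stats::approx(tOld, w@samples, xout = tNew, rule = 2)$y
    new("Waveform", samples = s, rate = rate)
}

#' Load a speech clip ready for the spectrogram pipeline
#'
#' Reads a PCM WAV file, resamples it to the configured rate and fixes its
#' duration, yielding a clip [melSpectrogram()] accepts directly.
#'
#' @param path path to a `.wav` file.
#' @param cfg a [CorpusConfig-class].
#' @return A [Waveform-class] of exactly the configured duration and rate.
#' @export
loadSpeechClip <- function(path, cfg = corpusConfig()) {
    fixDuration(resampleWaveform(readWavePCM(path), cfg@sampleRate),
                cfg@durationS)
}

#' Write / read a corpus configuration as JSON
#'
#' A flat key-value file mirroring the [CorpusConfig-class] fields, so
#' corpus generation settings can be versioned alongside results.
#'
#' @param cfg a [CorpusConfig-class].
#' @param path JSON file path.
#' @return `writeCorpusConfig` returns `path` invisibly;
#'   `readCorpusConfig` returns the [CorpusConfig-class].
#' @export
writeCorpusConfig <- function(cfg, path) {
    fields <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                     simplify = FALSE)
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCorpusConfig
#' @export
readCorpusConfig <- function(path) {
    f <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(corpusConfig, f)
}
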