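#' Multi-channel recording container
#'
#' An `multichannel_recording` holds an N x T matrix of dimensionless
#' amplitudes in \[-1, 1\] (one row per sensor channel), its sample rate in
#' Hz, and channel labels. Channel 1 is by convention the reference sensor
#' that anchors the beamformer.
#'
#' @param samples numeric matrix, channels x time, finite values.
#' @param sample_rate_hz positive integer sample rate in Hz.
#' @param channel_ids optional character vector of channel labels.
#' @return An object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(samples, sample_rate_hz,
                                   channel_ids = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), nrow(samples) >= 1L)
  if (!all(is.finite(samples))) {
    stop("recording samples must all be finite", call. = FALSE)
  }
  sample_rate_hz <- as.integer(sample_rate_hz)
  stopifnot(length(sample_rate_hz) == 1L, sample_rate_hz > 0L)
  if (is.null(channel_ids)) {
    channel_ids <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(channel_ids) == nrow(samples))
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         channel_ids = as.character(channel_ids)),
    class = "multichannel_recording"
  )
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d channel(s) x %d samples @ %d Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
              ncol(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec a `multichannel_recording`.
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$samples)

# ---- RIFF WAV (PCM 16-bit) ------------------------------------------------
# Hand-written chunk walker: no installed R package reads WAV. Only
# uncompressed PCM 16-bit is supported, matching the acquisition format.

read_wav_one <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      hdr <- readBin(body[1:16], "integer", n = 8L, size = 2L,
                     endian = "little", signed = FALSE)
      fmt <- list(
        audio_format = hdr[1],
        n_channels = hdr[2],
        sample_rate = hdr[3] + 65536L * hdr[4],
        bits = hdr[8]
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop("unsupported WAV encoding (need PCM 16-bit): ", path, call. = FALSE)
  }
  pcm <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                 size = 2L, endian = "little", signed = TRUE)
  nch <- fmt$n_channels
  nfr <- length(pcm) %/% nch
  samples <- matrix(pcm[seq_len(nfr * nch)], nrow = nch) / 32768
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Read a multi-channel WAV scene
#'
#' Accepts either one interleaved N-channel WAV file or a vector of N mono
#' WAV paths (one per sensor); both dialects occur in multi-probe field
#' recordings. PCM integers are scaled to \[-1, 1).
#'
#' @param paths character vector of one or more WAV file paths.
#' @return A [multichannel_recording()].
#' @export
read_multichannel_wav <- function(paths) {
  stopifnot(is.character(paths), length(paths) >= 1L, all(file.exists(paths)))
  parts <- lapply(paths, read_wav_one)
  rates <- vapply(parts, function(p) p$sample_rate, numeric(1))
  lens <- vapply(parts, function(p) ncol(p$samples), numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("channel files have mismatched sample rates", call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("channel files have mismatched lengths", call. = FALSE)
  }
  samples <- do.call(rbind, lapply(parts, function(p) p$samples))
  multichannel_recording(samples, rates[1])
}

#' Write a recording as one interleaved 16-bit PCM WAV
#'
#' Samples are clipped to the representable PCM range and rounded to the
#' nearest 16-bit level, so a write/read round trip agrees with the input to
#' within one quantization step (2^-15).
#'
#' @param rec a [multichannel_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multichannel_wav <- function(rec, path) {
  stopifnot(inherits(rec, "multichannel_recording"))
  x <- rec$samples
  pcm <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
  pcm <- as.vector(matrix(pcm, nrow = nrow(x)))  # interleave channels
  nch <- nrow(x)
  byte_rate <- rec$sample_rate_hz * nch * 2L
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, nch), con, size = 2L, endian = "little")
  writeBin(as.integer(rec$sample_rate_hz), con, size = 4L, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4L, endian = "little")
  writeBin(c(nch * 2L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
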