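#' Construct an audio signal object
#'
#' Light-weight container for a sampled mono waveform. Amplitudes are
#' dimensionless and nominally within \[-1, 1\] after 16-bit normalisation.
#'
#' @param samples numeric vector of sample amplitudes; must be finite and
#'   of length at least 1.
#' @param fs sample rate in Hz, positive.
#' @param source_id opaque recording identifier carried through the
#'   pipeline (file name, corpus id, ...).
#' @return an object of class `audio_signal` with fields `samples`, `fs`
#'   and `source_id`.
#' @export
audio_signal <- function(samples, fs, source_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("empty audio signal")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  structure(list(samples = samples, fs = as.numeric(fs),
                 source_id = source_id),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %s: %d samples @ %g Hz (%.3f s)\n",
              ifelse(is.na(x$source_id), "?", x$source_id),
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a RIFF PCM WAV file
#'
#' Reads 16-bit PCM WAV audio. Multi-channel files are reduced to channel 1.
#' Samples are scaled by 2^-15 so full scale maps to approximately
#' \[-1, 1\].
#'
#' @param path path to a RIFF PCM WAV file.
#' @return an [audio_signal] with `fs` taken from the file header.
#' @export
load_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(sz) == 0L) break
    chunk <- readBin(con, "raw", sz)
    if (identical(id, "fmt ")) fmt <- chunk
    if (identical(id, "data")) data_raw <- chunk
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV file (missing fmt/data chunk): ", path)
  }
  audio_format <- readBin(fmt[1:2], "integer", 1L, size = 2L,
                          signed = FALSE, endian = "little")
  n_channels <- readBin(fmt[3:4], "integer", 1L, size = 2L,
                        signed = FALSE, endian = "little")
  fs <- readBin(fmt[5:8], "integer", 1L, size = 4L, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1L, size = 2L,
                  signed = FALSE, endian = "little")
  if (audio_format != 1L || bits != 16L) {
    stop("only 16-bit PCM WAV is supported (format=", audio_format,
         ", bits=", bits, ")")
  }
  n <- length(data_raw) %/% 2L
  if (n < 1L) stop("zero-length WAV data: ", path)
  x <- readBin(data_raw, "integer", n, size = 2L, signed = TRUE,
               endian = "little")
  if (n_channels > 1L) {
    x <- x[seq(1L, n, by = n_channels)]  # interleaved; keep channel 1
  }
  audio_signal(x / 32768, fs, source_id = basename(path))
}

#' Write a RIFF PCM 16-bit WAV file
#'
#' @param sig an [audio_signal], or a numeric matrix with one channel per
#'   column (interleaved on write).
#' @param path output path.
#' @param fs sample rate; only needed when `sig` is a bare matrix/vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sig, path, fs = NULL) {
  if (inherits(sig, "audio_signal")) {
    x <- matrix(sig$samples, ncol = 1L)
    fs <- sig$fs
  } else {
    if (is.null(fs)) stop("fs required when writing a bare matrix")
    x <- as.matrix(sig)
  }
  n_channels <- ncol(x)
  q <- pmax(pmin(round(t(x) * 32768), 32767), -32768)  # interleave + clip
  pcm <- as.integer(q)
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")             # PCM
  writeBin(n_channels, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * n_channels * 2L), con, size = 4L,
           endian = "little")                                 # byte rate
  writeBin(as.integer(n_channels * 2L), con, size = 2L,
           endian = "little")                                 # block align
  writeBin(16L, con, size = 2L, endian = "little")            # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
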