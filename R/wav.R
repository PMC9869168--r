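#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit integer PCM (the format of the
#' emotional-speech corpora this package targets). Stereo input is averaged
#' to mono with a message. No compression, floats, or extensible headers.
#'
#' @param path Path to a `.wav` file.
#' @return An `imemd_signal` with samples scaled to [-1, 1].
#' @export
read_wav_pcm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (!length(id) || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      if (fmt[1L] != 1L) stop("only integer PCM WAV is supported")
      channels <- fmt[2L]
      rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
      rest <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      bits <- rest[2L]
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      if (bits != 16L) stop("only 16-bit PCM is supported")
      data <- readBin(con, "integer", sz / 2L, size = 2L, signed = TRUE,
                      endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(data)) stop("no data chunk found in ", path)
  x <- data / 32768
  if (channels > 1L) {
    message("averaging ", channels, "-channel audio to mono")
    x <- colMeans(matrix(x, nrow = channels))
  }
  imemd_signal(x, rate)
}

#' Write a PCM WAV file
#'
#' Writes a mono 16-bit PCM WAV. Samples are clipped to [-1, 1] before
#' quantization.
#'
#' @param x An `imemd_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav_pcm <- function(x, path) {
  stopifnot(inherits(x, "imemd_signal"))
  v <- pmin(pmax(x$samples, -1), 1)
  q <- as.integer(round(v * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(q) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")        # PCM, mono
  writeBin(as.integer(x$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(x$rate * 2L), con, size = 4L, endian = "little")
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
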