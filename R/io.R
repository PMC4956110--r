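#' Read and write mono PCM WAV files
#'
#' A minimal RIFF/WAVE codec for the package's audio interchange: 16- or
#' 24-bit integer PCM, single channel. Samples are scaled to `[-1, 1]`.
#'
#' @param path File path.
#' @return `read_wav` returns a numeric vector with attribute
#'   `sample_rate`; `write_wav` returns `path` invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (hdr != "RIFF") stop("invalid-input: not a RIFF file")
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  if (readChar(con, 4L, useBytes = TRUE) != "WAVE")
    stop("invalid-input: not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, 2L, endian = "little"),
        channels = readBin(con, "integer", 1L, 2L, endian = "little"),
        sample_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, 2L, endian = "little"),
        bits = readBin(con, "integer", 1L, 2L, endian = "little"))
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
      break
    } else readBin(con, "raw", size + size %% 2L)
  }
  if (is.null(fmt) || is.null(data)) stop("invalid-input: malformed WAV")
  if (fmt$channels != 1L) stop("invalid-input: only mono WAV is supported")
  if (fmt$audio_format != 1L) stop("invalid-input: only PCM WAV is supported")
  x <- if (fmt$bits == 16L) {
    readBin(data, "integer", length(data) %/% 2L, 2L, signed = TRUE,
            endian = "little") / 32767
  } else if (fmt$bits == 24L) {
    n <- length(data) %/% 3L
    b <- matrix(as.integer(data[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388607
  } else stop("invalid-input: only 16/24-bit PCM is supported")
  structure(x, sample_rate = fmt$sample_rate)
}

#' @rdname read_wav
#' @param wave Numeric samples in `[-1, 1]` (clipped if outside).
#' @param sample_rate Sample rate in Hz.
#' @export
write_wav <- function(wave, path, sample_rate = 32000) {
  x <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4L, endian = "little")
  writeBin(x, con, size = 2L, endian = "little")
  invisible(path)
}
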