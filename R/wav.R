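#' Read and write WAV audio files
#'
#' Minimal RIFF/WAVE codec covering integer PCM (16/24/32-bit) and IEEE
#' float (32-bit) encodings. Stereo and multichannel files are mixed down to
#' mono by averaging channels; integer samples are scaled to `[-1, 1]`.
#'
#' @param path file path.
#' @param id,group labels attached to the returned [sm_signal]; `id`
#'   defaults to the file name.
#' @return `read_wav()` returns a [sm_signal]; `write_wav()` returns `path`
#'   invisibly.
#' @export
read_wav <- function(path, id = basename(path), group = id) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4L, useBytes = TRUE)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (tag == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        channels = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
    } else if (tag == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      n <- size %/% (fmt$bits %/% 8L)
      samples <- if (fmt$audio_format == 3L) {
        readBin(con, "double", n, size = fmt$bits %/% 8L, endian = "little")
      } else if (fmt$bits == 24L) {
        raw <- readBin(con, "raw", size)
        b <- matrix(as.integer(raw), nrow = 3L)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        ifelse(v >= 8388608, v - 16777216, v) / 8388608
      } else {
        readBin(con, "integer", n, size = fmt$bits %/% 8L, signed = TRUE,
                endian = "little") / 2^(fmt$bits - 1L)
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  if (fmt$channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  sm_signal(samples, fmt$rate, id = id, group = group)
}

#' @rdname read_wav
#' @param x a [sm_signal] or numeric vector in `[-1, 1]`.
#' @param rate sample rate when `x` is a bare vector.
#' @param bits output encoding: 16 or 32 (integer PCM).
#' @export
write_wav <- function(x, path, rate = NULL, bits = 16L) {
  sig <- if (inherits(x, "sm_signal")) x else as_sm_signal(x, rate)
  stopifnot(bits %in% c(16L, 32L))
  s <- pmax(-1, pmin(1, sig$samples))
  v <- as.integer(round(s * (2^(bits - 1L) - 1L)))
  bytes <- bits %/% 8L
  data_size <- length(v) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")             # PCM
  writeBin(1L, con, size = 2L, endian = "little")             # mono
  writeBin(as.integer(sig$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sig$rate * bytes), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(v, con, size = bytes, endian = "little")
  invisible(path)
}
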