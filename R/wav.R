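# Minimal RIFF/WAVE reader and writer: PCM16, PCM24 and IEEE float32,
# mono or stereo. (No WAV-capable R package is part of this stack, and the
# container is simple enough to handle directly.)

#' Read a WAV file
#'
#' Supports PCM 16/24-bit and IEEE float32, any channel count.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `audio` (numeric vector, or samples x channels
#'   matrix for multichannel files, in \[-1, 1\] for PCM) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file")
  x <- switch(
    paste(fmt$audio_format, fmt$bits),
    "1 16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                     signed = TRUE, endian = "little") / 32768,
    "1 24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 2^23, v - 2^24, v)
      v / 2^23
    },
    "3 32" = readBin(data_raw, "double", length(data_raw) / 4, 4,
                     endian = "little"),
    stop(sprintf("unsupported WAV codec (format %d, %d bits)",
                 fmt$audio_format, fmt$bits)))
  if (fmt$n_channels > 1L)
    x <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  list(audio = x, fs = fmt$fs)
}

#' Write a WAV file
#'
#' @param audio Numeric vector, or samples x channels matrix.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float32, lossless round-trip).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, fs, path, bits = 32) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  m <- if (is.matrix(audio)) audio else matrix(audio, ncol = 1)
  x <- as.numeric(t(m))                   # interleave channels
  n_ch <- ncol(m)
  bytes_per <- bits / 8
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(if (bits == 16) 1 else 3); w16(n_ch); w32(fs)
  w32(fs * n_ch * bytes_per); w16(n_ch * bytes_per); w16(bits)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bits == 16) {
    v <- as.integer(round(pmin(pmax(x, -1), 32767 / 32768) * 32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
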