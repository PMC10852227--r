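# Minimal RIFF/WAVE reader and writer (PCM 16/24/32-bit and IEEE float32),
# sufficient for speech stimuli; returns samples scaled to [-1, 1].

#' Read a WAV file
#'
#' Supports PCM 16/24/32-bit and 32-bit IEEE float, mono or multi-channel.
#' Integer formats are scaled to `[-1, 1]`.
#'
#' @param path file path.
#' @return list with `samples` (matrix, one column per channel) and `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      u16 <- function(i) sum(as.integer(fmt_raw[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(fmt_raw[i:(i + 3)]) * 256^(0:3))
      fmt <- list(format = u16(1), channels = u16(3), rate = u32(5), bits = u16(15))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt or data chunk")
  bytes <- fmt$bits / 8
  n <- length(data) %/% (bytes * fmt$channels)
  if (fmt$format == 3 || (fmt$format == 65534 && fmt$bits == 32)) {
    x <- readBin(data, "double", n * fmt$channels, size = 4, endian = "little")
  } else if (fmt$format == 1 && fmt$bits %in% c(16, 32)) {
    x <- readBin(data, "integer", n * fmt$channels, size = bytes,
                 signed = TRUE, endian = "little") / 2^(fmt$bits - 1)
  } else if (fmt$format == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(data[seq_len(n * fmt$channels * 3)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    stop("unsupported WAV format: code ", fmt$format, ", ", fmt$bits, " bits")
  }
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE), rate_hz = fmt$rate)
}

#' Write a WAV file
#'
#' @param samples numeric vector or matrix (one column per channel), expected
#'   in `[-1, 1]` for PCM output.
#' @param rate_hz sampling rate in Hz.
#' @param path output path.
#' @param bits 16 or 24 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate_hz, path, bits = 16) {
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  ch <- ncol(x)
  inter <- as.numeric(t(x))
  bytes <- bits / 8
  data_sz <- length(inter) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 32) 3 else 1), con, size = 2, endian = "little")
  writeBin(as.integer(ch), con, size = 2, endian = "little")
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * ch * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(ch * bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else if (bits == 16) {
    v <- as.integer(round(pmax(pmin(inter, 1), -1) * (2^15 - 1)))
    writeBin(v, con, size = 2, endian = "little")
  } else if (bits == 24) {
    v <- round(pmax(pmin(inter, 1), -1) * (2^23 - 1))
    v <- ifelse(v < 0, v + 2^24, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else stop("bits must be 16, 24 or 32")
  invisible(path)
}
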