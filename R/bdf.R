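# Readers for raw EEG: BioSemi BDF (24-bit EDF variant) and plain columnar
# text. Referencing (e.g. Cz minus mastoid average) is done at read time so
# downstream stages see a single referenced channel.

#' Read one referenced channel from a BioSemi BDF file
#'
#' Parses the BDF header (the 24-bit variant of EDF), extracts the requested
#' channel and optional reference channels, and returns the referenced
#' single-channel signal in physical units.
#'
#' @param path BDF file path.
#' @param channel channel label (e.g. `"Cz"`).
#' @param ref character vector of reference channel labels whose average is
#'   subtracted (e.g. `c("M1", "M2")`); empty for none.
#' @return list with `samples` and `rate_hz`.
#' @export
read_bdf <- function(path, channel, ref = character(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  id0 <- readBin(con, "raw", 1)
  magic <- readChar(con, 7, useBytes = TRUE)
  if (!(as.integer(id0) == 255L && identical(magic, "BIOSEMI")))
    stop("not a BDF file")
  invisible(readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE))
  invisible(readChar(con, 8, useBytes = TRUE))          # header bytes
  invisible(readChar(con, 44, useBytes = TRUE))         # version / reserved
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  rd <- function(w) vapply(seq_len(ns), function(i)
    trimws(readChar(con, w, useBytes = TRUE)), character(1))
  labels <- rd(16)
  invisible(rd(80)); invisible(rd(8))                   # transducer, unit
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin_ <- as.numeric(rd(8)); dmax_ <- as.numeric(rd(8))
  invisible(rd(80))                                     # prefilter
  nsamp <- as.integer(rd(8))
  invisible(rd(32))                                     # reserved
  want <- c(channel, ref)
  idx <- match(want, labels)
  if (anyNA(idx)) stop("channel(s) not found: ",
                       paste(want[is.na(idx)], collapse = ", "))
  rates <- nsamp / dur
  if (length(unique(rates[idx])) != 1) stop("channels differ in rate")
  out <- matrix(0, n_rec * nsamp[idx[1]], length(idx))
  read24 <- function(raw3) {
    m <- matrix(as.integer(raw3), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 2^23, v - 2^24, v)
  }
  rec_bytes <- nsamp * 3
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw3 <- readBin(con, "raw", rec_bytes[s])
      j <- match(s, idx)
      if (!is.na(j)) {
        dig <- read24(raw3)
        phys <- pmin_[s] + (dig - dmin_[s]) * (pmax_[s] - pmin_[s]) /
          (dmax_[s] - dmin_[s])
        out[((r - 1) * nsamp[s] + 1):(r * nsamp[s]), j] <- phys
      }
    }
  }
  sig <- out[, 1]
  if (length(ref) > 0) sig <- sig - rowMeans(out[, -1, drop = FALSE])
  list(samples = sig, rate_hz = rates[idx[1]])
}

#' Read a single-column EEG text file
#'
#' Expects a header line `# rate_hz: <rate>` followed by one numeric sample
#' per line (comment lines starting with `#` are skipped).
#'
#' @param path file path.
#' @return list with `samples` and `rate_hz`.
#' @export
read_eeg_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*rate_hz\\s*:", lines, value = TRUE)
  if (length(hdr) == 0) stop("missing '# rate_hz:' header")
  rate <- as.numeric(sub("^#\\s*rate_hz\\s*:\\s*", "", hdr[1]))
  body <- lines[!startsWith(trimws(lines), "#")]
  list(samples = as.numeric(body[nzchar(body)]), rate_hz = rate)
}

#' Write a single-column EEG text file
#'
#' @param samples numeric series.
#' @param rate_hz sampling rate recorded in the header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_text <- function(samples, rate_hz, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %g", rate_hz), con)
  writeLines(format(samples, digits = 17, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}
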