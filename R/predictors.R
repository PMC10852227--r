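# Auditory-periphery predictor models of increasing complexity.
#
# RS   - half-wave rectified speech.
# GT   - gammatone filterbank (31 filters, 80-8000 Hz, 1-ERB spacing),
#        absolute band outputs averaged over bands.
# OSS  - gammatone + inner-hair-cell transduction (half-wave rectification
#        followed by lowpass), averaged over bands.
# OSSA - OSS + five divisive adaptation loops, averaged over bands.
#
# All predictors are computed at the audio rate for both stimulus polarities,
# anti-alias resampled to the EEG rate, circularly shifted to maximize the
# correlation with the rectified-speech predictor (removing model lags), and
# scaled to unit variance.

#' ERB-number scale
#'
#' `erb_number(f) = 21.4 * log10(0.00437 * f + 1)`; its inverse maps an
#' ERB-number back to frequency in Hz.
#'
#' @param f_hz frequency in Hz.
#' @return ERB-number (dimensionless).
#' @export
erb_number <- function(f_hz) 21.4 * log10(0.00437 * f_hz + 1)

#' @rdname erb_number
#' @param erb ERB-number.
#' @export
erb_number_inv <- function(erb) (10^(erb / 21.4) - 1) / 0.00437

# Equivalent rectangular bandwidth (Glasberg & Moore) in Hz at frequency f.
erb_bandwidth <- function(f_hz) 24.7 * (0.00437 * f_hz + 1)

#' ERB-spaced filterbank centre frequencies
#'
#' Centre frequencies start at `f_lo` and step by `spacing_erb` on the
#' ERB-number scale, never exceeding `f_hi`. The default span of 80-8000 Hz
#' at 1-ERB spacing yields 31 filters.
#'
#' @param f_lo,f_hi frequency range in Hz.
#' @param spacing_erb spacing in ERB-numbers (default 1).
#' @return An object of class `filterbank_spec` with fields `f_lo`, `f_hi`,
#'   `spacing_erb`, `center_freqs`.
#' @export
erb_space <- function(f_lo = 80, f_hi = 8000, spacing_erb = 1) {
  if (!(f_lo > 0) || f_lo > f_hi) stop("need 0 < f_lo <= f_hi")
  if (spacing_erb <= 0) stop("spacing_erb must be > 0")
  e_lo <- erb_number(f_lo); e_hi <- erb_number(f_hi)
  steps <- seq(e_lo, e_hi + 1e-12, by = spacing_erb)
  cf <- erb_number_inv(steps)
  cf[1] <- f_lo
  cf <- cf[cf <= f_hi + 1e-9]
  structure(list(f_lo = f_lo, f_hi = f_hi, spacing_erb = spacing_erb,
                 center_freqs = cf),
            class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf("<filterbank_spec> %d filters, %g-%g Hz, %g ERB spacing\n",
              length(x$center_freqs), x$f_lo, x$f_hi, x$spacing_erb))
  invisible(x)
}

# Slaney-style 4th-order gammatone as four cascaded second-order sections.
# Returns list(sections = list of list(b, a), gain) with unit gain at cf.
gammatone_coefs <- function(cf, rate_hz) {
  T <- 1 / rate_hz
  B <- 1.019 * 2 * pi * erb_bandwidth(cf)
  ct <- cos(2 * pi * cf * T); st <- sin(2 * pi * cf * T); eb <- exp(B * T)
  a <- c(1, -2 * ct / eb, exp(-2 * B * T))
  k <- c(sqrt(3 + 2^1.5), -sqrt(3 + 2^1.5), sqrt(3 - 2^1.5), -sqrt(3 - 2^1.5))
  sections <- lapply(k, function(kk) {
    list(b = c(T, -(2 * T * ct / eb + kk * T * st / eb) / 2, 0), a = a)
  })
  # normalize to unit magnitude response at cf (evaluated on the unit circle)
  z <- exp(2i * pi * cf / rate_hz)
  H <- prod(vapply(sections, function(s) {
    abs(sum(s$b * z^(0:-2)) / sum(s$a * z^(0:-2)))
  }, numeric(1)))
  list(sections = sections, gain = H)
}

#' Gammatone filterbank
#'
#' Applies a bank of 4th-order gammatone filters (four cascaded second-order
#' sections per band) to a stimulus. Each band is normalized to unit gain at
#' its centre frequency.
#'
#' @param x an [audio_stimulus()] or numeric vector.
#' @param spec a [erb_space()] filterbank specification.
#' @param rate_hz rate for bare numeric input.
#' @return numeric matrix, one column per centre frequency.
#' @export
gammatone_filterbank <- function(x, spec = erb_space(), rate_hz = NULL) {
  x <- as_stimulus(x, rate_hz)
  if (x$rate_hz < 2 * spec$f_hi) stop("sampling rate below 2 * f_hi")
  cfs <- spec$center_freqs
  out <- matrix(0, length(x$samples), length(cfs))
  for (i in seq_along(cfs)) {
    co <- gammatone_coefs(cfs[i], x$rate_hz)
    y <- x$samples
    for (s in co$sections) y <- as.numeric(signal::filter(s$b, s$a, y))
    out[, i] <- y / co$gain
  }
  colnames(out) <- sprintf("%.1fHz", cfs)
  out
}

#' Inner-hair-cell transduction
#'
#' Half-wave rectification followed by a first-order Butterworth lowpass
#' (default cutoff 1000 Hz, unit DC gain) applied per band: a standard
#' approximation of inner-hair-cell transduction.
#'
#' @param bands numeric matrix (one column per band) or vector.
#' @param rate_hz sampling rate.
#' @param cutoff_hz lowpass cutoff in Hz.
#' @return matrix of non-negative band signals.
#' @export
ihc_transduction <- function(bands, rate_hz, cutoff_hz = 1000) {
  b <- if (is.matrix(bands)) bands else matrix(bands, ncol = 1)
  if (!all(is.finite(b))) stop("non-finite band input")
  out <- apply(b, 2, function(col) {
    butter1_filter(pmax(col, 0), cutoff_hz, rate_hz, "low")
  })
  pmax(matrix(out, nrow = nrow(b)), 0)
}

#' Adaptation loops
#'
#' Five cascaded divisive-feedback loops per band with time constants
#' `{5, 50, 129, 253, 500}` ms: each loop divides its input by a lowpass
#' (RC) filtered copy of its own output. Steady-state output for constant
#' input `I` is `I^(1/32)`, the canonical compressive adaptation law; onsets
#' overshoot, capped by a smooth limiter at `limit` times the steady-state
#' response to full-scale input. Inputs are floored at `minlvl` of full
#' scale. The raw divisor-chain output is returned (no rescaling to model
#' units).
#'
#' @param bands non-negative matrix (one column per band) or vector, the
#'   output of [ihc_transduction()].
#' @param rate_hz sampling rate.
#' @param tau_s loop time constants in seconds.
#' @param minlvl minimum input level relative to full scale.
#' @param limit overshoot limiter factor (set `<= 1` to disable).
#' @return matrix of adapted band signals.
#' @export
adaptation_loops <- function(bands, rate_hz,
                             tau_s = c(0.005, 0.05, 0.129, 0.253, 0.5),
                             minlvl = 1e-5, limit = 10) {
  b <- if (is.matrix(bands)) bands else matrix(bands, ncol = 1)
  if (any(b < 0)) stop("adaptation loops require non-negative input")
  adapt_loops_cpp(b, rate_hz, tau_s, minlvl, limit)
}

#' Predictor container
#'
#' @param samples numeric series at the EEG rate.
#' @param rate_hz sampling rate.
#' @param kind one of `"RS"`, `"GT"`, `"OSS"`, `"OSSA"`, `"EXTERNAL"`.
#' @param polarity `"+"` or `"-"`.
#' @param shift integer circular alignment shift (samples) already applied.
#' @return object of class `predictor`.
#' @export
predictor <- function(samples, rate_hz, kind, polarity = "+", shift = 0L) {
  stopifnot(kind %in% c("RS", "GT", "OSS", "OSSA", "EXTERNAL"))
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 kind = kind, polarity = polarity, shift = as.integer(shift)),
            class = "predictor")
}

#' @export
print.predictor <- function(x, ...) {
  cat(sprintf("<predictor> %s (%s): %d samples at %g Hz, shift %d\n",
              x$kind, x$polarity, length(x$samples), x$rate_hz, x$shift))
  invisible(x)
}

# Model-stage transform at the audio rate (single polarity, before
# resampling). Returns a numeric series.
predictor_drive <- function(x, kind, spec, ihc_cutoff_hz) {
  s <- x$samples
  switch(kind,
    RS = pmax(s, 0),
    GT = rowMeans(abs(gammatone_filterbank(x, spec))),
    OSS = rowMeans(ihc_transduction(gammatone_filterbank(x, spec), x$rate_hz,
                                    ihc_cutoff_hz)),
    OSSA = rowMeans(adaptation_loops(
      ihc_transduction(gammatone_filterbank(x, spec), x$rate_hz, ihc_cutoff_hz),
      x$rate_hz)),
    stop("unknown predictor kind: ", kind)
  )
}

#' Generate a predictor pair from a stimulus polarity pair
#'
#' Runs the chosen auditory model on both polarities of the stimulus,
#' resamples the outputs to the EEG rate with brick-wall anti-aliasing,
#' removes the model's inherent lag by circularly shifting to the maximum
#' correlation with the rectified-speech (RS) predictor, and scales each
#' polarity to unit variance (predictor units are arbitrary; unit variance
#' makes TRF amplitudes comparable across models).
#'
#' @param pair a [polarity_pair()] (or single [audio_stimulus()], from which
#'   the pair is formed).
#' @param kind `"RS"`, `"GT"`, `"OSS"` or `"OSSA"`.
#' @param eeg_rate_hz target rate (default 4096).
#' @param rs_reference optional precomputed RS reference [predictor()] at the
#'   EEG rate used for lag alignment; computed internally when `NULL`.
#' @param spec filterbank specification for the filterbank models.
#' @param ihc_cutoff_hz inner-hair-cell lowpass cutoff.
#' @param external optional list with `positive` and `negative` numeric
#'   series at the audio rate for `kind = "EXTERNAL"` (adapter for
#'   externally computed auditory-nerve model outputs).
#' @return object of class `predictor_pair` with fields `positive`,
#'   `negative`, `kind`.
#' @export
make_predictor_pair <- function(pair, kind = "RS", eeg_rate_hz = 4096,
                                rs_reference = NULL, spec = erb_space(),
                                ihc_cutoff_hz = 1000, external = NULL) {
  if (inherits(pair, "audio_stimulus")) pair <- polarity_pair(pair)
  stopifnot(inherits(pair, "polarity_pair"))
  audio_rate <- pair$positive$rate_hz
  if (kind == "EXTERNAL") {
    if (is.null(external)) stop("kind EXTERNAL requires `external` series")
    drives <- list(positive = as.numeric(external$positive),
                   negative = as.numeric(external$negative))
  } else {
    drives <- list(positive = predictor_drive(pair$positive, kind, spec, ihc_cutoff_hz),
                   negative = predictor_drive(pair$negative, kind, spec, ihc_cutoff_hz))
  }
  down <- lapply(drives, resample_fft, rate_in = audio_rate, rate_out = eeg_rate_hz)
  if (length(down$positive) != length(down$negative))
    stop("length mismatch after resampling")
  if (kind == "RS" && is.null(rs_reference)) {
    shifts <- c(positive = 0L, negative = 0L)
  } else {
    ref <- if (is.null(rs_reference)) {
      resample_fft(predictor_drive(pair$positive, "RS", spec, ihc_cutoff_hz),
                   audio_rate, eeg_rate_hz)
    } else rs_reference$samples
    shifts <- vapply(down, best_circular_shift, integer(1), ref = ref)
    down <- Map(circ_shift, down, shifts)
  }
  scale_uv <- function(v) {
    sdv <- stats::sd(v)
    if (sdv == 0) stop("degenerate (constant) predictor")
    v / sdv
  }
  structure(list(
    positive = predictor(scale_uv(down$positive), eeg_rate_hz, kind, "+", shifts[["positive"]]),
    negative = predictor(scale_uv(down$negative), eeg_rate_hz, kind, "-", shifts[["negative"]]),
    kind = kind
  ), class = "predictor_pair")
}

#' @export
print.predictor_pair <- function(x, ...) {
  cat(sprintf("<predictor_pair> %s: %d samples at %g Hz\n",
              x$kind, length(x$positive$samples), x$positive$rate_hz))
  invisible(x)
}

# Mean of the two polarity predictors (used for prediction).
pair_mean <- function(pair) (pair$positive$samples + pair$negative$samples) / 2
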