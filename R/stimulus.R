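# Speech stimulus preconditioning: mono mix, gentle 1 kHz first-order
# highpass (emphasizes the frequencies that drive the brainstem response),
# r.m.s. calibration against speech-shaped noise, polarity pair.

#' Audio stimulus container
#'
#' A light container for a pressure waveform in arbitrary digital units.
#'
#' @param samples numeric waveform (one channel).
#' @param rate_hz sampling rate in Hz.
#' @param label free-text label.
#' @return An object of class `audio_stimulus` with fields `samples`,
#'   `rate_hz`, `label`.
#' @export
audio_stimulus <- function(samples, rate_hz, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty stimulus")
  if (!all(is.finite(samples))) stop("non-finite samples in stimulus")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0")
  structure(list(samples = samples, rate_hz = rate_hz, label = label),
            class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("<audio_stimulus> %s: %.2f s at %g Hz, rms %.4g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples) / x$rate_hz, x$rate_hz, rms(x$samples)))
  invisible(x)
}

as_stimulus <- function(x, rate_hz = NULL, label = "") {
  if (inherits(x, "audio_stimulus")) return(x)
  if (is.null(rate_hz)) stop("rate_hz required for a bare numeric stimulus")
  audio_stimulus(x, rate_hz, label)
}

#' Precondition a speech stimulus
#'
#' Averages the channels to mono and applies a causal first-order Butterworth
#' highpass (default cutoff 1 kHz) that emphasizes the high frequencies the
#' brainstem response is most strongly driven by, while leaving the speech
#' natural-sounding.
#'
#' @param raw numeric vector (mono) or matrix with one channel per column.
#' @param rate_hz sampling rate in Hz; must exceed `2 * highpass_hz`.
#' @param highpass_hz highpass cutoff in Hz (default 1000).
#' @param label label for the returned stimulus.
#' @return An [audio_stimulus()].
#' @export
preprocess_stimulus <- function(raw, rate_hz, highpass_hz = 1000, label = "") {
  if (is.null(raw) || length(raw) == 0) stop("empty input")
  if (rate_hz <= 2 * highpass_hz) stop("sampling rate too low for the highpass cutoff")
  mono <- if (is.matrix(raw)) rowMeans(raw) else as.numeric(raw)
  y <- butter1_filter(mono, highpass_hz, rate_hz, "high")
  audio_stimulus(y, rate_hz, label)
}

#' Speech-shaped noise
#'
#' White Gaussian noise re-shaped to the long-term magnitude spectrum of a
#' reference stimulus: the full-length Fourier magnitudes of the reference are
#' imposed on random phases. Used as the r.m.s. calibration reference.
#'
#' @param reference an [audio_stimulus()] (or numeric with `rate_hz`).
#' @param seed integer seed; the output is reproducible for a fixed seed.
#' @param rate_hz rate, only needed when `reference` is a bare numeric.
#' @return An [audio_stimulus()] of the same length and rate as the reference.
#' @export
speech_shaped_noise <- function(reference, seed = 1L, rate_hz = NULL) {
  reference <- as_stimulus(reference, rate_hz)
  x <- reference$samples
  if (all(x == 0)) stop("all-zero reference")
  n <- length(x)
  mag <- Mod(stats::fft(x))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  ph <- W / ifelse(Mod(W) > 0, Mod(W), 1)
  y <- Re(stats::fft(mag * ph, inverse = TRUE)) / n
  audio_stimulus(y, reference$rate_hz, paste0(reference$label, " (speech-shaped noise)"))
}

#' Calibrate the r.m.s. level of a stimulus
#'
#' Pure digital rescaling so that the waveform's root-mean-square value equals
#' a target. Presentation level (dB SPL) is not modelled: a physical level
#' maps to a target r.m.s. in digital units, which is what level-dependent
#' predictor models consume.
#'
#' @param x an [audio_stimulus()] (or numeric with `rate_hz`).
#' @param target_rms positive target r.m.s. value.
#' @param rate_hz rate for bare numeric input.
#' @return The rescaled [audio_stimulus()].
#' @export
calibrate_rms <- function(x, target_rms = 1, rate_hz = NULL) {
  x <- as_stimulus(x, rate_hz)
  if (target_rms <= 0) stop("target_rms must be > 0")
  r <- rms(x$samples)
  if (r == 0) stop("silent input cannot be calibrated")
  audio_stimulus(x$samples * (target_rms / r), x$rate_hz, x$label)
}

#' Polarity pair
#'
#' The original and sign-inverted stimulus. Predictors and TRFs are computed
#' for both polarities and averaged, cancelling rectification-phase effects
#' (the analogue of alternating-polarity click protocols).
#'
#' @param x an [audio_stimulus()] (or numeric with `rate_hz`).
#' @param rate_hz rate for bare numeric input.
#' @return An object of class `polarity_pair` with fields `positive` and
#'   `negative`.
#' @export
polarity_pair <- function(x, rate_hz = NULL) {
  x <- as_stimulus(x, rate_hz)
  structure(list(
    positive = x,
    negative = audio_stimulus(-x$samples, x$rate_hz, paste0(x$label, " (inverted)"))
  ), class = "polarity_pair")
}
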