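# Temporal response function estimation.
#
# The TRF is estimated with the unregularized frequency-domain (cross-
# spectral) deconvolution
#
#   TRF = IFFT[ sum_i w_i conj(F{x_i}) F{y_i}  /  (1/N) sum_i conj(F{x_i}) F{x_i} ]
#
# with inverse-variance trial weights w_i in the numerator and the plain 1/N
# average in the denominator. The result has circular lags from -T/2 to T/2.
# Post-processing: 30-1000 Hz delay-compensated FIR bandpass, 2 ms Hamming
# smoothing, extraction of the -10..30 ms segment and subtraction of the
# -10..0 ms baseline mean.

#' TRF waveform container
#'
#' @param coef numeric coefficients.
#' @param lag_samples integer lags in samples (same length as `coef`).
#' @param rate_hz sampling rate.
#' @param stage processing stage: `"raw"`, `"smoothed"` (filtered and
#'   smoothed) or `"baselined"` (extracted segment).
#' @return object of class `trf_waveform`.
#' @export
trf_waveform <- function(coef, lag_samples, rate_hz, stage = "raw") {
  structure(list(coef = as.numeric(coef),
                 lag_samples = as.integer(lag_samples),
                 lag_ms = lag_samples / rate_hz * 1000,
                 rate_hz = rate_hz, stage = stage),
            class = "trf_waveform")
}

#' @export
print.trf_waveform <- function(x, ...) {
  cat(sprintf("<trf_waveform> stage %s: lags %.1f..%.1f ms at %g Hz (%d samples)\n",
              x$stage, min(x$lag_ms), max(x$lag_ms), x$rate_hz, length(x$coef)))
  invisible(x)
}

# Crop a waveform to a lag window in ms (inclusive on the sample grid).
window_waveform <- function(w, lo_ms, hi_ms) {
  keep <- w$lag_ms >= lo_ms - 1e-9 & w$lag_ms <= hi_ms + 1e-9
  trf_waveform(w$coef[keep], w$lag_samples[keep], w$rate_hz, w$stage)
}

extract_series <- function(x) {
  if (inherits(x, "predictor") || inherits(x, "eeg_trial") ||
      inherits(x, "audio_stimulus")) return(x$samples)
  as.numeric(x)
}

as_trial_list <- function(x) {
  if (inherits(x, "eeg_session")) return(lapply(x$trials, function(t) t$samples))
  if (inherits(x, c("predictor", "eeg_trial", "audio_stimulus"))) {
    return(list(x$samples))
  }
  if (is.list(x)) return(lapply(x, extract_series))
  list(as.numeric(x))
}

#' Inverse-variance trial weights
#'
#' `w_i = (1 / var_i) / sum_j (1 / var_j)`: noisy (high-variance) trials are
#' down-weighted; the weights sum to one.
#'
#' @param trials an [eeg_session()], list of [eeg_trial()]s or list of
#'   numeric series.
#' @return object of class `trial_weights` (numeric vector `w`).
#' @export
trial_weights <- function(trials) {
  ys <- as_trial_list(trials)
  v <- vapply(ys, stats::var, numeric(1))
  if (any(v == 0)) stop("zero-variance trial")
  w <- (1 / v) / sum(1 / v)
  structure(list(w = w), class = "trial_weights")
}

#' @export
print.trial_weights <- function(x, ...) {
  cat("<trial_weights>", format(x$w, digits = 4), "\n")
  invisible(x)
}

as_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1 / n, n))
  w <- if (inherits(weights, "trial_weights")) weights$w else as.numeric(weights)
  if (length(w) != n) stop("weights length mismatch")
  if (any(w < 0)) stop("negative weight")
  w
}

# Ascending circular lag axis for length n: IFFT index k maps to lag k for
# k <= n/2 and k - n beyond.
lag_axis <- function(n) {
  k <- 0:(n - 1)
  lag <- ifelse(k <= n / 2, k, k - n)
  lag
}

#' Estimate a raw TRF by frequency-domain deconvolution
#'
#' Implements the weighted cross-spectral estimator: numerator
#' `sum_i w_i conj(F{x_i}) F{y_i}`, denominator
#' `(1/N) sum_i conj(F{x_i}) F{x_i}` (with a small numerical floor), inverse
#' transformed and reordered to circular lags from `-T/2` to `T/2`. No
#' regularization is applied.
#'
#' @param x predictors: a [predictor()], numeric vector or list of either
#'   (one per trial).
#' @param y EEG: an [eeg_session()], [eeg_trial()], numeric vector or list
#'   (one per trial, lengths matching `x`).
#' @param weights a [trial_weights()] object or numeric vector summing to 1;
#'   uniform `1/N` when `NULL`.
#' @param rate_hz sampling rate of predictors and EEG.
#' @param eps_rel denominator floor, relative to the mean denominator.
#' @return a full-length `"raw"` [trf_waveform()].
#' @export
estimate_trf <- function(x, y, weights = NULL, rate_hz = 4096,
                         eps_rel = 1e-10) {
  xs <- as_trial_list(x)
  ys <- as_trial_list(y)
  if (length(xs) != length(ys)) stop("x and y trial counts differ")
  n <- length(xs[[1]])
  if (any(vapply(xs, length, numeric(1)) != n) ||
      any(vapply(ys, length, numeric(1)) != n))
    stop("per-trial length mismatch")
  if (all(vapply(xs, function(v) all(v == 0), logical(1))))
    stop("all-zero predictor")
  N <- length(xs)
  w <- as_weights(weights, N)
  num <- complex(length.out = n)
  den <- numeric(n)
  for (i in seq_len(N)) {
    Fx <- stats::fft(xs[[i]])
    Fy <- stats::fft(ys[[i]])
    num <- num + w[i] * Conj(Fx) * Fy
    den <- den + Mod(Fx)^2 / N
  }
  den <- den + eps_rel * mean(den)
  h <- Re(stats::fft(num / den, inverse = TRUE)) / n
  lag <- lag_axis(n)
  ord <- order(lag)
  trf_waveform(h[ord], lag[ord], rate_hz, "raw")
}

#' Average the TRFs of a polarity pair
#'
#' @param trf_pos,trf_neg [trf_waveform()]s on identical lag axes.
#' @return their sample-wise mean.
#' @export
combine_polarity_trfs <- function(trf_pos, trf_neg) {
  if (!identical(trf_pos$lag_samples, trf_neg$lag_samples) ||
      trf_pos$rate_hz != trf_neg$rate_hz)
    stop("lag axis mismatch")
  trf_waveform((trf_pos$coef + trf_neg$coef) / 2, trf_pos$lag_samples,
               trf_pos$rate_hz, trf_pos$stage)
}

# Unit-sum symmetric Hamming smoothing window of the given width.
smoothing_window <- function(width_ms, rate_hz) {
  m <- 2 * floor(width_ms * rate_hz / 1000 / 2) + 1
  w <- hamming_win(m)
  w / sum(w)
}

#' Post-process a raw TRF
#'
#' Applies, in order: a delay-compensated linear-phase FIR bandpass
#' (default 30-1000 Hz, about one second of taps), smoothing with a
#' unit-sum Hamming window (default 2 ms wide, nearest odd sample count),
#' extraction of the lag segment (default -10..30 ms) and subtraction of
#' the baseline mean (default over -10..0 ms). The filtered-and-smoothed
#' waveform over `processed_window_ms` (which the wave V noise estimate
#' needs) is attached as attribute `"processed"`.
#'
#' @param trf a `"raw"` [trf_waveform()] from [estimate_trf()].
#' @param band_hz bandpass edges in Hz.
#' @param smooth_ms Hamming smoothing width in ms.
#' @param extract_ms extracted lag window in ms.
#' @param baseline_ms baseline lag window in ms (half-open: lag < upper edge).
#' @param processed_window_ms lag window retained for the processed stage.
#' @param fir_taps bandpass FIR length (odd); default about one second.
#' @return the extracted, baselined [trf_waveform()] with attribute
#'   `"processed"`.
#' @export
postprocess_trf <- function(trf, band_hz = c(30, 1000), smooth_ms = 2,
                            extract_ms = c(-10, 30), baseline_ms = c(-10, 0),
                            processed_window_ms = c(-510, 40),
                            fir_taps = NULL) {
  span_ms <- diff(range(trf$lag_ms))
  if (span_ms < 80) stop("TRF span shorter than 80 ms")
  rate <- trf$rate_hz
  if (is.null(fir_taps)) fir_taps <- 2 * floor(rate / 2) + 1
  half_ms <- (fir_taps - 1) / 2 / rate * 1000
  lo <- max(min(trf$lag_ms), processed_window_ms[1] - half_ms - 10)
  hi <- min(max(trf$lag_ms), processed_window_ms[2] + half_ms + 10)
  w <- window_waveform(trf, lo, hi)
  key <- sprintf("bp_%g_%g_%g_%d", band_hz[1], band_hz[2], rate, fir_taps)
  h <- cache_get(key, function()
    design_bandpass_fir(band_hz[1], band_hz[2], rate, fir_taps))
  cf <- fir_filter_zerophase(w$coef, h)
  sw <- smoothing_window(smooth_ms, rate)
  cf <- fir_filter_zerophase(cf, sw)
  proc <- trf_waveform(cf, w$lag_samples, rate, "smoothed")
  proc <- window_waveform(proc, max(lo, processed_window_ms[1]),
                          min(hi, processed_window_ms[2]))
  ext <- window_waveform(proc, extract_ms[1], extract_ms[2])
  base <- ext$lag_ms >= baseline_ms[1] - 1e-9 & ext$lag_ms < baseline_ms[2]
  out <- trf_waveform(ext$coef - mean(ext$coef[base]), ext$lag_samples,
                      rate, "baselined")
  attr(out, "processed") <- proc
  out
}

#' Fit a subcortical temporal response function
#'
#' The central model-fitting function. Takes per-trial predictor pairs (or
#' single-polarity predictors) and EEG trials, computes inverse-variance
#' trial weights, estimates one TRF per stimulus polarity by unregularized
#' frequency-domain deconvolution, averages the pair, and post-processes
#' (30-1000 Hz bandpass, 2 ms Hamming smoothing, -10..30 ms extraction,
#' baseline subtraction). Returns a fitted-model object with the usual
#' methods (`print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#' `fitted`, `simulate`).
#'
#' @param x a [predictor_pair()] or list of them (one per trial), or
#'   single-polarity predictors (a [predictor()], numeric vector or list).
#' @param y an [eeg_session()], [eeg_trial()], numeric vector or list of
#'   per-trial series.
#' @param weights trial weights; computed from the EEG trial variances when
#'   `NULL` and more than one trial is given.
#' @param rate_hz sampling rate (taken from `x`/`y` objects when available).
#' @param keep_data store the training data in the object (enables
#'   `residuals()`, `fitted()` and data-free `predict()`).
#' @param ... post-processing arguments passed to [postprocess_trf()].
#' @return an object of class `trf`.
#' @export
trf <- function(x, y, weights = NULL, rate_hz = NULL, keep_data = FALSE, ...) {
  cl <- match.call()
  if (inherits(x, "predictor_pair")) x <- list(x)
  paired <- is.list(x) && length(x) > 0 && inherits(x[[1]], "predictor_pair")
  if (is.null(rate_hz)) {
    rate_hz <- if (paired) x[[1]]$positive$rate_hz
    else if (inherits(y, "eeg_session")) y$rate_hz
    else if (inherits(x, "predictor")) x$rate_hz
    else 4096
  }
  ys <- as_trial_list(y)
  if (is.null(weights) && length(ys) > 1) weights <- trial_weights(ys)
  w <- as_weights(weights, length(ys))
  if (paired) {
    kind <- x[[1]]$kind
    xp <- lapply(x, function(p) p$positive$samples)
    xn <- lapply(x, function(p) p$negative$samples)
    raw_p <- estimate_trf(xp, ys, w, rate_hz)
    raw_n <- estimate_trf(xn, ys, w, rate_hz)
    raw <- combine_polarity_trfs(raw_p, raw_n)
  } else {
    kind <- if (inherits(x, "predictor")) x$kind
    else if (is.list(x) && inherits(x[[1]], "predictor")) x[[1]]$kind
    else "EXTERNAL"
    raw <- estimate_trf(x, ys, w, rate_hz)
  }
  ext <- postprocess_trf(raw, ...)
  wv <- tryCatch(wave_v_metrics(attr(ext, "processed")), error = function(e) NULL)
  obj <- structure(list(
    coefficients = ext$coef,
    lag_ms = ext$lag_ms,
    lag_samples = ext$lag_samples,
    extracted = ext,
    processed = attr(ext, "processed"),
    wave_v = wv,
    weights = w,
    rate_hz = rate_hz,
    kind = kind,
    n_trials = length(ys),
    trial_samples = length(ys[[1]]),
    call = cl
  ), class = "trf")
  if (keep_data) {
    obj$x <- x
    obj$y <- ys
  }
  obj
}

#' @export
print.trf <- function(x, ...) {
  cat(sprintf("Subcortical TRF (%s predictor), %d trial%s of %.1f s at %g Hz\n",
              x$kind, x$n_trials, if (x$n_trials == 1) "" else "s",
              x$trial_samples / x$rate_hz, x$rate_hz))
  if (!is.null(x$wave_v)) {
    cat(sprintf("  wave V: %.2f ms, amplitude %.4g, SNR %.2f dB (%s)\n",
                x$wave_v$latency_ms, x$wave_v$amplitude, x$wave_v$snr_db,
                if (x$wave_v$detected) "detected" else "not detected"))
  }
  invisible(x)
}

#' @export
summary.trf <- function(object, ...) {
  structure(list(
    kind = object$kind, n_trials = object$n_trials,
    minutes = object$n_trials * object$trial_samples / object$rate_hz / 60,
    weights = object$weights, wave_v = object$wave_v,
    lag_range_ms = range(object$lag_ms),
    coef_range = range(object$coefficients)
  ), class = "summary.trf")
}

#' @export
print.summary.trf <- function(x, ...) {
  cat(sprintf("Subcortical TRF summary (%s predictor)\n", x$kind))
  cat(sprintf("  data: %d trials, %.1f minutes\n", x$n_trials, x$minutes))
  cat("  trial weights:", format(x$weights, digits = 3), "\n")
  cat(sprintf("  extracted lags: %.1f..%.1f ms\n",
              x$lag_range_ms[1], x$lag_range_ms[2]))
  if (!is.null(x$wave_v)) {
    cat(sprintf("  wave V latency : %.2f ms\n", x$wave_v$latency_ms))
    cat(sprintf("  wave V amplitude: %.4g (arbitrary units)\n", x$wave_v$amplitude))
    cat(sprintf("  wave V SNR     : %.2f dB (threshold 3 dB: %s)\n",
                x$wave_v$snr_db,
                if (x$wave_v$detected) "detected" else "not detected"))
  }
  invisible(x)
}

#' @export
coef.trf <- function(object, ...) {
  stats::setNames(object$coefficients, sprintf("%.3fms", object$lag_ms))
}

# Circular convolution of an extracted TRF with a predictor series; returns
# the predicted series plus the index range unaffected by circular wrap.
convolve_trf <- function(coef, lag_samples, x) {
  n <- length(x)
  g <- numeric(n)
  g[(lag_samples %% n) + 1] <- coef
  pred <- Re(stats::fft(stats::fft(g) * stats::fft(x), inverse = TRUE)) / n
  lo <- max(lag_samples); hi <- min(lag_samples)
  valid <- c(max(1, lo + 1), min(n, n + min(hi, 0)))
  list(pred = pred, valid = valid)
}

#' Predict EEG from a fitted TRF
#'
#' Convolves the extracted TRF with a predictor (the mean of a polarity
#' pair, or a single predictor series).
#'
#' @param object a fitted [trf()] model.
#' @param newdata a [predictor_pair()], [predictor()] or numeric series.
#' @param ... unused.
#' @return numeric predicted series with attribute `"valid"`, the index
#'   range free of circular edge effects.
#' @export
predict.trf <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "predictor_pair")) pair_mean(newdata)
  else extract_series(newdata)
  cv <- convolve_trf(object$coefficients, object$lag_samples, x)
  structure(cv$pred, valid = cv$valid)
}

#' @export
fitted.trf <- function(object, ...) {
  if (is.null(object$x)) stop("refit with keep_data = TRUE to use fitted()")
  lapply(object$x, function(p) as.numeric(predict(object, p)))
}

#' @export
residuals.trf <- function(object, ...) {
  f <- fitted(object)
  Map(function(y, p) y - p, object$y, f)
}

#' Simulate EEG trials from a fitted TRF
#'
#' Generates `nsim` trials as the TRF prediction for a predictor plus white
#' Gaussian noise.
#'
#' @param object a fitted [trf()] model.
#' @param nsim number of trials.
#' @param seed optional integer seed.
#' @param newdata predictor ([predictor_pair()], [predictor()] or numeric);
#'   defaults to the first stored training predictor.
#' @param sigma noise standard deviation; defaults to the residual SD of the
#'   stored training data.
#' @param ... unused.
#' @return list of simulated numeric trials.
#' @export
simulate.trf <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                         sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) {
    if (is.null(object$x)) stop("supply newdata or refit with keep_data = TRUE")
    newdata <- object$x[[1]]
  }
  mu <- as.numeric(predict(object, newdata))
  if (is.null(sigma)) {
    if (is.null(object$x)) stop("supply sigma or refit with keep_data = TRUE")
    sigma <- stats::sd(unlist(residuals(object)))
  }
  lapply(seq_len(nsim), function(i) mu + stats::rnorm(length(mu), 0, sigma))
}

#' Plot a fitted TRF
#'
#' Draws the extracted TRF with the detected wave V peak marked, and
#' optionally the processed waveform over its full lag window.
#'
#' @param x a fitted [trf()] model.
#' @param full also show the processed (pre-extraction) waveform.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trf <- function(x, full = FALSE, ...) {
  if (full) {
    graphics::plot(x$processed$lag_ms, x$processed$coef, type = "l",
                   xlab = "lag (ms)", ylab = "TRF (a.u.)",
                   main = sprintf("TRF (%s)", x$kind), ...)
  } else {
    graphics::plot(x$lag_ms, x$coefficients, type = "l",
                   xlab = "lag (ms)", ylab = "TRF (a.u.)",
                   main = sprintf("TRF (%s)", x$kind), ...)
  }
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(x$wave_v)) {
    graphics::abline(v = x$wave_v$latency_ms, col = "red", lty = 2)
    graphics::mtext(sprintf("wave V %.2f ms, %.1f dB", x$wave_v$latency_ms,
                            x$wave_v$snr_db), side = 3, line = 0.2, cex = 0.8)
  }
  invisible(x)
}
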