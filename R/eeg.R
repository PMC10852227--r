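# Single-channel EEG preprocessing: 1 Hz first-order highpass, FIR notches
# at all multiples of 50 Hz up to 1000 Hz (5 Hz wide), anti-aliased
# downsampling to 4096 Hz, +/-5 SD artifact zeroing, 2-242 s trimming.

#' EEG trial container
#'
#' @param samples microvolt series.
#' @param rate_hz sampling rate.
#' @param trial_index 1-based presentation index.
#' @param weight inverse-variance trial weight (filled by the TRF stage).
#' @param zeroed_mask logical mask of artifact-zeroed samples.
#' @return object of class `eeg_trial`.
#' @export
eeg_trial <- function(samples, rate_hz, trial_index = 1L, weight = NA_real_,
                      zeroed_mask = NULL) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("non-finite EEG samples")
  structure(list(samples = samples, rate_hz = rate_hz,
                 trial_index = as.integer(trial_index), weight = weight,
                 zeroed_mask = zeroed_mask %||% rep(FALSE, length(samples))),
            class = "eeg_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> #%d: %.2f s at %g Hz, sd %.3g uV, %.2f%% zeroed\n",
              x$trial_index, length(x$samples) / x$rate_hz, x$rate_hz,
              stats::sd(x$samples), 100 * mean(x$zeroed_mask)))
  invisible(x)
}

#' EEG session container
#'
#' An ordered list of preprocessed trials at a common rate, presentation
#' order preserved.
#'
#' @param trials list of [eeg_trial()] objects.
#' @param participant_id identifier.
#' @return object of class `eeg_session`.
#' @export
eeg_session <- function(trials, participant_id = "P01") {
  rates <- vapply(trials, function(t) t$rate_hz, numeric(1))
  if (length(unique(rates)) != 1) stop("trials must share a sampling rate")
  lens <- vapply(trials, function(t) length(t$samples), numeric(1))
  if (length(unique(lens)) != 1) stop("trials must share a length")
  structure(list(trials = trials, participant_id = participant_id,
                 rate_hz = rates[1]),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %s: %d trials of %.1f s at %g Hz\n",
              x$participant_id, length(x$trials),
              length(x$trials[[1]]$samples) / x$rate_hz, x$rate_hz))
  invisible(x)
}

#' Preprocess a raw EEG trial
#'
#' Applies, in order: a causal first-order Butterworth highpass (default
#' 1 Hz), linear-phase FIR notch filters at all multiples of 50 Hz up to
#' 1000 Hz (each 5 Hz wide, delay compensated), and anti-aliased resampling
#' to the target rate (default 4096 Hz). For long signals the notch bank is
#' applied in the frequency domain as multiplication by the FIR's
#' delay-compensated transfer function.
#'
#' @param raw numeric series (already referenced, e.g. Cz minus mastoid
#'   average).
#' @param rate_in_hz input rate; must be at least 8192 Hz.
#' @param rate_out_hz output rate (default 4096).
#' @param highpass_hz highpass cutoff.
#' @param line_hz power-line fundamental (notches at its multiples up to
#'   `notch_max_hz`).
#' @param notch_max_hz highest notch centre.
#' @param notch_width_hz full notch width.
#' @param trial_index stored trial index.
#' @return an [eeg_trial()] at `rate_out_hz`.
#' @export
preprocess_eeg <- function(raw, rate_in_hz, rate_out_hz = 4096,
                           highpass_hz = 1, line_hz = 50, notch_max_hz = 1000,
                           notch_width_hz = 5, trial_index = 1L) {
  if (rate_in_hz < 8192) stop("input rate must be at least 8192 Hz")
  x <- as.numeric(raw)
  x <- butter1_filter(x, highpass_hz, rate_in_hz, "high")
  freqs <- seq(line_hz, notch_max_hz, by = line_hz)
  key <- sprintf("notchfir_%g_%g_%g_%g", rate_in_hz, line_hz, notch_max_hz,
                 notch_width_hz)
  h <- cache_get(key, function()
    design_notch_fir(rate_in_hz, freqs, notch_width_hz))
  n <- length(x)
  n_out <- round(n * rate_out_hz / rate_in_hz)
  if (n >= 2 * length(h)) {
    # frequency-domain application of the delay-compensated FIR, fused
    # with the resampling spectrum truncation (one FFT pair per trial)
    rkey <- sprintf("%s_resp_%d", key, n)
    H <- cache_get(rkey, function() fir_zerophase_response(h, n))
    y <- resample_spectrum(stats::fft(x) * H, n, n_out)
  } else {
    x <- fir_filter_zerophase(x, h)
    y <- resample_fft(x, rate_in_hz, rate_out_hz)
  }
  eeg_trial(y, rate_out_hz, trial_index = trial_index)
}

#' Zero out high-amplitude artifact segments
#'
#' Samples deviating from the trial mean by more than `threshold_sd`
#' standard deviations (two-sided by default; the SD is computed once,
#' before any zeroing) have a window of `window_s` seconds centred on them
#' set to zero. Overlapping windows merge. The zeroed-sample mask is stored
#' on the trial.
#'
#' @param trial an [eeg_trial()].
#' @param threshold_sd threshold in standard deviations (default 5).
#' @param window_s zeroed window length in seconds (default 1).
#' @param two_sided if `FALSE`, only positive deviations trigger zeroing.
#' @return the trial with artifacts zeroed and `zeroed_mask` filled.
#' @export
suppress_artifacts <- function(trial, threshold_sd = 5, window_s = 1,
                               two_sided = TRUE) {
  x <- trial$samples
  mu <- mean(x); sdv <- stats::sd(x)
  if (sdv == 0) return(trial)   # zero-variance trial: documented no-op
  dev <- if (two_sided) abs(x - mu) else x - mu
  bad <- which(dev > threshold_sd * sdv)
  if (length(bad) == 0) return(trial)
  half <- round(window_s * trial$rate_hz / 2)
  mask <- rep(FALSE, length(x))
  for (i in bad) {
    mask[max(1, i - half):min(length(x), i + half)] <- TRUE
  }
  x[mask] <- 0
  eeg_trial(x, trial$rate_hz, trial$trial_index, trial$weight, mask)
}

#' Trim a trial to its analysis window
#'
#' Keeps the segment from `start_s` to `end_s` seconds (default 2-242 s,
#' i.e. 240 s of data), discarding onset effects and equalizing trial
#' lengths.
#'
#' @param trial an [eeg_trial()].
#' @param start_s,end_s window in seconds from trial onset.
#' @return the trimmed [eeg_trial()].
#' @export
trim_trial <- function(trial, start_s = 2, end_s = 242) {
  n <- length(trial$samples)
  i0 <- round(start_s * trial$rate_hz) + 1
  i1 <- round(end_s * trial$rate_hz)
  if (i1 > n) stop("trial shorter than the requested end time")
  eeg_trial(trial$samples[i0:i1], trial$rate_hz, trial$trial_index,
            trial$weight, trial$zeroed_mask[i0:i1])
}

# Trim a predictor (or bare numeric) to the same analysis window.
trim_samples <- function(x, rate_hz, start_s = 2, end_s = 242) {
  n <- length(x)
  i0 <- round(start_s * rate_hz) + 1
  i1 <- round(end_s * rate_hz)
  if (i1 > n) stop("series shorter than the requested end time")
  x[i0:i1]
}
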