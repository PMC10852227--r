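# Model evaluation: wave V peak metrics, leave-one-out cross-validated
# prediction correlations across data lengths, and circular-shift null
# models that estimate the chance level of the prediction correlation.

#' Wave V peak metrics
#'
#' Detects the wave V peak as the global maximum of the TRF between 5 and
#' 10 ms (ties broken by the earliest latency), computes the signal power S
#' as the mean square in a 5 ms window centred on the peak, the noise power
#' N as the average of per-window mean squares over contiguous,
#' non-overlapping 5 ms windows tiling -500..-20 ms, and the SNR as
#' `10 log10(S/N)`, floored at 0 dB. A peak is "detected" at 3 dB or more
#' (signal power at least twice the noise power). The noise estimate needs
#' the filtered-and-smoothed TRF *before* the -10..30 ms extraction; pass a
#' fitted [trf()] (its processed waveform is used) or a [trf_waveform()]
#' covering the noise range.
#'
#' @param x a fitted [trf()] or a [trf_waveform()] spanning at least
#'   `noise_range_ms[1]` to `peak_ms[2]`.
#' @param peak_ms peak search window in ms.
#' @param signal_width_ms width of the signal window centred on the peak.
#' @param noise_range_ms lag range tiled by noise windows.
#' @param noise_win_ms noise window width.
#' @param floor_db SNR floor in dB.
#' @param detect_db detection threshold in dB.
#' @return object of class `wave_v_result` with fields `latency_ms`,
#'   `amplitude`, `snr_db` (floored), `snr_raw_db`, `detected`.
#' @export
wave_v_metrics <- function(x, peak_ms = c(5, 10), signal_width_ms = 5,
                           noise_range_ms = c(-500, -20), noise_win_ms = 5,
                           floor_db = 0, detect_db = 3) {
  w <- if (inherits(x, "trf")) x$processed else x
  stopifnot(inherits(w, "trf_waveform"))
  if (min(w$lag_ms) > noise_range_ms[1] + 1e-9 ||
      max(w$lag_ms) < peak_ms[2] - 1e-9)
    stop("waveform does not cover the noise range and peak window")
  lag <- w$lag_ms; cf <- w$coef
  in_peak <- lag >= peak_ms[1] - 1e-9 & lag <= peak_ms[2] + 1e-9
  ip <- which(in_peak)[which.max(cf[in_peak])]
  latency <- lag[ip]; amplitude <- cf[ip]
  half <- signal_width_ms / 2
  sig <- lag >= latency - half - 1e-9 & lag <= latency + half + 1e-9
  S <- mean(cf[sig]^2)
  edges <- seq(noise_range_ms[1], noise_range_ms[2], by = noise_win_ms)
  pw <- vapply(seq_len(length(edges) - 1), function(j) {
    m <- lag >= edges[j] - 1e-9 & lag < edges[j + 1] - 1e-9
    mean(cf[m]^2)
  }, numeric(1))
  N <- mean(pw)
  if (!is.finite(N) || N == 0) stop("degenerate input: zero noise power")
  raw <- 10 * log10(S / N)
  snr <- max(floor_db, raw)
  structure(list(latency_ms = latency, amplitude = amplitude, snr_db = snr,
                 snr_raw_db = raw, detected = snr >= detect_db),
            class = "wave_v_result")
}

#' @export
print.wave_v_result <- function(x, ...) {
  cat(sprintf("<wave_v> %.2f ms, amplitude %.4g, SNR %.2f dB, %s\n",
              x$latency_ms, x$amplitude, x$snr_db,
              if (x$detected) "detected" else "not detected"))
  invisible(x)
}

#' Prediction correlation on a held-out trial
#'
#' Convolves the extracted TRF with the polarity-averaged predictor and
#' correlates the prediction with the test EEG, dropping edge samples
#' without full kernel support.
#'
#' @param object a fitted [trf()].
#' @param pair the test trial's [predictor_pair()] (or a single predictor /
#'   numeric series).
#' @param test the test [eeg_trial()] or numeric series.
#' @return Pearson correlation (scalar).
#' @export
predict_and_score <- function(object, pair, test) {
  y <- extract_series(test)
  if (stats::sd(y) == 0) stop("constant test trial: correlation undefined")
  pred <- predict(object, pair)
  v <- attr(pred, "valid")
  idx <- v[1]:v[2]
  stats::cor(as.numeric(pred)[idx], y[idx])
}

# ---- internal fast evaluation engine -------------------------------------
#
# Real signals have Hermitian spectra, so all per-trial cross/auto spectra
# are stored on the non-negative-frequency half grid (n/2 + 1 bins, n
# even). Train/test splits reduce to subtracting one trial's contribution
# from running sums; circular predictor shifts become spectral phase
# ramps. One inverse FFT per fold recovers the raw TRF.

session_spectra <- function(pairs, trials, rate_hz) {
  ys <- as_trial_list(trials)
  N <- length(ys)
  stopifnot(length(pairs) == N)
  n <- length(ys[[1]])
  stopifnot(n %% 2 == 0)
  nh <- n / 2 + 1
  out <- vector("list", N)
  for (i in seq_len(N)) {
    xp <- pairs[[i]]$positive$samples
    xn <- pairs[[i]]$negative$samples
    stopifnot(length(xp) == n, length(ys[[i]]) == n)
    Fxp <- stats::fft(xp)[1:nh]
    Fxn <- stats::fft(xn)[1:nh]
    Fy <- stats::fft(ys[[i]])[1:nh]
    v <- stats::var(ys[[i]])
    if (v == 0) stop("zero-variance trial")
    out[[i]] <- list(
      crossp = Conj(Fxp) * Fy, crossn = Conj(Fxn) * Fy,
      autop = Mod(Fxp)^2, auton = Mod(Fxn)^2,
      Fxa = (Fxp + Fxn) / 2,
      # full-spectrum sums of the auto spectra (Parseval), for the
      # denominator floor
      sum_autop = n * sum(xp^2), sum_auton = n * sum(xn^2),
      iv = 1 / v, y = ys[[i]]
    )
  }
  list(trials = out, n = n, nh = nh, rate_hz = rate_hz)
}

# Hermitian mirror of a half spectrum back to the full grid (n even).
mirror_half <- function(h, n) {
  c(h, Conj(h[seq(n / 2, 2)]))
}

# Phase ramp (half grid) implementing a circular delay of `shift` samples.
shift_ramp_half <- function(n, shift) {
  exp(-2i * pi * (0:(n / 2)) * shift / n)
}

half_ratio_to_raw <- function(ratio, n, rate_hz) {
  full <- mirror_half(ratio, n)
  h <- Re(stats::fft(full, inverse = TRUE)) / n
  lag <- lag_axis(n)
  ord <- order(lag)
  trf_waveform(h[ord], lag[ord], rate_hz, "raw")
}

# Prediction correlation of an extracted fold TRF on one held-out trial.
score_heldout <- function(ext, trial, n, ramp = NULL) {
  Fxa <- if (is.null(ramp)) trial$Fxa else trial$Fxa * ramp
  g <- numeric(n)
  g[(ext$lag_samples %% n) + 1] <- ext$coef
  G <- stats::fft(g)[1:(n / 2 + 1)]
  pred <- Re(stats::fft(mirror_half(Fxa * G, n), inverse = TRUE)) / n
  lo <- max(ext$lag_samples); hi <- min(ext$lag_samples)
  idx <- (max(1, lo + 1)):(n + min(hi, 0))
  stats::cor(pred[idx], trial$y[idx])
}

# Leave-one-out engine shared by loo_evaluate() and null_model_score().
loo_engine <- function(sp, lengths, score = TRUE, shifts_s = NULL,
                       eps_rel = 1e-10, ...) {
  n <- sp$n; nh <- sp$nh
  lengths <- sort(unique(lengths))
  if (max(lengths) > length(sp$trials)) stop("not enough trials")
  ramps <- lapply(shifts_s, function(s) {
    shift <- round(s * sp$rate_hz)
    if (shift >= n) stop("shift exceeds trial length")
    shift_ramp_half(n, shift)
  })
  Up <- Un <- complex(length.out = nh)
  Dp <- Dn <- numeric(nh)
  Siv <- 0; sump <- 0; sumn <- 0
  m_cur <- 0
  rows <- vector("list", length(lengths))
  trfs <- vector("list", length(lengths))
  trial_s <- n / sp$rate_hz
  for (li in seq_along(lengths)) {
    m <- lengths[li]
    while (m_cur < m) {
      i <- m_cur + 1
      t <- sp$trials[[i]]
      Up <- Up + t$iv * t$crossp
      Un <- Un + t$iv * t$crossn
      Dp <- Dp + t$autop
      Dn <- Dn + t$auton
      Siv <- Siv + t$iv
      sump <- sump + t$sum_autop
      sumn <- sumn + t$sum_auton
      m_cur <- i
    }
    ratio_sum <- complex(length.out = nh)
    rs <- rep(NA_real_, m)
    null_rs <- c()
    for (j in seq_len(m)) {
      t <- sp$trials[[j]]
      a <- Siv - t$iv
      nump <- (Up - t$iv * t$crossp) / a
      numn <- (Un - t$iv * t$crossn) / a
      denp <- (Dp - t$autop) / (m - 1)
      denn <- (Dn - t$auton) / (m - 1)
      ep <- eps_rel * (sump - t$sum_autop) / (m - 1) / n
      en <- eps_rel * (sumn - t$sum_auton) / (m - 1) / n
      ratio <- 0.5 * (nump / (denp + ep) + numn / (denn + en))
      ratio_sum <- ratio_sum + ratio / m
      if (score) {
        ext <- postprocess_trf(half_ratio_to_raw(ratio, n, sp$rate_hz), ...)
        rs[j] <- score_heldout(ext, t, n)
      }
      for (ramp in ramps) {
        # shifting the predictors phase-ramps the ratio spectrum
        rsh <- Conj(ramp) * ratio
        ext <- postprocess_trf(half_ratio_to_raw(rsh, n, sp$rate_hz), ...)
        null_rs <- c(null_rs, score_heldout(ext, t, n, ramp))
      }
    }
    ext_avg <- postprocess_trf(half_ratio_to_raw(ratio_sum, n, sp$rate_hz), ...)
    # wave V needs the -500..-20 ms noise range; unavailable for very
    # short trials
    wv <- tryCatch(wave_v_metrics(attr(ext_avg, "processed")),
                   error = function(e) NULL)
    rows[[li]] <- data.frame(
      n_trials = m, minutes = m * trial_s / 60,
      prediction_r = mean(rs),
      null_r = if (length(null_rs)) mean(null_rs) else NA_real_,
      snr_db = if (is.null(wv)) NA_real_ else wv$snr_db,
      latency_ms = if (is.null(wv)) NA_real_ else wv$latency_ms,
      amplitude = if (is.null(wv)) NA_real_ else wv$amplitude,
      detected = if (is.null(wv)) NA else wv$detected
    )
    trfs[[li]] <- ext_avg
  }
  out <- do.call(rbind, rows)
  attr(out, "trfs") <- trfs
  out
}

# ---- public evaluation --------------------------------------------------

#' Leave-one-out evaluation over increasing data lengths
#'
#' For each requested number of trials `m` (taken in presentation order),
#' runs `m` cross-validation folds: the TRF is fitted on `m - 1` trials
#' (inverse-variance weights renormalized over the training trials, both
#' polarities averaged) and the prediction correlation computed on the
#' held-out trial. The per-fold TRFs are averaged into the final TRF for
#' that data length, from which wave V metrics are taken.
#'
#' @param session an [eeg_session()] (preprocessed, trimmed trials).
#' @param pairs list of [predictor_pair()]s, one per trial.
#' @param lengths integer vector of trial counts (each at least 2).
#' @param score compute prediction correlations (adds one fold-TRF
#'   extraction per fold); wave V metrics are always computed.
#' @param shifts_s optional circular predictor shifts in seconds; when
#'   given, the same LOO procedure is additionally run with shifted
#'   predictors and the mean null correlation reported per length (column
#'   `null_r`).
#' @param ... post-processing arguments passed to [postprocess_trf()].
#' @return data.frame with one row per data length: `n_trials`, `minutes`,
#'   `prediction_r`, `null_r`, `snr_db`, `latency_ms`, `amplitude`,
#'   `detected`; the fold-averaged extracted TRFs are attached as attribute
#'   `"trfs"`.
#' @export
loo_evaluate <- function(session, pairs, lengths = 2:8, score = TRUE,
                         shifts_s = NULL, ...) {
  if (any(lengths < 2)) stop("each data length needs at least 2 trials")
  sp <- session_spectra(pairs, session, session$rate_hz)
  loo_engine(sp, lengths, score = score, shifts_s = shifts_s, ...)
}

#' Circular-shift null model score
#'
#' Reruns the leave-one-out evaluation with every predictor circularly
#' shifted (default shifts 30, 60 and 90 s), destroying stimulus-EEG
#' alignment while preserving the temporal structure of both, and returns
#' the mean prediction correlation over folds and shifts: an estimate of
#' the chance-level correlation.
#'
#' @param session an [eeg_session()].
#' @param pairs list of [predictor_pair()]s.
#' @param n_trials number of trials to use (in presentation order).
#' @param shifts_s circular shifts in seconds; each must be shorter than a
#'   trial.
#' @param ... post-processing arguments passed to [postprocess_trf()].
#' @return mean null prediction correlation (scalar).
#' @export
null_model_score <- function(session, pairs, n_trials = length(session$trials),
                             shifts_s = c(30, 60, 90), ...) {
  sp <- session_spectra(pairs, session, session$rate_hz)
  if (length(shifts_s) == 1 && shifts_s[1] == 0) {
    # zero shift: identical to the true-model score by construction
    out <- loo_engine(sp, n_trials, score = TRUE, shifts_s = NULL, ...)
    return(out$prediction_r)
  }
  out <- loo_engine(sp, n_trials, score = FALSE, shifts_s = shifts_s, ...)
  out$null_r
}
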