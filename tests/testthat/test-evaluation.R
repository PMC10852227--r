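# Evaluation: wave V metrics, prediction scoring, LOO structure, and the
# circular-shift null model.

test_that("wave V SNR identities hold on constructed waveforms", {
  # S exactly twice N -> 3.01 dB, detected
  w2 <- constructed_snr_waveform(2)
  wv <- wave_v_metrics(w2)
  expect_equal(wv$snr_db, 10 * log10(2), tolerance = 1e-6)
  expect_true(wv$detected)
  expect_equal(wv$latency_ms, 7, tolerance = 0.13)
  # S = N -> floored at 0, not detected
  w1 <- constructed_snr_waveform(1)
  wv1 <- wave_v_metrics(w1)
  expect_equal(wv1$snr_db, 0)
  expect_false(wv1$detected)
  # S = 10 N -> exactly 10 dB
  w10 <- constructed_snr_waveform(10)
  expect_equal(wave_v_metrics(w10)$snr_db, 10, tolerance = 1e-6)
})

test_that("wave V SNR is invariant to global scaling", {
  set.seed(22)
  rate <- 4096
  lag <- seq(round(-0.52 * rate), round(0.04 * rate))
  cf <- rnorm(length(lag))
  w <- trf_waveform(cf, lag, rate, "smoothed")
  w5 <- trf_waveform(5 * cf, lag, rate, "smoothed")
  expect_equal(wave_v_metrics(w)$snr_db, wave_v_metrics(w5)$snr_db,
               tolerance = 1e-12)
  expect_equal(wave_v_metrics(w)$latency_ms, wave_v_metrics(w5)$latency_ms)
})

test_that("wave V peak detection takes the earliest tied maximum", {
  rate <- 4096
  lag <- seq(round(-0.52 * rate), round(0.04 * rate))
  cf <- rep(0.1, length(lag))
  lag_ms <- lag / rate * 1000
  cf[which(lag_ms >= 5 & lag_ms <= 10)] <- 1   # flat plateau: tie
  w <- trf_waveform(cf, lag, rate, "smoothed")
  wv <- wave_v_metrics(w)
  expect_equal(wv$latency_ms, min(lag_ms[lag_ms >= 5]), tolerance = 1e-9)
  # degenerate all-zero waveform errors
  wz <- trf_waveform(rep(0, length(lag)), lag, rate, "smoothed")
  expect_error(wave_v_metrics(wz), "zero noise")
  # waveform not covering the noise range errors
  wshort <- trf_waveform(rnorm(200), -50:149, rate, "smoothed")
  expect_error(wave_v_metrics(wshort), "cover")
})

test_that("prediction scoring returns +-1 for exact and negated tests", {
  ws <- white_session(n_trials = 2, n = 8192, noise_sd = 0.05, seed = 23)
  fit <- trf(ws$pairs, ws$session)
  pred <- predict(fit, ws$pairs[[1]])
  v <- attr(pred, "valid")
  y_exact <- as.numeric(pred)
  expect_equal(predict_and_score(fit, ws$pairs[[1]], y_exact), 1,
               tolerance = 1e-9)
  expect_equal(predict_and_score(fit, ws$pairs[[1]], -y_exact), -1,
               tolerance = 1e-9)
  expect_error(predict_and_score(fit, ws$pairs[[1]], rep(1, 8192)),
               "constant")
})

test_that("noiseless sessions are predicted near perfectly", {
  # identifiable noiseless case: a narrowband kernel (processing response
  # nearly constant over its spectral support; prediction correlation is
  # scale invariant) and a generation drive equal to the fitted predictor
  set.seed(24)
  n <- 16384; rate <- 4096
  k <- as.numeric(gen_kernel(peak_ms = 7, width_ms = 8, rate_hz = rate))
  mk <- function() {
    x <- pmax(rnorm(n), 0); x <- x / sd(x)
    structure(list(positive = predictor(x, rate, "RS", "+"),
                   negative = predictor(x, rate, "RS", "-"), kind = "RS"),
              class = "predictor_pair")
  }
  pairs <- list(mk(), mk())
  K <- fft(c(k, numeric(n - length(k))))
  trials <- lapply(pairs, function(p) {
    y <- Re(fft(fft(p$positive$samples) * K, inverse = TRUE)) / n
    eeg_trial(y, rate)
  })
  fit <- trf(pairs[1], list(trials[[1]]))
  r <- predict_and_score(fit, pairs[[2]], trials[[2]])
  expect_gt(r, 0.99)
})

test_that("noiseless generation lets the estimator recover the kernel", {
  truth <- synthetic_truth(noise_scale = 0, line_amp = 0, artifact_rate = 0,
                           polarity = "positive")
  sim <- gen_session(n_trials = 1, trial_s = 30, truth = truth, seed = 31)
  # reconstruct the generation drive through the same public path
  prep <- preprocess_stimulus(sim$stimuli[[1]]$samples, sim$rate_hz)
  drive <- subtrf:::predictor_drive(prep, "RS", NULL, 1000)
  drive <- drive / sd(drive)
  est <- estimate_trf(drive, sim$eeg_raw[[1]], rate_hz = sim$rate_hz)
  k <- sim$truth$kernel
  keep <- est$lag_samples >= 0 & est$lag_samples < length(k)
  err <- sqrt(sum((est$coef[keep] - k)^2) / sum(k^2))
  expect_lt(err, 0.01)
})

test_that("LOO evaluation has the right fold structure and data mapping", {
  ws <- white_session(n_trials = 4, n = 16384, noise_sd = 0.5, seed = 25)
  ev <- loo_evaluate(ws$session, ws$pairs, lengths = 2:4)
  expect_equal(ev$n_trials, 2:4)
  expect_equal(ev$minutes, (2:4) * (16384 / 4096) / 60)
  expect_true(all(is.finite(ev$prediction_r)))
  # trfs attached per length
  expect_length(attr(ev, "trfs"), 3)
  expect_error(loo_evaluate(ws$session, ws$pairs, lengths = 1), "at least 2")
  expect_error(loo_evaluate(ws$session, ws$pairs, lengths = 5), "not enough")
})

test_that("a zero circular shift reproduces the true-model score", {
  ws <- white_session(n_trials = 3, n = 8192, noise_sd = 0.5, seed = 26)
  true_r <- loo_evaluate(ws$session, ws$pairs, lengths = 3)$prediction_r
  null0 <- null_model_score(ws$session, ws$pairs, n_trials = 3, shifts_s = 0)
  expect_equal(null0, true_r, tolerance = 1e-12)
  expect_error(null_model_score(ws$session, ws$pairs, 3, shifts_s = 10),
               "exceeds")
})

test_that("shifted predictors score near chance on synthetic data", {
  ws <- white_session(n_trials = 3, n = 16384, noise_sd = 0.3, seed = 27)
  nr <- null_model_score(ws$session, ws$pairs, n_trials = 3,
                         shifts_s = c(1, 2))
  expect_lt(abs(nr), 3 / sqrt(16384))
  true_r <- loo_evaluate(ws$session, ws$pairs, lengths = 3)$prediction_r
  expect_gt(true_r, 10 * abs(nr))
})

test_that("artifact suppression blanks generated artifact bursts", {
  truth <- synthetic_truth(artifact_rate = 2)
  sim <- gen_session(n_trials = 1, trial_s = 120, truth = truth, seed = 41)
  bursts <- sim$truth$artifact_log[[1]]
  expect_gt(length(bursts), 0)
  tr <- preprocess_eeg(sim$eeg_raw[[1]], sim$rate_hz)
  tr <- suppress_artifacts(tr)
  burst_idx <- unlist(lapply(bursts, function(b) {
    (round(b * 4096) + 1):(round((b + truth$artifact_dur_s) * 4096))
  }))
  burst_idx <- burst_idx[burst_idx <= length(tr$samples)]
  expect_gt(mean(tr$zeroed_mask[burst_idx]), 0.9)
})
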