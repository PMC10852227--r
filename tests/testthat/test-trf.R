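# TRF estimation: trial weights, the frequency-domain estimator against
# its circulant least-squares oracle, polarity averaging, post-processing,
# and the fitted-model methods.

test_that("trial weights are normalized reciprocal variances", {
  y1 <- rnorm(1000); y1 <- y1 / sd(y1)           # var 1
  y3 <- rnorm(1000); y3 <- y3 / sd(y3) * sqrt(3) # var 3
  w <- trial_weights(list(y1, y1))
  expect_equal(w$w, c(0.5, 0.5))
  w13 <- trial_weights(list(y1, y3))
  expect_equal(w13$w, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(sum(w13$w), 1, tolerance = 1e-12)
  expect_error(trial_weights(list(rep(1, 10))), "zero-variance")
})

test_that("a unit-impulse predictor returns the EEG on the lag axis", {
  n <- 64
  x <- c(1, numeric(n - 1))
  y <- rnorm(n)
  w <- estimate_trf(x, y, rate_hz = 4096)
  expect_equal(trf_index_order(w), y, tolerance = 1e-8)
  expect_true(0 %in% w$lag_samples)
  expect_equal(range(w$lag_samples), c(-(n / 2 - 1), n / 2))
})

test_that("a circular delay appears as an impulse at the matching lag", {
  set.seed(15)
  n <- 4096
  x <- rnorm(n)
  y <- subtrf:::circ_shift(x, 5)
  w <- estimate_trf(x, y, rate_hz = 4096)
  expect_equal(w$lag_samples[which.max(w$coef)], 5)
  expect_equal(max(w$coef), 1, tolerance = 1e-6)
  expect_lt(sort(abs(w$coef), decreasing = TRUE)[2], 1e-6)
})

test_that("the estimator matches the circulant weighted LS oracle", {
  set.seed(16)
  n <- 128
  for (N in 1:3) {
    xs <- lapply(seq_len(N), function(i) rnorm(n))
    ys <- lapply(seq_len(N), function(i) rnorm(n))
    w <- runif(N); w <- w / sum(w)
    est <- estimate_trf(xs, ys, w, 4096)
    oracle <- circulant_trf_oracle(xs, ys, w)
    expect_equal(trf_index_order(est), oracle, tolerance = 1e-8)
  }
})

test_that("the estimator is linear in the EEG and shift-covariant", {
  set.seed(17)
  n <- 1024
  x <- rnorm(n); y <- rnorm(n)
  w1 <- estimate_trf(x, y, rate_hz = 4096)
  w2 <- estimate_trf(x, 2.5 * y, rate_hz = 4096)
  expect_equal(w2$coef, 2.5 * w1$coef, tolerance = 1e-10)
  # delaying y by k shifts the TRF peak by k
  xk <- rnorm(n)
  yk <- subtrf:::circ_shift(xk, 3)
  wk <- estimate_trf(xk, yk, rate_hz = 4096)
  yk7 <- subtrf:::circ_shift(xk, 10)
  wk7 <- estimate_trf(xk, yk7, rate_hz = 4096)
  expect_equal(wk7$lag_samples[which.max(wk7$coef)] -
                 wk$lag_samples[which.max(wk$coef)], 7)
  # duplicated trials with equal weights equal the single-trial estimate
  wd <- estimate_trf(list(x, x), list(y, y), c(0.5, 0.5), 4096)
  ws <- estimate_trf(x, y, rate_hz = 4096)
  expect_equal(wd$coef, ws$coef, tolerance = 1e-10)
  expect_error(estimate_trf(list(x), list(y, y)), "counts differ")
  expect_error(estimate_trf(rep(0, n), y), "all-zero")
})

test_that("polarity TRFs combine by sample-wise averaging", {
  set.seed(18)
  a <- estimate_trf(rnorm(256), rnorm(256), rate_hz = 4096)
  b <- estimate_trf(rnorm(256), rnorm(256), rate_hz = 4096)
  avg <- combine_polarity_trfs(a, b)
  expect_equal(avg$coef, (a$coef + b$coef) / 2)
  expect_equal(combine_polarity_trfs(a, a)$coef, a$coef)
  neg <- trf_waveform(-a$coef, a$lag_samples, a$rate_hz, a$stage)
  expect_equal(combine_polarity_trfs(a, neg)$coef, rep(0, 256))
  short <- trf_waveform(a$coef[1:100], a$lag_samples[1:100], a$rate_hz)
  expect_error(combine_polarity_trfs(a, short), "mismatch")
})

test_that("post-processing baselines, smooths, and removes DC", {
  set.seed(19)
  rate <- 4096
  n <- 8192
  raw <- estimate_trf(rnorm(n), rnorm(n), rate_hz = rate)
  out <- postprocess_trf(raw)
  base <- out$lag_ms >= -10 & out$lag_ms < 0
  expect_equal(mean(out$coef[base]), 0, tolerance = 1e-12)
  expect_equal(range(out$lag_ms)[1], -10, tolerance = 0.25)
  expect_equal(range(out$lag_ms)[2], 30, tolerance = 0.25)
  # an impulse TRF at 7 ms keeps its peak at 7 ms after smoothing
  imp <- numeric(n)
  lag <- subtrf:::lag_axis(n); ord <- order(lag)
  wimp <- trf_waveform(imp[ord], lag[ord], rate, "raw")
  wimp$coef[which.min(abs(wimp$lag_ms - 7))] <- 1
  oimp <- postprocess_trf(wimp)
  expect_equal(oimp$lag_ms[which.max(oimp$coef)], 7, tolerance = 0.3)
  # constant TRF is annihilated by the bandpass (zero DC gain)
  wconst <- trf_waveform(rep(1, n), lag[ord], rate, "raw")
  oconst <- postprocess_trf(wconst)
  expect_lt(max(abs(oconst$coef)), 1e-3)
  # too short a TRF is rejected
  tiny <- trf_waveform(rnorm(64), -31:32, rate, "raw")
  expect_error(postprocess_trf(tiny), "80 ms")
})

test_that("the fitted-model object supports the standard methods", {
  ws <- white_session(n_trials = 2, n = 16384, noise_sd = 0.01, seed = 20)
  fit <- trf(ws$pairs, ws$session, keep_data = TRUE)
  expect_s3_class(fit, "trf")
  expect_output(print(fit), "Subcortical TRF")
  expect_output(print(summary(fit)), "wave V")
  expect_equal(length(coef(fit)), length(fit$lag_ms))
  pred <- predict(fit, ws$pairs[[1]])
  expect_equal(length(pred), 16384)
  r <- predict_and_score(fit, ws$pairs[[1]], ws$session$trials[[1]])
  expect_gt(r, 0.9)
  res <- residuals(fit)
  expect_length(res, 2)
  expect_lt(sd(res[[1]]), sd(ws$session$trials[[1]]$samples))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_length(sim[[1]], 16384)
  # polarity pair with negated predictors gives mirrored TRF averaging
  expect_equal(fit$n_trials, 2)
})

test_that("the fast evaluation engine equals the direct estimator", {
  ws <- white_session(n_trials = 3, n = 4096, noise_sd = 0.5, seed = 21)
  sp <- subtrf:::session_spectra(ws$pairs, ws$session, 4096)
  # direct: fold holding out trial 3
  ys <- lapply(ws$session$trials, function(t) t$samples)
  iv <- 1 / sapply(ys[1:2], var); w <- iv / sum(iv)
  tp <- estimate_trf(lapply(ws$pairs[1:2], function(p) p$positive$samples),
                     ys[1:2], w, 4096)
  tn <- estimate_trf(lapply(ws$pairs[1:2], function(p) p$negative$samples),
                     ys[1:2], w, 4096)
  direct <- combine_polarity_trfs(tp, tn)
  # engine: rebuild the same fold ratio
  env <- new.env()
  Up <- Un <- complex(length.out = sp$nh); Dp <- Dn <- numeric(sp$nh)
  Siv <- 0; sump <- sumn <- 0
  for (t in sp$trials) {
    Up <- Up + t$iv * t$crossp; Un <- Un + t$iv * t$crossn
    Dp <- Dp + t$autop; Dn <- Dn + t$auton
    Siv <- Siv + t$iv; sump <- sump + t$sum_autop; sumn <- sumn + t$sum_auton
  }
  t3 <- sp$trials[[3]]
  nump <- (Up - t3$iv * t3$crossp) / (Siv - t3$iv)
  numn <- (Un - t3$iv * t3$crossn) / (Siv - t3$iv)
  denp <- (Dp - t3$autop) / 2; denn <- (Dn - t3$auton) / 2
  ep <- 1e-10 * (sump - t3$sum_autop) / 2 / sp$n
  en <- 1e-10 * (sumn - t3$sum_auton) / 2 / sp$n
  ratio <- 0.5 * (nump / (denp + ep) + numn / (denn + en))
  eng <- subtrf:::half_ratio_to_raw(ratio, sp$n, 4096)
  expect_equal(eng$coef, direct$coef, tolerance = 1e-12)
})

test_that("the full pipeline recovers the kernel peak latency", {
  # one default-noise session through generation, preprocessing,
  # predictor building and the LOO sweep (shared with the study cache)
  res <- study_one(1)
  row8 <- res$sweep[res$sweep$n_trials == 8, ]
  expect_lt(abs(row8$latency_ms - 7), 0.5)
  expect_true(row8$detected)
})
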