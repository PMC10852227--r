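# Auditory-periphery predictor models: ERB spacing, gammatone filterbank,
# inner-hair-cell transduction, adaptation loops, pair generation and lag
# alignment.

test_that("ERB spacing spans 80-8000 Hz with 31 filters", {
  sp <- erb_space(80, 8000, 1)
  expect_length(sp$center_freqs, 31)
  expect_equal(sp$center_freqs[1], 80)
  expect_true(all(diff(sp$center_freqs) > 0))
  expect_true(max(sp$center_freqs) <= 8000)
  # steps are exactly 1 apart on the ERB-number scale
  expect_equal(diff(erb_number(sp$center_freqs)), rep(1, 30), tolerance = 1e-9)
  # degenerate range: a single filter at f
  expect_equal(erb_space(440, 440, 1)$center_freqs, 440)
  expect_error(erb_space(8000, 80), "f_lo")
})

test_that("the ERB-number scale matches its defining formula", {
  expect_equal(erb_number(1000), 21.4 * log10(0.00437 * 1000 + 1))
  expect_equal(erb_number(1000), 15.6214, tolerance = 1e-4)
  expect_equal(erb_number_inv(erb_number(523)), 523, tolerance = 1e-9)
})

test_that("gammatone bands pass a centre-frequency tone at unity gain", {
  rate <- 16384
  sp <- erb_space(200, 4000, 2)
  x <- audio_stimulus(sin(2 * pi * sp$center_freqs[3] * (0:(rate - 1)) / rate),
                      rate)
  bands <- gammatone_filterbank(x, sp)
  expect_equal(ncol(bands), length(sp$center_freqs))
  steady <- bands[(rate / 2):rate, 3]
  gain_db <- 20 * log10(sd(steady) * sqrt(2))
  expect_lt(abs(gain_db), 1)
  expect_error(gammatone_filterbank(x, erb_space(80, 10000)), "rate")
})

test_that("gammatone impulse response peaks near the analytic gamma peak", {
  rate <- 16384
  cf <- 1000
  sp <- erb_space(cf, cf, 1)
  imp <- c(1, numeric(rate / 2))
  b <- gammatone_filterbank(audio_stimulus(imp, rate), sp)[, 1]
  # analytic order-4 gammatone envelope t^3 exp(-2 pi b t) peaks at
  # t = 3 / (2 pi * 1.019 * ERB(cf))
  env <- abs(b) # peak of |response| is close to the envelope peak
  t_peak <- (which.max(env) - 1) / rate
  t_analytic <- 3 / (2 * pi * 1.019 * 24.7 * (0.00437 * cf + 1))
  expect_equal(t_peak, t_analytic, tolerance = 0.25)
})

test_that("inner-hair-cell transduction rectifies and lowpasses", {
  rate <- 16384
  expect_equal(ihc_transduction(matrix(-abs(rnorm(100)), ncol = 1), rate),
               matrix(0, 100, 1))
  # constant positive input passes with unit DC gain
  const <- ihc_transduction(matrix(1, 8000, 1), rate)
  expect_equal(const[6000:8000, 1], rep(1, 2001), tolerance = 1e-4)
  # 2 kHz ripple attenuated per the lowpass magnitude response
  tone <- sin(2 * pi * 2000 * (0:(rate - 1)) / rate)
  out <- ihc_transduction(matrix(tone, ncol = 1), rate, cutoff_hz = 1000)[, 1]
  ba <- signal::butter(1, 2 * 1000 / rate, "low")
  z <- exp(2i * pi * 2000 / rate)
  gain <- abs(sum(ba$b * z^(0:-1)) / sum(ba$a * z^(0:-1)))
  # fundamental ripple of half-wave rectified sine has amplitude 1/2
  ripple <- sd(out[(rate / 2):rate] - mean(out[(rate / 2):rate])) * sqrt(2)
  expect_equal(ripple, gain / 2, tolerance = 0.15)
  expect_true(all(out >= 0))
})

test_that("adaptation loops follow the I^(1/32) steady-state law", {
  fs <- 2000
  n <- 30 * fs
  o_hi <- adaptation_loops(matrix(1, n, 1), fs)
  o_lo <- adaptation_loops(matrix(1 / 1024, n, 1), fs)
  ratio <- o_hi[n, 1] / o_lo[n, 1]
  expect_equal(ratio, 1024^(1 / 32), tolerance = 0.01)
  # absolute steady state for unit input is 1
  expect_equal(o_hi[n, 1], 1, tolerance = 0.01)
})

test_that("adaptation loops bound zero input and limit onset overshoot", {
  fs <- 2000
  z <- adaptation_loops(matrix(0, 5000, 1), fs)
  expect_true(all(is.finite(z)))
  expect_equal(z[5000, 1], 1e-5^(1 / 32), tolerance = 1e-3)
  # step onset from silence: overshoot present but capped by the limiter
  step <- matrix(c(numeric(2000), rep(1, 28000)), ncol = 1)
  out <- adaptation_loops(step, fs, limit = 10)
  steady <- out[30000, 1]
  expect_gt(max(out), 1.5 * steady)           # clear overshoot
  expect_lte(max(out), 10 * steady * 1.05)    # bounded by the limiter factor
  # negative input is rejected
  expect_error(adaptation_loops(matrix(-1, 10, 1), fs), "non-negative")
})

test_that("adaptation compresses level growth sublinearly", {
  set.seed(6)
  rate <- 16384
  x <- audio_stimulus(abs(rnorm(rate)) * 0.1, rate)
  sp <- erb_space(200, 4000, 4)
  d1 <- subtrf:::predictor_drive(x, "OSSA", sp, 1000)
  x2 <- audio_stimulus(2 * x$samples, rate)
  d2 <- subtrf:::predictor_drive(x2, "OSSA", sp, 1000)
  expect_lt(mean(d2) / mean(d1), 2)
})

test_that("predictor pairs are unit variance and correctly rectified", {
  set.seed(7)
  stim <- audio_stimulus(rnorm(8192), 8192)
  pp <- make_predictor_pair(polarity_pair(stim), "RS", 4096)
  expect_equal(var(pp$positive$samples), 1, tolerance = 1e-9)
  expect_equal(var(pp$negative$samples), 1, tolerance = 1e-9)
  expect_equal(length(pp$positive$samples), 4096)
  # rectification: at the stimulus rate, RS(+) + RS(-) reconstructs |x|
  s <- c(1, -1, 2, -0.5)
  xs <- audio_stimulus(s, 100)
  dp <- subtrf:::predictor_drive(xs, "RS", NULL, 1000)
  dn <- subtrf:::predictor_drive(audio_stimulus(-s, 100), "RS", NULL, 1000)
  expect_equal(dp, c(1, 0, 2, 0))
  expect_equal(dp + dn, abs(s))
})

test_that("GT output is invariant to stimulus sign flip", {
  set.seed(8)
  stim <- gen_stimulus(2, 16384, seed = 9)
  sp <- erb_space(200, 6000, 3)
  gp <- subtrf:::predictor_drive(stim, "GT", sp, 1000)
  gn <- subtrf:::predictor_drive(audio_stimulus(-stim$samples, 16384), "GT",
                                 sp, 1000)
  expect_gt(cor(gp, gn), 0.99)
})

test_that("model lag alignment recovers an artificial delay", {
  set.seed(9)
  stim <- audio_stimulus(rnorm(16384), 4096)
  pair <- polarity_pair(stim)
  ref <- make_predictor_pair(pair, "RS", 4096)
  delayed <- subtrf:::circ_shift(ref$positive$samples, 12)
  aligned <- make_predictor_pair(pair, "EXTERNAL", 4096,
                                 rs_reference = ref$positive,
                                 external = list(positive = delayed,
                                                 negative = delayed))
  expect_equal(aligned$positive$shift, -12L)
  # brute-force check: after alignment the peak cross-correlation is at 0
  cc <- vapply(-20:20, function(s) {
    cor(ref$positive$samples,
        subtrf:::circ_shift(aligned$positive$samples, s))
  }, numeric(1))
  expect_equal(c(-20:20)[which.max(cc)], 0)
})
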