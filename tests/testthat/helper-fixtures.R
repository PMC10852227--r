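# Shared fixtures, all built in code at test time.

# A predictor pair of unit-variance white half-wave-ish series (no auditory
# model), for exercising the estimator machinery on small problems.
white_pair <- function(n, rate = 4096, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xp <- pmax(stats::rnorm(n), 0); xn <- pmax(stats::rnorm(n), 0)
  structure(list(positive = predictor(xp / sd(xp), rate, "RS", "+"),
                 negative = predictor(xn / sd(xn), rate, "RS", "-"),
                 kind = "RS"),
            class = "predictor_pair")
}

# A small white-noise session with known kernel: y_i = conv(xa_i, k) + noise.
white_session <- function(n_trials = 3, n = 8192, rate = 4096, kernel = NULL,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  pairs <- lapply(seq_len(n_trials), function(i) white_pair(n, rate))
  if (is.null(kernel)) kernel <- gen_kernel(rate_hz = rate)
  trials <- lapply(seq_len(n_trials), function(i) {
    xa <- pair_mean_samples(pairs[[i]])
    K <- stats::fft(c(kernel, numeric(n - length(kernel))))
    y <- Re(stats::fft(stats::fft(xa) * K, inverse = TRUE)) / n
    eeg_trial(y + stats::rnorm(n, 0, noise_sd), rate, i)
  })
  list(session = eeg_session(trials), pairs = pairs, kernel = kernel)
}

pair_mean_samples <- function(pair) {
  (pair$positive$samples + pair$negative$samples) / 2
}

# Direct circulant weighted-least-squares oracle for the TRF estimator:
# solve [ (1/N) sum_i X_i' X_i + eps tr(.)/n I ] h = sum_i w_i X_i' y_i
# with circulant X_i. The eps term is the estimator's declared numerical
# floor (eps x mean denominator bin), which in the time domain is exactly
# that multiple of the identity.
circulant_trf_oracle <- function(xs, ys, w, eps_rel = 1e-10) {
  n <- length(xs[[1]])
  A <- matrix(0, n, n); b <- numeric(n)
  for (i in seq_along(xs)) {
    X <- sapply(0:(n - 1), function(l) xs[[i]][((0:(n - 1) - l) %% n) + 1])
    A <- A + t(X) %*% X / length(xs)
    b <- b + w[i] * t(X) %*% ys[[i]]
  }
  A <- A + eps_rel * (sum(diag(A)) / n) * diag(n)
  as.numeric(solve(A, b))
}

# Reorder a trf_waveform back to IFFT index order (lag 0, 1, ..., -1).
trf_index_order <- function(w) {
  n <- length(w$coef)
  w$coef[order(w$lag_samples %% n)]
}

# Exact signed-rank two-tailed p by brute-force enumeration of all 2^n sign
# assignments (independent oracle for the DP implementation).
signed_rank_p_bruteforce <- function(r, T_obs) {
  n <- length(r)
  sums <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  mu <- sum(r) / 2
  mean(abs(sums - mu) >= abs(T_obs - mu) - 1e-9)
}

# Holm step-down adjustment straight from its definition.
holm_definition <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (k in seq_len(m)) {
    run <- max(run, min(1, (m - k + 1) * p[o[k]]))
    adj[o[k]] <- run
  }
  adj
}

# Construct a processed-stage TRF whose 5 ms noise windows all have mean
# square 1 and whose 5 ms signal window around a 7 ms peak has mean square
# `s_over_n`; used for the SNR identity checks.
constructed_snr_waveform <- function(s_over_n = 2, rate = 4096) {
  lag <- seq(round(-0.510 * rate), round(0.040 * rate))
  cf <- rep(1, length(lag))
  lag_ms <- lag / rate * 1000
  # place the plateau on exactly the samples a 5 ms window centred on the
  # on-grid peak latency will cover
  peak <- which.min(abs(lag_ms - 7))
  latency <- lag_ms[peak]
  win <- lag_ms >= latency - 2.5 - 1e-9 & lag_ms <= latency + 2.5 + 1e-9
  cf[win] <- sqrt(s_over_n)
  cf[peak] <- cf[peak] * (1 + 1e-9)
  trf_waveform(cf, lag, rate, "smoothed")
}

# Minimal BDF writer for reader round-trip tests (synthetic file).
write_test_bdf <- function(path, channels, rate, labels) {
  ns <- length(channels)
  n <- length(channels[[1]])
  n_rec <- 1L
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    writeChar(sprintf(paste0("%-", w, "s"), s), con, eos = NULL)
  }
  writeBin(as.raw(255), con)
  pad("BIOSEMI", 7)
  pad("", 80); pad("", 80)
  pad("01.01.01", 8); pad("01.01.01", 8)
  pad(as.character(256 * (ns + 1)), 8)
  pad("24BIT", 44)
  pad(as.character(n_rec), 8)
  pad(as.character(n / rate), 8)
  pad(as.character(ns), 4)
  for (l in labels) pad(l, 16)
  for (i in 1:ns) pad("transducer", 80)
  for (i in 1:ns) pad("uV", 8)
  for (i in 1:ns) pad("-262144", 8)
  for (i in 1:ns) pad("262143", 8)
  for (i in 1:ns) pad("-8388608", 8)
  for (i in 1:ns) pad("8388607", 8)
  for (i in 1:ns) pad("HP:DC", 80)
  for (i in 1:ns) pad(as.character(n), 8)
  for (i in 1:ns) pad("", 32)
  # data: physical = digital / 32 with these scaling ranges
  for (ch in channels) {
    dig <- round(ch * 32)
    dig <- ifelse(dig < 0, dig + 2^24, dig)
    b <- rbind(dig %% 256, (dig %/% 256) %% 256, (dig %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  }
  invisible(path)
}
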