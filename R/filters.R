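# Internal signal-processing utilities shared across modules.
#
# Conventions: signals are plain numeric vectors; sampling rates in Hz.
# Long-signal filtering goes through the FFT; designed FIR responses are
# cached per (design, signal length) in a package-local environment.

.subtrf_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .subtrf_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .subtrf_cache)
  }
  get(key, envir = .subtrf_cache, inherits = FALSE)
}

#' Fourier-method resampling
#'
#' Resamples a real signal to a new rate by truncating or zero-padding its
#' discrete spectrum, which is equivalent to ideal (brick-wall) anti-alias
#' filtering. Output length is `round(n * rate_out / rate_in)`.
#'
#' @param x numeric signal.
#' @param rate_in,rate_out sampling rates in Hz.
#' @return numeric vector of the resampled signal.
#' @keywords internal
#' @noRd
resample_fft <- function(x, rate_in, rate_out) {
  n <- length(x)
  n_out <- round(n * rate_out / rate_in)
  if (n_out == n) return(x)
  resample_spectrum(stats::fft(x), n, n_out)
}

# Core of the Fourier resampler: given the full spectrum X of a length-n
# real signal, return the length-n_out resampled time series.
resample_spectrum <- function(X, n, n_out) {
  stopifnot(n_out > 1)
  Xo <- complex(length.out = n_out)
  # positive-frequency bins excluding DC and any shared Nyquist
  m <- min(floor((n - 1) / 2), floor((n_out - 1) / 2))
  Xo[1] <- X[1]
  if (m > 0) {
    Xo[2:(m + 1)] <- X[2:(m + 1)]
    Xo[(n_out - m + 1):n_out] <- X[(n - m + 1):n]
  }
  if (n_out < n && n_out %% 2 == 0) {
    # fold energy at the new Nyquist onto a real bin
    Xo[n_out / 2 + 1] <- Re(X[n_out / 2 + 1])
  }
  if (n_out > n && n %% 2 == 0) {
    # split the old Nyquist bin between the two new half-bins
    Xo[n / 2 + 1] <- Re(X[n / 2 + 1]) / 2
    Xo[n_out - n / 2 + 1] <- Re(X[n / 2 + 1]) / 2
  }
  Re(stats::fft(Xo, inverse = TRUE)) * (n_out / n) / n_out
}

# First-order Butterworth section (bilinear design via signal::butter),
# applied causally (forward only). The moving-average and recursive parts
# are applied with stats::filter, which is much faster than
# signal::filter on long signals.
butter1_filter <- function(x, cutoff_hz, rate_hz, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(cutoff_hz > 0, cutoff_hz < rate_hz / 2)
  key <- sprintf("butter1_%s_%g_%g", type, cutoff_hz, rate_hz)
  ba <- cache_get(key, function() signal::butter(1, 2 * cutoff_hz / rate_hz, type))
  b <- ba$b; a <- ba$a
  v <- b[1] * x + b[2] * c(0, x[-length(x)])
  as.numeric(stats::filter(v, -a[2], method = "recursive"))
}

# Linear convolution of x with an odd-length symmetric FIR h, with the
# (ntaps-1)/2 group delay compensated, so the output is aligned with x
# ("same" length). Uses FFT convolution.
fir_filter_zerophase <- function(x, h) {
  n <- length(x); m <- length(h)
  stopifnot(m %% 2 == 1)
  half <- (m - 1) / 2
  nfft <- stats::nextn(n + m - 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - m)))
  full <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  full[(half + 1):(half + n)]
}

# Hamming window of given length (periodic = FALSE, symmetric), base R.
hamming_win <- function(m) {
  if (m == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / (m - 1))
}

#' Linear-phase FIR notch bank (frequency-sampling design)
#'
#' Designs a type-I linear-phase FIR whose amplitude response is unity except
#' in notches of the given width centred at `freqs`, with one raised-cosine
#' transition bin on each notch edge to control passband ripple.
#'
#' @param rate_hz sampling rate.
#' @param freqs notch centre frequencies in Hz.
#' @param width_hz full notch width in Hz.
#' @param ntaps odd FIR length; defaults to about one second of taps, which
#'   puts the design-grid spacing near 1 Hz.
#' @return numeric vector of FIR coefficients (odd length, symmetric).
#' @keywords internal
#' @noRd
design_notch_fir <- function(rate_hz, freqs = seq(50, 1000, by = 50),
                             width_hz = 5, ntaps = NULL) {
  if (is.null(ntaps)) ntaps <- 2 * floor(rate_hz / 2) + 1
  stopifnot(ntaps %% 2 == 1, all(freqs < rate_hz / 2))
  grid <- (0:(ntaps - 1)) * rate_hz / ntaps
  f <- pmin(grid, rate_hz - grid)           # folded frequency of each DFT bin
  amp <- rep(1, ntaps)
  df <- rate_hz / ntaps
  for (f0 in freqs) {
    d <- abs(f - f0)
    amp[d <= width_hz / 2] <- 0
    tr <- d > width_hz / 2 & d <= width_hz / 2 + df
    amp[tr] <- pmin(amp[tr], sin(pi / 2 * (d[tr] - width_hz / 2) / df))
  }
  tau <- (ntaps - 1) / 2
  H <- amp * exp(-2i * pi * (0:(ntaps - 1)) * tau / ntaps)
  h <- Re(stats::fft(H, inverse = TRUE)) / ntaps
  h
}

# Zero-phase (delay-compensated) transfer magnitude of a symmetric odd FIR on
# the DFT grid of a length-n signal; real-valued by symmetry.
fir_zerophase_response <- function(h, n) {
  m <- length(h); half <- (m - 1) / 2
  stopifnot(m %% 2 == 1, n >= m)
  # center the impulse response at sample 0 (circularly) -> real spectrum
  hc <- numeric(n)
  hc[1] <- h[half + 1]
  hc[2:(half + 1)] <- h[(half + 2):m]
  hc[(n - half + 1):n] <- h[1:half]
  Re(stats::fft(hc))
}

#' Windowed-sinc linear-phase FIR bandpass
#'
#' Hamming-windowed sinc design for the TRF post-processing bandpass.
#'
#' @param lo_hz,hi_hz band edges in Hz.
#' @param rate_hz sampling rate.
#' @param ntaps odd FIR length.
#' @return numeric FIR coefficients.
#' @keywords internal
#' @noRd
design_bandpass_fir <- function(lo_hz, hi_hz, rate_hz, ntaps = 4097) {
  stopifnot(ntaps %% 2 == 1, lo_hz < hi_hz, hi_hz <= rate_hz / 2)
  m <- (ntaps - 1) / 2
  t <- (-m):m
  sinc <- function(fc) {
    out <- 2 * fc / rate_hz * rep(1, length(t))
    nz <- t != 0
    out[nz] <- sin(2 * pi * fc * t[nz] / rate_hz) / (pi * t[nz])
    out
  }
  h <- (sinc(hi_hz) - sinc(lo_hz)) * hamming_win(ntaps)
  h
}

# Circular shift: y[t] = x[t - s] (positive s delays the signal).
circ_shift <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[1:(n - s)])
}

# Lag (in samples) of the maximum circular cross-correlation between a
# reference and a signal: returns s maximizing cor(ref, circ_shift(x, s)).
best_circular_shift <- function(ref, x) {
  n <- length(x)
  stopifnot(length(ref) == n)
  cc <- Re(stats::fft(Conj(stats::fft(x)) * stats::fft(ref), inverse = TRUE))
  k <- which.max(cc) - 1L        # cc[k+1] = sum_u ref[u] * x[u - k]  (circular)
  s <- k
  if (s > n / 2) s <- s - n
  as.integer(s)
}

# RMS helper
rms <- function(x) sqrt(mean(x^2))
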