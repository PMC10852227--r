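# Synthetic stimulus / EEG session generator.
#
# Emulates the statistical structure the analysis assumes: trials of
# speech-like audio, EEG equal to a stimulus-derived predictor convolved
# with a short wave-V-like kernel (peak near 7 ms), buried in 1/f
# background noise with 50 Hz line harmonics and rare high-amplitude
# artifact bursts. All randomness flows from a single session seed via
# sequential draws.

#' Generate a speech-like stimulus
#'
#' Pink-noise carrier (power ~ 1/f) multiplied by a slow amplitude
#' envelope band-limited to the syllabic 2-8 Hz range, with intermittent
#' near-silent stretches where the envelope is clipped at zero.
#'
#' @param duration_s duration in seconds.
#' @param rate_hz sampling rate (default 8192 Hz; broadband content up to
#'   the 4096 Hz Nyquist).
#' @param seed integer seed.
#' @param mod_band_hz envelope band in Hz.
#' @return an [audio_stimulus()].
#' @export
gen_stimulus <- function(duration_s, rate_hz = 8192, seed = 1L,
                         mod_band_hz = c(2, 8)) {
  stopifnot(duration_s > 0)
  set.seed(as.integer(seed))
  n <- round(duration_s * rate_hz)
  # pink carrier: amplitude ~ f^{-1/2} above 50 Hz, flat below
  W <- stats::fft(stats::rnorm(n))
  f <- bin_freqs(n, rate_hz)
  carrier <- Re(stats::fft(W / sqrt(pmax(f, 50)), inverse = TRUE)) / n
  # syllabic envelope: band-limited Gaussian noise generated on a coarse
  # 64 Hz grid (ample for a 2-8 Hz band), interpolated, shifted and clipped
  env_rate <- 64
  ne <- ceiling(duration_s * env_rate)
  E <- stats::fft(stats::rnorm(ne))
  fe <- bin_freqs(ne, env_rate)
  e <- Re(stats::fft(E * (fe >= mod_band_hz[1] & fe <= mod_band_hz[2]),
                     inverse = TRUE)) / ne
  e <- e / stats::sd(e)
  e_full <- stats::approx(seq(0, by = 1 / env_rate, length.out = ne), e,
                          xout = (0:(n - 1)) / rate_hz, rule = 2)$y
  env <- pmax(e_full + 0.4, 0)
  x <- carrier * env
  x <- x / rms(x) * 0.1
  audio_stimulus(x, rate_hz, sprintf("synthetic speech (seed %d)", seed))
}

# folded frequency (Hz) of each DFT bin of a length-n signal
bin_freqs <- function(n, rate_hz) {
  k <- 0:(n - 1)
  pmin(k, n - k) * rate_hz / n
}

#' Generate a wave-V-like response kernel
#'
#' Gabor pulse: a Gaussian envelope (FWHM `width_ms`) on a cosine carrier,
#' with its maximum at `peak_ms`. Defined on causal lags from 0 to
#' `peak_ms + 2 * width_ms`.
#'
#' @param peak_ms peak latency in ms (default 7, inside the 5-10 ms wave V
#'   search window).
#' @param amplitude peak amplitude (microvolts per unit-variance predictor).
#' @param width_ms Gaussian full width at half maximum in ms.
#' @param rate_hz sampling rate.
#' @param carrier_hz cosine carrier frequency (inside the 30-1000 Hz TRF
#'   analysis band).
#' @return numeric kernel with attributes `rate_hz` and `peak_ms`.
#' @export
gen_kernel <- function(peak_ms = 7, amplitude = 0.06, width_ms = 3,
                       rate_hz = 8192, carrier_hz = 300) {
  stopifnot(width_ms > 0, width_ms < 10)
  sigma_ms <- width_ms / (2 * sqrt(2 * log(2)))
  t_ms <- (0:round((peak_ms + 2 * width_ms) * rate_hz / 1000)) / rate_hz * 1000
  k <- amplitude * exp(-0.5 * ((t_ms - peak_ms) / sigma_ms)^2) *
    cos(2 * pi * carrier_hz * (t_ms - peak_ms) / 1000)
  attr(k, "rate_hz") <- rate_hz
  attr(k, "peak_ms") <- peak_ms
  k
}

#' Default ground-truth parameters for synthetic sessions
#'
#' The defaults define the simulated study conditions: a 0.06 uV wave-V-like
#' kernel peaking at 7 ms against 15 uV (rms) 1/f background noise, 3 uV
#' line-noise harmonics at 50-200 Hz, and rare (0.5/min) 150 uV artifact
#' bursts; the generation drive is the polarity-averaged rectified-speech
#' predictor (the brainstem response is polarity-agnostic).
#'
#' @param peak_ms,amplitude,width_ms,carrier_hz kernel parameters, see
#'   [gen_kernel()].
#' @param noise_scale rms of the 1/f background noise in microvolts.
#' @param noise_exponent spectral exponent of the background (power ~
#'   1/f^exponent).
#' @param line_amp amplitude per line-noise harmonic in microvolts.
#' @param line_harmonics_hz line-noise component frequencies.
#' @param artifact_rate artifact bursts per minute.
#' @param artifact_amp artifact burst amplitude in microvolts.
#' @param artifact_dur_s artifact burst duration in seconds.
#' @param kind predictor model generating the true drive.
#' @param polarity `"mean"` (average of the polarity pair) or `"positive"`.
#' @param stim_highpass_hz stimulus preconditioning highpass.
#' @return list of ground-truth parameters.
#' @export
synthetic_truth <- function(peak_ms = 7, amplitude = 0.06, width_ms = 3,
                            carrier_hz = 300, noise_scale = 15,
                            noise_exponent = 1, line_amp = 3,
                            line_harmonics_hz = c(50, 100, 150, 200),
                            artifact_rate = 0.5, artifact_amp = 150,
                            artifact_dur_s = 0.3, kind = "RS",
                            polarity = c("mean", "positive"),
                            stim_highpass_hz = 1000) {
  polarity <- match.arg(polarity)
  as.list(environment())
}

#' Generate a synthetic EEG session with known ground truth
#'
#' Per trial: a speech-like stimulus is generated, preconditioned exactly
#' as the analysis preconditions real stimuli (mono, 1 kHz first-order
#' highpass), transformed by the configured predictor model at the raw EEG
#' rate, scaled to unit variance, and convolved with the ground-truth
#' kernel; 1/f noise, line-noise harmonics, and Poisson-timed artifact
#' bursts are added. Burst positions are logged so artifact suppression can
#' be validated.
#'
#' @param n_trials number of trials (default 8).
#' @param trial_s raw trial duration in seconds (default 245; analysis
#'   trims to 2-242 s, leaving 240 s).
#' @param rate_hz common audio / raw-EEG rate (default 8192).
#' @param truth ground-truth parameters from [synthetic_truth()].
#' @param seed session seed; every random draw derives from it.
#' @return object of class `synthetic_session`: `stimuli` (list of raw
#'   [audio_stimulus()]), `eeg_raw` (list of numeric microvolt series at
#'   `rate_hz`), `rate_hz`, `truth` (parameters plus `kernel` and
#'   per-trial `artifact_log`), `seed`.
#' @export
gen_session <- function(n_trials = 8, trial_s = 245, rate_hz = 8192,
                        truth = synthetic_truth(), seed = 1L) {
  kernel <- gen_kernel(truth$peak_ms, truth$amplitude, truth$width_ms,
                       rate_hz, truth$carrier_hz)
  stimuli <- vector("list", n_trials)
  eeg <- vector("list", n_trials)
  art_log <- vector("list", n_trials)
  n <- round(trial_s * rate_hz)
  f <- bin_freqs(n, rate_hz)
  K <- stats::fft(c(kernel, numeric(n - length(kernel))))
  t_s <- (0:(n - 1)) / rate_hz
  for (i in seq_len(n_trials)) {
    trial_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483629)
    stimuli[[i]] <- gen_stimulus(trial_s, rate_hz, seed = trial_seed)
    # drive: the analysis-style predictor of the preconditioned stimulus
    prep <- preprocess_stimulus(stimuli[[i]]$samples, rate_hz,
                                truth$stim_highpass_hz)
    pair <- polarity_pair(prep)
    dp <- predictor_drive(pair$positive, truth$kind, erb_space(80, 3500), 1000)
    drive <- if (truth$polarity == "mean") {
      dn <- predictor_drive(pair$negative, truth$kind, erb_space(80, 3500), 1000)
      (dp + dn) / 2
    } else dp
    drive <- drive / stats::sd(drive)
    clean <- Re(stats::fft(stats::fft(drive) * K, inverse = TRUE)) / n
    # background: 1/f noise scaled to noise_scale rms
    pink <- Re(stats::fft(stats::fft(stats::rnorm(n)) /
                            pmax(f, 0.5)^(truth$noise_exponent / 2),
                          inverse = TRUE)) / n
    pink <- pink / rms(pink) * truth$noise_scale
    line <- numeric(n)
    for (fh in truth$line_harmonics_hz) {
      line <- line + truth$line_amp * sin(2 * pi * fh * t_s + stats::runif(1, 0, 2 * pi))
    }
    y <- clean + pink + line
    # artifact bursts
    n_art <- stats::rpois(1, truth$artifact_rate * trial_s / 60)
    bursts <- sort(stats::runif(n_art, 0, trial_s - truth$artifact_dur_s))
    dur_n <- round(truth$artifact_dur_s * rate_hz)
    win <- 0.5 * (1 - cos(2 * pi * (0:(dur_n - 1)) / (dur_n - 1)))
    for (b in bursts) {
      i0 <- round(b * rate_hz) + 1
      idx <- i0:min(n, i0 + dur_n - 1)
      y[idx] <- y[idx] + truth$artifact_amp * win[seq_along(idx)] *
        stats::rnorm(length(idx))
    }
    art_log[[i]] <- bursts
    eeg[[i]] <- y
  }
  truth$kernel <- kernel
  truth$artifact_log <- art_log
  structure(list(stimuli = stimuli, eeg_raw = eeg, rate_hz = rate_hz,
                 n_trials = n_trials, trial_s = trial_s, truth = truth,
                 seed = as.integer(seed)),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d trials of %g s at %g Hz (seed %d)\n",
              x$n_trials, x$trial_s, x$rate_hz, x$seed))
  cat(sprintf("  kernel: peak %.1f ms, amplitude %g uV; noise %g uV rms\n",
              x$truth$peak_ms, x$truth$amplitude, x$truth$noise_scale))
  invisible(x)
}
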