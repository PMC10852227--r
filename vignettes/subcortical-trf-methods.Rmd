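---
title: "Estimating subcortical TRFs to continuous speech: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subcortical TRFs to continuous speech: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtrf)
```

## The problem

The auditory brainstem response (ABR) is a sub-10-ms scalp potential
generated by subcortical auditory structures. Its most prominent feature,
wave V, is a standard clinical marker of auditory function, conventionally
obtained by averaging responses to thousands of clicks. `subtrf`
implements an alternative that works with *continuous, natural speech*:
the temporal response function (TRF), a linear kernel `h(lag)` relating a
stimulus-derived predictor `x(t)` to the ongoing single-channel EEG
`y(t)`,

$$ y(t) \approx \sum_{\ell} h(\ell)\, x(t - \ell) + \varepsilon(t). $$

Because the auditory periphery is strongly nonlinear, the choice of
predictor matters. The package provides a family of predictors of
increasing physiological fidelity:

* **RS** — half-wave rectified speech waveform (coarse cochlear
  rectification);
* **GT** — gammatone filterbank (31 filters, 80–8000 Hz, spaced 1 ERB
  apart on the ERB-number scale \(E(f) = 21.4\log_{10}(0.00437 f + 1)\)),
  absolute band outputs averaged across bands;
* **OSS** — GT followed by inner-hair-cell transduction (half-wave
  rectification + 1 kHz first-order lowpass) per band;
* **OSSA** — OSS followed by five divisive adaptation loops per band
  (time constants 5, 50, 129, 253, 500 ms), the classic functional model
  of auditory-nerve adaptation whose steady-state response to a constant
  input \(I\) is \(I^{1/32}\).

An `EXTERNAL` adapter accepts precomputed predictor series from
biophysical auditory-nerve models (e.g. mean firing rates of a
high-spontaneous-rate fiber population, 125 Hz–16 kHz log-spaced), which
are outside the scope of this package.

## The estimator

TRFs are estimated per trial set by unregularized frequency-domain
deconvolution,

$$ \mathrm{TRF} = \mathcal{F}^{-1}\!\left\{ \frac{\sum_{i=1}^{N} w_i\,
   \mathcal{F}\{x_i\}^{*}\, \mathcal{F}\{y_i\}}{\frac{1}{N}\sum_{i=1}^{N}
   \mathcal{F}\{x_i\}^{*}\, \mathcal{F}\{x_i\}} \right\}, $$

with inverse-variance trial weights \(w_i \propto 1/\mathrm{var}(y_i)\)
normalized to sum to one. Note the deliberate asymmetry: the weights
appear in the numerator while the denominator is a plain \(1/N\) average;
this is implemented exactly as stated. The only numerical concession is a
denominator floor of \(10^{-10}\times\) its mean bin value, which equals
adding that multiple of the identity to the circulant normal equations —
far below any regularization that would change results (the test suite
checks agreement with a direct circulant least-squares solve to
\(10^{-8}\) relative error).

Predictors are computed for the stimulus and its sign-inverted copy
(`polarity_pair()`), two TRFs are fitted and averaged — the
continuous-speech analogue of alternating click polarity, which cancels
stimulus artifacts and rectification-phase effects. Each predictor is
circularly shifted to maximize correlation with the RS predictor
(removing model-inherent lags; 1-sample resolution at 4096 Hz = 0.24 ms,
well below the 2 ms smoothing width) and scaled to unit variance, so TRF
amplitudes are comparable across predictor models (units are therefore
arbitrary).

The raw TRF (circular lags −T/2..T/2) is post-processed by: a
delay-compensated linear-phase FIR bandpass, 30–1000 Hz (Hamming-windowed
sinc, ~1 s of taps); smoothing with a unit-sum Hamming window of 2 ms
width (9 samples at 4096 Hz, the nearest odd count); extraction of the
−10..30 ms segment; and subtraction of the −10..0 ms baseline mean.
Smoothing precedes extraction, following the processing order of the
estimation procedure; the filtered-and-smoothed waveform over −510..40 ms
is retained because the wave V noise estimate needs lags the extraction
would discard.

## Preprocessing defaults

All constants live in `default_config()` and are never hard-coded in
computation code:

| parameter | default | meaning |
|---|---|---|
| stimulus highpass | 1 kHz, 1st-order Butterworth, causal | emphasizes the high frequencies that drive the brainstem |
| EEG highpass | 1 Hz, 1st-order Butterworth, causal | drift removal, matching online acquisition filters |
| notches | 50…1000 Hz, 5 Hz wide, linear-phase FIR | power-line harmonics |
| analysis rate | 4096 Hz | brainstem band with headroom |
| artifact rule | \|x − mean\| > 5 SD → zero 1 s window | SD computed once, two-sided (safer than one-sided for EEG; one-sided available) |
| trial window | 2–242 s | onset removal, equal trial lengths (240 s) |
| TRF band | 30–1000 Hz | wave V spectral content |
| smoothing | 2 ms Hamming | stabilizes unregularized estimates |
| peak search | 5–10 ms | wave V latency range |
| noise windows | 96 × 5 ms tiling −500..−20 ms, non-overlapping | pre-stimulus noise floor |
| detection | SNR ≥ 3 dB (signal power twice noise) | wave V present |
| null shifts | 30, 60, 90 s circular | chance-level correlation |

Notch filters are designed by frequency sampling with ~1 Hz grid spacing
and one raised-cosine transition bin per edge; at the notch centres
attenuation exceeds 40 dB while a 30–40 Hz probe changes by less than
0.5 dB. For long signals the notch FIR is applied in the frequency domain
(multiplication by its delay-compensated transfer function, cached per
signal length), which is the circular, delay-compensated application of
the same filter and is fused with the Fourier-method resampler so each
trial costs a single FFT pair.

Resampling uses spectrum truncation (ideal anti-aliasing). The artifact
rule's mean and SD are computed once before zeroing, not iterated.

## Evaluation

`loo_evaluate()` fits on `m − 1` trials and scores the held-out trial by
Pearson correlation between the measured EEG and the prediction
(extracted TRF convolved with the polarity-averaged predictor; edge
samples without full kernel support are dropped). This is repeated for
`m = 2..8` consecutive trials in presentation order, simulating early
termination of an experiment; per data length the fold TRFs are averaged
into the final TRF whose wave V metrics are reported. Chance level comes
from `null_model_score()`: the same procedure with predictors circularly
shifted by 30/60/90 s, which preserves the temporal structure of both
signals while destroying their alignment.

Wave V is the global maximum between 5 and 10 ms (ties: earliest). SNR is
`10 log10(S/N)` with S the mean square in a 5 ms window around the peak
and N the mean of per-window mean squares over the noise tiling, floored
at 0 dB because signal power cannot fall below the noise floor.

Group-level comparisons use paired two-tailed Wilcoxon signed-rank tests
with Holm–Bonferroni correction. The implementation reports the rank sum
above zero, drops zero differences, assigns average ranks to ties, and
computes the exact two-tailed p-value for n ≤ 25 by dynamic programming
over doubled ranks, so ties (common when SNRs are floored at 0 dB) remain
exact; beyond that a tie-corrected normal approximation is used.
Participants lacking the full trial count are excluded from paired tests.

## The synthetic generator

No public recordings exist for this paradigm, so `gen_session()` creates
sessions with the statistical structure the analysis assumes, with known
ground truth:

* **Stimulus**: pink-noise carrier with a 2–8 Hz band-limited envelope
  (clipped at zero, giving intermittent silences) — the syllabic
  modulation and spectral tilt of speech, at 8192 Hz so the EEG analysis
  band is fully covered. It is *not* speech: no harmonic structure,
  formants, or phonemes, so tests exercise the signal path, not
  phonetic specificity.
* **Response**: the preconditioned stimulus is passed through a predictor
  model (RS by default; configurable, so predictor-mismatch experiments
  are possible), scaled to unit variance, and convolved with a Gabor
  kernel — peak 7.0 ms (mid wave V range), 3 ms FWHM, 300 Hz carrier,
  0.06 µV amplitude. The generation drive is the *polarity-averaged*
  predictor, reflecting the polarity-agnostic brainstem response.
* **Noise**: 1/f background at 15 µV rms (typical scalp EEG), 3 µV line
  harmonics at 50–200 Hz (so the notch stages do real work), and
  Poisson-timed 150 µV artifact bursts at 0.5/min (so artifact zeroing
  does real work), with burst times logged for validation.

The kernel amplitude was fixed once so that the 32-minute wave V SNR of
the default sessions sits near the 13–14 dB range that adaptation-based
predictors reach in this paradigm, and left untouched thereafter; with it,
wave V crosses the 3 dB detection threshold at around 12 minutes of data,
reproducing the qualitative data-length behaviour of the method. All
randomness derives from one session seed (per-trial sub-seeds
`seed*1000 + trial`, then sequential draws).

Because generation drives the EEG with the polarity-*averaged* predictor
while the analysis fits each polarity separately, the estimator is not
exactly unbiased on these sessions — the expected TRF is the kernel times
a real, positive spectral attenuation factor. This leaves the peak
latency intact (the factor is zero-phase) and mildly lowers amplitude,
which is the realistic situation: with real EEG the predictor never
matches the true drive either. Tests that need the exact noiseless
identity configure the generator with a single-polarity drive.

## Verification strategy

The test suite checks, among others: the estimator against a direct
circulant weighted least-squares oracle (relative error < 1e−8); the
adaptation-loop closed form \((I_1/I_2)^{1/32}\) within 1%; exact
Wilcoxon p-values against full sign-flip enumeration (n ≤ 12) and Holm
against its step-down definition; the SNR identities (scale invariance,
0 dB flooring, 3 dB ⇔ S = 2N, exact baseline zeroing); and a 20-seed
simulation study at the default conditions (8 trials × 240 s usable at
4096 Hz) verifying median latency error < 0.5 ms, ≥ 90% wave V detection
at 32 minutes, a positive SNR trend across 2→8 training trials, and
circular-shift null correlations centred at zero. The study sizes were
chosen to keep a full run at desk scale; they are the package's own
simulation defaults.

What passing these tests does *not* show: performance on real EEG with
real speech (phonetic structure, non-stationary noise, electrode
artifacts beyond simple bursts), the behaviour of the GT/OSS/OSSA
predictors as *generating* models at full audio bandwidth, or the
absolute calibration of SPL-dependent nonlinearities (presentation level
enters only as a configurable digital r.m.s. target).

## Known limitations and open choices

* The estimator is unregularized by design; it needs minutes of data and
  benefits from the 2 ms smoothing. Ridge or boosting estimators are out
  of scope.
* GT band "amplitude" is the absolute filter output (default), not a
  Hilbert envelope; both readings exist in the literature and the
  rectified reading keeps GT comparable to RS.
* The adaptation stage returns the raw divisor-chain output without the
  conventional rescaling to "model units"; rescaling is affine and would
  break the clean \(I^{1/32}\) steady-state law that the tests pin down.
* Whether fold-level or fold-averaged TRFs feed the wave V metric is an
  open reading; the fold-averaged TRF is used, matching the final-TRF
  definition per data length.
* The artifact threshold statistic is two-sided (|x − mean|), the safer
  reading for EEG; a one-sided variant is available via
  `suppress_artifacts(two_sided = FALSE)`.
* Synthetic sessions use 8192 Hz audio; gammatone banks on synthetic
  stimuli are therefore limited to centre frequencies below 4096 Hz
  (the pipeline config defaults to 80–3500 Hz for the filterbank models
  in simulation; with real 44.1/48 kHz recordings the full 80–8000 Hz
  bank applies).

## A worked example

```{r example, eval = FALSE}
library(subtrf)

sim <- gen_session(seed = 11)             # 8 trials, known 7 ms kernel
prep <- prepare_synthetic(sim)            # predictors + EEG preprocessing
fit <- trf(prep$pairs, prep$session)      # polarity-averaged TRF
summary(fit)
plot(fit)

ev <- loo_evaluate(prep$session, prep$pairs, lengths = 2:8)
null_r <- null_model_score(prep$session, prep$pairs, n_trials = 4)
```

Running the full default experiment (several simulated participants, all
predictor kinds, statistics and serialization) is `run_experiment(default_config(...))`.
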