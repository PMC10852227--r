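# subtrf

Subcortical temporal response functions (TRFs) from single-channel EEG
recorded during continuous-speech listening.

## What it does, and for whom

Auditory brainstem responses (ABRs) are usually measured by averaging
thousands of clicks. For researchers and audiologists who want the same
subcortical markers — most importantly the **wave V peak** at 5–10 ms —
from *natural, continuous speech*, `subtrf` implements the linear
encoding-model alternative: the temporal response function

    y(t) ≈ Σ_ℓ h(ℓ) x(t − ℓ) + ε(t),

where `y` is the EEG (Cz referenced to the mastoids, 4096 Hz) and `x` is
a predictor derived from the speech waveform. The TRF `h` is estimated by
unregularized frequency-domain deconvolution with inverse-variance trial
weights,

    TRF = F⁻¹[ Σᵢ wᵢ F{xᵢ}* F{yᵢ} / ( (1/N) Σᵢ F{xᵢ}* F{xᵢ} ) ],

fitted separately for the stimulus and its sign-inverted copy and
averaged (the continuous-speech analogue of alternating click polarity).

Because the auditory periphery is nonlinear, the package provides
predictors of increasing physiological fidelity — rectified speech (RS),
a 31-band gammatone filterbank at 1-ERB spacing over 80–8000 Hz (GT),
inner-hair-cell transduction (OSS), and divisive adaptation loops with
the classic `I^(1/32)` steady-state compression (OSSA) — plus an adapter
for externally computed auditory-nerve model outputs. Wave V is scored by
its SNR, `10·log10(S/N)` with S the power in a 5 ms window around the
detected peak and N the average power of 5 ms windows tiling −500..−20 ms,
floored at 0 dB and "detected" at ≥ 3 dB; model fit is the leave-one-out
prediction correlation against circular-shift (30/60/90 s) null models.

A first-class synthetic-session generator (`gen_session()`) produces
speech-like stimuli and EEG with a known wave-V-like kernel buried in
1/f noise, line harmonics and artifact bursts, so the entire pipeline is
verifiable without access to any recordings.

## Worked example

```r
library(subtrf)

sim  <- gen_session(seed = 11)        # 8 trials x 240 s usable, true peak at 7 ms
prep <- prepare_synthetic(sim)        # predictors at 4096 Hz + EEG preprocessing
fit  <- trf(prep$pairs, prep$session) # polarity-averaged, smoothed, baselined TRF
fit
#> Subcortical TRF (RS predictor), 8 trials of 240.0 s at 4096 Hz
#>   wave V: 7.08 ms, amplitude 0.03831, SNR 14.12 dB (detected)

ev <- loo_evaluate(prep$session, prep$pairs, lengths = 2:8, score = FALSE)
ev[, c("n_trials", "minutes", "snr_db", "latency_ms", "detected")]
#>   n_trials minutes    snr_db latency_ms detected
#> 1        2       8  0.000000   6.835938    FALSE
#> 2        3      12  7.637449   7.080078     TRUE
#> 3        4      16 10.437933   7.080078     TRUE
#> 4        5      20 11.128812   7.080078     TRUE
#> 5        6      24 12.441205   7.080078     TRUE
#> 6        7      28 13.464254   7.080078     TRUE
#> 7        8      32 14.123458   7.080078     TRUE

null_model_score(prep$session, prep$pairs, n_trials = 4)
#> [1] 0.00147872
```

Reading: the generator's 7 ms kernel is recovered at 7.08 ms (the nearest
4096 Hz sample); wave V emerges above the 3 dB detection threshold at
around 12 minutes of data and keeps growing with data length, while the
chance-level prediction correlation of the shift null sits at ~0.001.
`plot(fit)` draws the extracted −10..30 ms TRF with the detected peak
marked; `summary(fit)`, `coef()`, `predict()`, `residuals()` and
`simulate()` behave as for any fitted model. `run_experiment()` runs the
whole multi-participant experiment (evaluation table, Wilcoxon/Holm
statistics, serialized TRFs, reproducibility manifest) from a single JSON
config.

See `vignette("subcortical-trf-methods")` for the model, parameter
defaults, generator design and known limitations.

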