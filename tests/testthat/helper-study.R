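# Simulation study shared across test files: 20 independent synthetic
# sessions at the default study conditions (8 trials x 240 s usable at
# 4096 Hz, default noise), each run through the full analysis pipeline.
# Sessions are expensive, so per-seed results are computed lazily and
# memoized for the duration of the test run.

.study_env <- new.env(parent = emptyenv())

study_one <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.study_env[[key]])) {
    sim <- gen_session(seed = seed)
    prep <- prepare_synthetic(sim)
    sweep <- loo_evaluate(prep$session, prep$pairs, lengths = 2:8,
                          score = FALSE)
    null_r <- null_model_score(prep$session, prep$pairs, n_trials = 4)
    .study_env[[key]] <- list(sweep = sweep, null_r = null_r)
    rm(sim, prep); gc(verbose = FALSE)
  }
  .study_env[[key]]
}

study_results <- function(seeds = 1:20) {
  lapply(seeds, study_one)
}
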