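# End-to-end orchestration: simulate (or load) sessions, build predictors,
# preprocess EEG, fit and evaluate TRFs over data lengths, run group
# statistics, and serialize results with a reproducibility manifest.
# All method constants live in the config with the analysis defaults
# (1 kHz / 1 Hz highpass, 4096 Hz, 30-1000 Hz band, 2 ms smoothing,
# -10..30 ms extraction, 5-10 ms peak search, -500..-20 ms noise range,
# 30/60/90 s shifts, 3 dB threshold).

#' Default run configuration
#'
#' @param ... named overrides of the defaults.
#' @return a validated config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    mode = "simulate",
    participants = 2L,
    seed = 1L,
    n_trials = 8L,
    trial_s = 245,
    raw_rate_hz = 8192,
    eeg_rate_hz = 4096,
    trim_s = c(2, 242),
    kinds = "RS",
    lengths = 2:8,
    null_shifts_s = c(30, 60, 90),
    compute_null = FALSE,
    stim_highpass_hz = 1000,
    eeg_highpass_hz = 1,
    line_hz = 50, notch_max_hz = 1000, notch_width_hz = 5,
    artifact_sd = 5,
    band_hz = c(30, 1000), smooth_ms = 2,
    extract_ms = c(-10, 30), baseline_ms = c(-10, 0),
    peak_ms = c(5, 10), noise_range_ms = c(-500, -20),
    detect_db = 3,
    filterbank = list(f_lo = 80, f_hi = 3500, spacing_erb = 1),
    truth = synthetic_truth(),
    stats_metric = "snr_db",
    contrasts = NULL,
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg config list (e.g. from [default_config()] or [read_config()]).
#' @return the config, invisibly errors otherwise.
#' @export
validate_config <- function(cfg) {
  need <- c("mode", "participants", "seed", "n_trials", "trial_s",
            "raw_rate_hz", "eeg_rate_hz", "kinds", "lengths")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  stopifnot(cfg$mode %in% c("simulate"),
            cfg$eeg_rate_hz > 0, cfg$raw_rate_hz >= 2 * cfg$eeg_rate_hz,
            all(cfg$lengths >= 2),
            all(cfg$kinds %in% c("RS", "GT", "OSS", "OSSA", "EXTERNAL")))
  if (diff(cfg$trim_s) <= 0) stop("empty trim window")
  if (any(cfg$null_shifts_s >= diff(cfg$trim_s)))
    stop("null shift exceeds the trimmed trial length")
  invisible(cfg)
}

#' Read / write a JSON run configuration
#'
#' @param path JSON file path.
#' @return `read_config()`: a validated config list merged over the
#'   defaults.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg config list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Prepare a synthetic session for analysis
#'
#' Runs the full analysis-side preparation on a generated session: stimulus
#' preconditioning, predictor-pair generation at the EEG rate, EEG
#' preprocessing (highpass, notches, downsampling), artifact suppression and
#' trimming, with predictors trimmed to the same window and rescaled to
#' unit variance.
#'
#' @param sim a [gen_session()] result.
#' @param kind predictor model for the analysis (may differ from the
#'   generating model, enabling predictor-mismatch experiments).
#' @param cfg config list (defaults from [default_config()]).
#' @param participant_id identifier stored on the session.
#' @return list with `session` (an [eeg_session()]) and `pairs` (list of
#'   [predictor_pair()], one per trial).
#' @export
prepare_synthetic <- function(sim, kind = "RS", cfg = default_config(),
                              participant_id = "S01") {
  fb <- erb_space(cfg$filterbank$f_lo, cfg$filterbank$f_hi,
                  cfg$filterbank$spacing_erb)
  trials <- vector("list", sim$n_trials)
  pairs <- vector("list", sim$n_trials)
  zeroed <- numeric(sim$n_trials)
  for (i in seq_len(sim$n_trials)) {
    prep <- preprocess_stimulus(sim$stimuli[[i]]$samples, sim$rate_hz,
                                cfg$stim_highpass_hz)
    pp <- make_predictor_pair(polarity_pair(prep), kind, cfg$eeg_rate_hz,
                              spec = fb)
    tr <- preprocess_eeg(sim$eeg_raw[[i]], sim$rate_hz, cfg$eeg_rate_hz,
                         cfg$eeg_highpass_hz, cfg$line_hz, cfg$notch_max_hz,
                         cfg$notch_width_hz, trial_index = i)
    tr <- suppress_artifacts(tr, cfg$artifact_sd)
    tr <- trim_trial(tr, cfg$trim_s[1], cfg$trim_s[2])
    zeroed[i] <- mean(tr$zeroed_mask)
    trim_uv <- function(v) {
      v <- trim_samples(v, cfg$eeg_rate_hz, cfg$trim_s[1], cfg$trim_s[2])
      v / stats::sd(v)
    }
    pairs[[i]] <- structure(list(
      positive = predictor(trim_uv(pp$positive$samples), cfg$eeg_rate_hz,
                           kind, "+", pp$positive$shift),
      negative = predictor(trim_uv(pp$negative$samples), cfg$eeg_rate_hz,
                           kind, "-", pp$negative$shift),
      kind = kind), class = "predictor_pair")
    trials[[i]] <- tr
  }
  session <- eeg_session(trials, participant_id)
  attr(session, "zeroed_fraction") <- zeroed
  list(session = session, pairs = pairs)
}

#' Run a full experiment
#'
#' Simulates one session per participant, runs the leave-one-out
#' evaluation for every predictor kind and data length (optionally with
#' circular-shift null models), applies the group statistics at the
#' longest data length, and (when `cfg$out_dir` is set) serializes the
#' results, statistics, extracted TRFs and a machine-readable manifest.
#'
#' @param cfg config from [default_config()] / [read_config()].
#' @return list with `results` (data.frame), `stats` (data.frame or NULL),
#'   `trfs` (nested list of extracted TRF waveforms), `manifest` (list).
#' @export
run_experiment <- function(cfg = default_config()) {
  validate_config(cfg)
  part_seeds <- cfg$seed + seq_len(cfg$participants) - 1
  trials_per <- rep(cfg$n_trials, cfg$participants)
  if (!is.null(cfg$trials_per_participant))
    trials_per <- rep_len(cfg$trials_per_participant, cfg$participants)
  res <- list(); trfs <- list()
  excluded <- character(0)
  for (p in seq_len(cfg$participants)) {
    pid <- sprintf("S%02d", p)
    sim <- gen_session(trials_per[p], cfg$trial_s, cfg$raw_rate_hz,
                       cfg$truth, seed = part_seeds[p])
    lens <- cfg$lengths[cfg$lengths <= trials_per[p]]
    if (length(lens) < length(cfg$lengths)) excluded <- c(excluded, pid)
    if (length(lens) == 0) next
    for (kind in cfg$kinds) {
      prep <- prepare_synthetic(sim, kind, cfg, pid)
      ev <- loo_evaluate(prep$session, prep$pairs, lens,
                         shifts_s = if (isTRUE(cfg$compute_null)) cfg$null_shifts_s,
                         band_hz = cfg$band_hz, smooth_ms = cfg$smooth_ms,
                         extract_ms = cfg$extract_ms,
                         baseline_ms = cfg$baseline_ms)
      ev <- cbind(participant = pid, kind = kind, ev)
      res[[length(res) + 1]] <- ev
      trfs[[pid]][[kind]] <- attr(ev, "trfs")
    }
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  stats_df <- NULL
  full_len <- max(cfg$lengths)
  at_full <- results[results$n_trials == full_len &
                       !(results$participant %in% excluded), ]
  if (length(unique(at_full$kind)) >= 2 &&
      length(unique(at_full$participant)) >= 5) {
    stats_df <- compare_predictors(at_full, cfg$stats_metric, cfg$contrasts)
  }
  manifest <- list(
    package = "subtrf",
    version = as.character(utils::packageVersion("subtrf")),
    r_version = R.version.string,
    seed = cfg$seed,
    participants = cfg$participants,
    excluded_participants = excluded,
    config_hash = config_hash(cfg),
    n_results = nrow(results)
  )
  bundle <- list(results = results, stats = stats_df, trfs = trfs,
                 manifest = manifest, config = cfg)
  if (!is.null(cfg$out_dir)) serialize_results(bundle, cfg$out_dir)
  bundle
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  js <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' Serialize a results bundle
#'
#' Writes `results.csv`, `stats.csv` (when present), one CSV per extracted
#' TRF under `trf/`, `config.json` and `manifest.json`. Numeric fields are
#' written at full precision, so a write-read-write cycle is lossless.
#'
#' @param bundle output of [run_experiment()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
serialize_results <- function(bundle, out_dir) {
  if (is.null(bundle$results) || is.null(bundle$manifest))
    stop("incomplete bundle")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "trf"), showWarnings = FALSE)
  write_full_csv(bundle$results, file.path(out_dir, "results.csv"))
  if (!is.null(bundle$stats))
    write_full_csv(bundle$stats, file.path(out_dir, "stats.csv"))
  for (pid in names(bundle$trfs)) {
    for (kind in names(bundle$trfs[[pid]])) {
      for (li in seq_along(bundle$trfs[[pid]][[kind]])) {
        w <- bundle$trfs[[pid]][[kind]][[li]]
        write_full_csv(
          data.frame(lag_ms = w$lag_ms, coef = w$coef),
          file.path(out_dir, "trf",
                    sprintf("%s_%s_len%d.csv", pid, kind, li)))
      }
    }
  }
  write_config(bundle$config, file.path(out_dir, "config.json"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# full-precision CSV (numbers via format with 17 significant digits)
write_full_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format(out[[j]], digits = 17, trim = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
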