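#' Write a session container to disk
#'
#' The container is a directory with `meta.json` (sampling rates, units,
#' trial geometry, seed), raw little-endian 32-bit float arrays `eeg.f32`
#' and `unit.f32` (row-major by trial), `spikes.csv` (columns `cell_id`,
#' `trial`, `time_ms`) and, when ground truth is present, `truth.json`.
#'
#' @param session A `"session"`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    n_trials = nrow(session$eeg),
    n_samples_eeg = ncol(session$eeg),
    n_samples_unit = ncol(session$unit),
    fs_eeg = session$fs_eeg, fs_unit = session$fs_unit,
    trial_length_ms = session$trial_length,
    stim_time_ms = session$stim_time,
    units = list(eeg = "nV", unit = "uV"),
    rng_seed = session$config$rng_seed)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_f32 <- function(m, f) {
    con <- file(file.path(path, f), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  write_f32(session$eeg, "eeg.f32")
  write_f32(session$unit, "unit.f32")
  utils::write.csv(as_spike_df(session$spikes),
                   file.path(path, "spikes.csv"), row.names = FALSE)
  if (!is.null(session$truth)) {
    tr <- list(depth_mm = session$truth$depth_mm)
    if (!is.null(session$truth$kernel))
      tr$kernel <- list(a_sta = session$truth$kernel$a_sta,
                        b_sta = session$truth$kernel$b_sta,
                        t_sta = session$truth$kernel$t_sta)
    jsonlite::write_json(tr, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session container from disk
#'
#' @param path Directory written by [write_session()].
#' @return A `"session"` (the `config` field holds only the stored
#'   metadata; spike times in `spikes` are those stored in `spikes.csv`).
#' @export
read_session <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing session file: ", f)
    fp
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  read_f32 <- function(f, nr, nc, what) {
    fp <- need(f)
    v <- readBin(fp, numeric(), n = file.size(fp) / 4 + 16, size = 4,
                 endian = "little")
    if (length(v) != nr * nc)
      stop(sprintf("%s: array length %d inconsistent with metadata (%d x %d)",
                   what, length(v), nr, nc))
    matrix(v, nrow = nr, byrow = TRUE)
  }
  exp_eeg <- floor(meta$trial_length_ms * meta$fs_eeg / 1000)
  if (meta$n_samples_eeg != exp_eeg)
    stop("metadata inconsistent: EEG sample count does not match ",
         "trial length and sampling rate")
  eeg <- read_f32("eeg.f32", meta$n_trials, meta$n_samples_eeg, "eeg.f32")
  unit <- read_f32("unit.f32", meta$n_trials, meta$n_samples_unit, "unit.f32")
  spikes_df <- utils::read.csv(need("spikes.csv"))
  spikes <- spike_train_from_df(spikes_df, n_trials = meta$n_trials)
  truth <- NULL
  tp <- file.path(path, "truth.json")
  if (file.exists(tp)) {
    tj <- jsonlite::read_json(tp, simplifyVector = TRUE)
    truth <- list(depth_mm = tj$depth_mm, spikes = spikes)
    if (!is.null(tj$kernel))
      truth$kernel <- mexican_hat(tj$kernel$a_sta, tj$kernel$b_sta,
                                  tj$kernel$t_sta)
  }
  structure(
    list(eeg = eeg, unit = unit, fs_eeg = meta$fs_eeg,
         fs_unit = meta$fs_unit, stim_time = meta$stim_time_ms,
         trial_length = meta$trial_length_ms, spikes = spikes,
         truth = truth, config = list(rng_seed = meta$rng_seed)),
    class = "session")
}

#' Analysis presets for the two EEG bands
#'
#' The high-frequency preset filters 800-3000 Hz, uses a +/-3 ms STA
#' window and prunes spikes closer than 6 ms; the wideband preset filters
#' 3-3000 Hz with +/-15 ms windows and 30 ms pruning.
#'
#' @param name `"high_frequency"` or `"wideband"`.
#' @return A list with `filter` (a `"filter_spec"`), `half_window` (ms)
#'   and `min_isi` (ms).
#' @export
band_preset <- function(name) {
  switch(name,
         high_frequency = list(filter = hf_band(), half_window = 3,
                               min_isi = 6, baseline_correct = TRUE),
         wideband = list(filter = wideband(), half_window = 15,
                         min_isi = 30, baseline_correct = TRUE),
         stop("unknown band preset: ", name))
}

#' Run the full spike-triggered EEG analysis pipeline
#'
#' Orchestrates the analysis stages on a synthetic or stored session:
#' band-pass filter each trial, upsample to 10 kHz, prune spikes by the
#' preset minimum separation, extract segments, average, compute the
#' shift predictor and 99% confidence band, baseline-correct, run the
#' bootstrap peak test, estimate spectra, evaluate the closed-form
#' correlated-population model (on a Mexican hat fitted to the STA when
#' the fit succeeds) and the dipole forward model. All randomness derives
#' from `seed`, so reports are reproducible.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `session` (a `"session"`, a `"session_config"`, or a path to a
#'   session container), `preset` (`"high_frequency"` or `"wideband"`,
#'   default high-frequency), `seed` (integer, default 1), `n_shuffles`
#'   (default 100), `n_boot` (default 5000), `use_truth_spikes` (default
#'   `TRUE`; otherwise spikes are detected from the unit channel),
#'   `correlation` (list `A_xcf`, `T_xcf`, `N`) and `dipole` (list `Q_lo`,
#'   `Q_hi`, `eta`, `theta`, `h`, `d`).
#' @return An `"analysis_report"`: a nested list of per-stage results
#'   (each enabled stage contributes a section; a failing stage records
#'   its error message without discarding earlier results).
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(preset = "high_frequency", seed = 1L, n_shuffles = 100,
         n_boot = 5000, use_truth_spikes = TRUE,
         correlation = list(A_xcf = 0.008, T_xcf = 17, N = 1e7),
         dipole = list(Q_lo = 0.78, Q_hi = 2.97, eta = 2.47, theta = 0,
                       h = 2.18, d = 10)),
    config)
  preset <- band_preset(cfg$preset)
  report <- list(config = cfg[setdiff(names(cfg), "session")],
                 preset = cfg$preset, seed = cfg$seed)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      list(error = conditionMessage(e), stage = name))
    report[[name]] <<- res
    res
  }

  session <- cfg$session
  if (inherits(session, "session_config")) {
    if (is.null(session$rng_seed)) session$rng_seed <- cfg$seed
    session <- simulate_session(session)
  } else if (is.character(session)) {
    session <- read_session(session)
  }
  stopifnot(inherits(session, "session"))
  report$session <- list(n_trials = nrow(session$eeg),
                         trial_length_ms = session$trial_length,
                         fs_eeg = session$fs_eeg)

  spikes <- if (isTRUE(cfg$use_truth_spikes)) session$spikes
            else detect_session_spikes(session)
  pruned <- prune_train(spikes, preset$min_isi)
  report$spikes <- list(n_spikes = n_spikes(spikes),
                        n_pruned = n_spikes(pruned),
                        isi_violation = isTRUE(spikes$qc$isi_violation))

  filtered <- filter_trials(session$eeg, session$fs_eeg, preset$filter)
  up <- upsample_trials(filtered, session$fs_eeg, 10000)
  seg <- extract_segments(up, pruned, preset$half_window, 10000)
  if (nrow(seg) == 0) stop("no retainable spikes after pruning")
  sta <- eeg_sta(seg)
  pred <- shift_predictor(up, pruned, preset$half_window, 10000,
                          n_shuffles = cfg$n_shuffles, seed = cfg$seed,
                          keep_segments = TRUE)
  pred <- confidence_band(pred)
  corrected <- if (isTRUE(preset$baseline_correct))
    baseline_correct(sta, pred) else sta
  test <- peak_bootstrap_test(seg, pred$segments, n_boot = cfg$n_boot,
                              seed = cfg$seed + 1L)
  report$sta <- list(
    n_segments = sta$n_segments,
    p2p_nV = peak_to_peak(corrected),
    predictor_p2p_nV = peak_to_peak(pred),
    band_halfwidth_nV = 2.58 * stats::median(pred$sem),
    p_value = test$p,
    waveform = data.frame(lag_ms = corrected$lags, mean_nV = corrected$mean,
                          sem_nV = corrected$sem))

  stage("spectral", {
    sb <- spectral_bootstrap_test(seg, pred$segments, fs = 10000,
                                  n_boot = min(cfg$n_boot, 500),
                                  seed = cfg$seed + 2L)
    list(freqs_hz = sb$freqs, power = sb$observed, p = sb$p)
  })

  stage("correlation_model", {
    hat <- tryCatch(fit_mexican_hat(corrected$mean, corrected$lags),
                    error = function(e) session$truth$kernel)
    if (is.null(hat)) stop("no Mexican-hat kernel available")
    cs <- correlation_sta_closed_form(
      hat, gaussian_from_peak_width(cfg$correlation$A_xcf,
                                    cfg$correlation$T_xcf),
      cfg$correlation$N)
    list(A_STA_nV = hat$A_STA, T_STA_ms = hat$T_STA,
         A_cSTA_nV = cs$A_cSTA, T_cSTA_ms = cs$T_cSTA)
  })

  stage("dipole", {
    dp <- cfg$dipole
    r <- electrode_distance(dp$h, dp$d)
    V <- dipole_potential(c(dp$Q_lo, dp$Q_hi), dp$eta, dp$theta, r = r)
    list(r_mm = r, V_nV = V, V_nV_trunc = trunc(V),
         scalp_nV = scalp_extrapolation(V[1], V[2]))
  })

  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Spike-triggered EEG analysis report\n")
  cat(sprintf("  preset: %s, seed: %s\n", x$preset, x$seed))
  if (!is.null(x$spikes))
    cat(sprintf("  spikes: %d (%d after pruning)\n",
                x$spikes$n_spikes, x$spikes$n_pruned))
  if (!is.null(x$sta) && is.null(x$sta$error))
    cat(sprintf("  EEG-STA: %d segments, p2p %.1f nV, p = %.4g\n",
                x$sta$n_segments, x$sta$p2p_nV, x$sta$p_value))
  if (!is.null(x$correlation_model) && is.null(x$correlation_model$error))
    cat(sprintf("  correlation model: A_cSTA %.3g nV, T_cSTA %.3g ms\n",
                x$correlation_model$A_cSTA_nV, x$correlation_model$T_cSTA_ms))
  if (!is.null(x$dipole) && is.null(x$dipole$error))
    cat(sprintf("  dipole: r %.3f mm, V %.1f-%.1f nV\n",
                x$dipole$r_mm, x$dipole$V_nV[1], x$dipole$V_nV[2]))
  invisible(x)
}
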