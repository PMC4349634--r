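# shared fixtures and independent oracles, all built in code

# noise-only session in the high-frequency regime (no kernel, no SEP)
make_noise_session <- function(seed, n_trials = 40, trial_length = 250,
                               rate = 35, noise_sd_hf = 700) {
  cfg <- session_config(
    n_trials = n_trials, trial_length = trial_length, kernel = NULL,
    psth_profile = rate, sep_template = NULL, noise_sd_hf = noise_sd_hf,
    unit_noise_sd_uV = 0, spike_amp_uV = 0, rng_seed = seed)
  simulate_session(cfg)
}

# kernel-bearing session; kernel scaled so the in-band embedded
# peak-to-peak equals `target_p2p` on the 10 kHz analysis grid
make_kernel_session <- function(seed, target_p2p = 400, n_trials = 250,
                                trial_length = 400, rate = 30,
                                noise_sd_hf = 700, spikes = NULL) {
  k <- calibrated_kernel(target_p2p)
  cfg <- session_config(
    n_trials = n_trials, trial_length = trial_length, kernel = k,
    psth_profile = rate, sep_template = NULL, noise_sd_hf = noise_sd_hf,
    unit_noise_sd_uV = 0, spike_amp_uV = 0, spikes = spikes,
    rng_seed = seed)
  simulate_session(cfg)
}

# Mexican hat (T = 0.45 ms, t0 = 0.05 ms) whose in-band (800-3000 Hz)
# embedded waveform has exactly the requested peak-to-peak; the embedding
# chain is linear in the kernel amplitude, so a single calibration run
# suffices. Cached across tests.
calibrated_kernel <- local({
  cache <- list()
  function(target_p2p = 400) {
    key <- sprintf("%.6g", target_p2p)
    if (is.null(cache[[key]])) {
      base <- mexhat_from_amp_width(60, 0.45, 0.05)
      p2p0 <- peak_to_peak(embedded_kernel_sta(base))
      cache[[key]] <<- mexhat_from_amp_width(60 * target_p2p / p2p0,
                                             0.45, 0.05)
    }
    cache[[key]]
  }
})

# high-frequency STA analysis chain: filter, upsample, prune, extract
hf_chain <- function(session, min_isi = 6, half_window = 3) {
  pruned <- prune_train(session$spikes, min_isi)
  up <- upsample_trials(filter_trials(session$eeg, session$fs_eeg, hf_band()),
                        session$fs_eeg, 10000)
  list(up = up, pruned = pruned,
       segments = extract_segments(up, pruned, half_window, 10000))
}

# independent oracle: discrete-grid convolution N * (f_xcf o g_STA), with
# rates converted to 1/ms; spectrally accurate for dt well below the
# Gaussian widths
conv_oracle <- function(hat, xcf, N, t_eval) {
  width <- sqrt(xcf$b_xcf + hat$b_sta)
  dt <- min(sqrt(hat$b_sta), sqrt(xcf$b_xcf)) / 20
  support <- 8 * width + max(abs(t_eval)) + abs(hat$t_sta)
  tg <- seq(-support, support, by = dt)
  f <- (xcf$a_xcf / 1000) * exp(-tg^2 / xcf$b_xcf)
  out <- vapply(t_eval, function(t0)
    sum(f * mexhat_eval(hat, t0 - tg)) * dt, numeric(1))
  N * out
}
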