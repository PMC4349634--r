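#' Configuration of a synthetic recording session
#'
#' Describes a simulated session of simultaneous epidural-EEG and
#' micro-electrode recording under repetitive peripheral stimulation. The
#' defaults emulate the regime of awake-primate somatosensory sessions:
#' about a thousand stimulation trials at 3 Hz (333 ms trials), EEG sampled
#' at 6 kHz band-limited to 3-3000 Hz with about 700 nV of noise in the
#' 800-3000 Hz band, a micro-electrode channel at 24 kHz, a triphasic
#' per-spike EEG kernel of tens of nanovolts, and a firing profile with an
#' early driven response and a stationary late window.
#'
#' @param n_trials Number of trials (>= 1).
#' @param trial_length Trial duration in ms.
#' @param fs_eeg EEG sampling rate in Hz (default 6000).
#' @param fs_unit Micro-electrode sampling rate in Hz (default 24000).
#' @param stim_time Stimulus onset in ms within the trial (default 0; spike
#'   times and the SEP template are expressed relative to it).
#' @param noise_sd_hf EEG noise standard deviation in nV within the
#'   800-3000 Hz band (default 700). The generated noise is white noise
#'   band-passed to 3-3000 Hz and scaled so its 800-3000 Hz component has
#'   exactly this SD in expectation.
#' @param kernel A `"mexican_hat"` per-spike EEG kernel (nV), or `NULL` for
#'   no spike contribution to the EEG.
#' @param psth_profile Firing-rate profile in spikes/s: a single number
#'   (constant rate), a function of time in ms, or a data.frame with
#'   columns `time_ms` and `rate_hz` (linearly interpolated).
#' @param sep_template Evoked wideband EEG waveform in nV added to every
#'   trial starting at `stim_time`, as a numeric vector sampled at
#'   `fs_eeg`; `NULL` for none.
#' @param refractory Absolute refractory period in ms (default 1).
#' @param spike_amp_uV Peak amplitude of the stereotyped extracellular
#'   spike waveform on the unit channel (uV).
#' @param unit_noise_sd_uV Gaussian noise SD on the unit channel (uV).
#' @param kernel_halfwidth Half-support of the sampled EEG kernel in ms
#'   (default 3, matching the high-frequency analysis window).
#' @param depth_mm Recorded ground-truth cell depth in mm (default 2.18).
#' @param spikes Optional `"spike_train"` to embed instead of simulating
#'   one from `psth_profile` (useful for building matched noiseless /
#'   noisy session pairs with identical spike times).
#' @param rng_seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `"session_config"`.
#' @export
session_config <- function(n_trials = 1000,
                           trial_length = 333,
                           fs_eeg = 6000,
                           fs_unit = 24000,
                           stim_time = 0,
                           noise_sd_hf = 700,
                           kernel = mexhat_from_amp_width(60, 0.45, 0.05),
                           psth_profile = evoked_psth_profile(),
                           sep_template = default_sep_template(fs_eeg),
                           refractory = 1,
                           spike_amp_uV = 300,
                           unit_noise_sd_uV = 25,
                           kernel_halfwidth = 3,
                           depth_mm = 2.18,
                           spikes = NULL,
                           rng_seed = NULL) {
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be >= 1")
  if (fs_eeg <= 0 || fs_unit <= 0) stop("sampling rates must be positive")
  if (trial_length <= 0) stop("trial_length must be positive")
  if (noise_sd_hf < 0) stop("noise_sd_hf must be nonnegative")
  if (!is.null(kernel)) stopifnot(inherits(kernel, "mexican_hat"))
  if (2 * kernel_halfwidth >= trial_length)
    stop("kernel support exceeds the trial length")
  if (!is.null(spikes)) stopifnot(inherits(spikes, "spike_train"))
  structure(
    list(n_trials = as.integer(n_trials), trial_length = trial_length,
         fs_eeg = fs_eeg, fs_unit = fs_unit, stim_time = stim_time,
         noise_sd_hf = noise_sd_hf, kernel = kernel,
         psth_profile = psth_profile, sep_template = sep_template,
         refractory = refractory, spike_amp_uV = spike_amp_uV,
         unit_noise_sd_uV = unit_noise_sd_uV,
         kernel_halfwidth = kernel_halfwidth, depth_mm = depth_mm,
         spikes = spikes, rng_seed = rng_seed),
    class = "session_config")
}

#' Evoked firing-rate profile with a high-frequency burst
#'
#' Builds a rate profile (spikes/s as a function of post-stimulus time in
#' ms) with an early driven response between 5 and 50 ms containing a comb
#' of sharp peaks repeating at `comb_freq` between `burst_window`, and a
#' constant stationary rate in the late window. The comb emulates the
#' ~600 Hz repetition of driven spike volleys during the evoked
#' high-frequency EEG burst.
#'
#' @param base_rate Baseline rate in spikes/s.
#' @param early_rate Peak of the decaying early driven response, spikes/s.
#' @param early_window Early response window in ms.
#' @param burst_rate Amplitude of each comb peak, spikes/s.
#' @param burst_window Window containing the comb peaks, ms.
#' @param comb_freq Repetition frequency of the comb peaks in Hz.
#' @param peak_sd Gaussian SD of each comb peak in ms.
#' @param late_rate Constant rate in the late window, spikes/s.
#' @param late_window Late (stationary) window in ms.
#' @return A function of time (ms) returning rate in spikes/s.
#' @export
evoked_psth_profile <- function(base_rate = 5, early_rate = 60,
                                early_window = c(5, 50),
                                burst_rate = 400, burst_window = c(8, 18),
                                comb_freq = 600, peak_sd = 0.25,
                                late_rate = 20, late_window = c(200, 290)) {
  period <- 1000 / comb_freq
  peaks <- seq(burst_window[1], burst_window[2], by = period)
  force(base_rate); force(early_rate); force(late_rate)
  function(t) {
    r <- rep(base_rate, length(t))
    early <- t >= early_window[1] & t <= early_window[2]
    r[early] <- r[early] +
      early_rate * exp(-(t[early] - early_window[1]) / 15)
    for (p in peaks)
      r <- r + burst_rate * exp(-(t - p)^2 / (2 * peak_sd^2))
    late <- t >= late_window[1] & t <= late_window[2]
    r[late] <- late_rate
    r
  }
}

#' Default evoked wideband EEG template
#'
#' A stylized somatosensory evoked potential: a damped low-frequency wave
#' (amplitude ~20 uV) plus a small high-frequency burst at 8-18 ms
#' post-stimulus riding on its rising flank.
#'
#' @param fs_eeg Sampling rate in Hz.
#' @param duration Template duration in ms.
#' @param sep_amp_nV Amplitude of the slow evoked wave in nV.
#' @param burst_amp_nV Amplitude of the high-frequency burst in nV.
#' @return Numeric vector in nV sampled at `fs_eeg`.
#' @export
default_sep_template <- function(fs_eeg = 6000, duration = 80,
                                 sep_amp_nV = 20000, burst_amp_nV = 1000) {
  t <- seq(0, duration, by = 1000 / fs_eeg)
  slow <- sep_amp_nV * sin(2 * pi * (t - 8) / 30) *
    exp(-(t - 15)^2 / (2 * 12^2)) * (t > 8)
  burst <- burst_amp_nV * sin(2 * pi * 600 * t / 1000) *
    exp(-(t - 13)^2 / (2 * 2.5^2))
  slow + burst
}

eval_rate_profile <- function(profile, t) {
  r <- if (is.function(profile)) {
    profile(t)
  } else if (is.data.frame(profile)) {
    stopifnot(all(c("time_ms", "rate_hz") %in% names(profile)))
    stats::approx(profile$time_ms, profile$rate_hz, xout = t, rule = 2)$y
  } else if (is.numeric(profile) && length(profile) == 1L) {
    rep(profile, length(t))
  } else {
    stop("psth_profile must be a number, function or data.frame")
  }
  if (any(r < 0)) stop("firing-rate profile must be nonnegative")
  r
}

#' Simulate spike trains from a rate profile
#'
#' Draws inhomogeneous-Poisson spikes on the micro-electrode sampling grid
#' (thinning on a fine time grid) and enforces an absolute refractory period
#' by deleting the later spike of any pair closer than `refractory`.
#'
#' @param psth_profile Rate profile in spikes/s (see [session_config()]).
#' @param n_trials Number of trials.
#' @param trial_length Trial duration in ms.
#' @param refractory Absolute refractory period in ms (>= 0).
#' @param fs_grid Sampling grid for spike times in Hz (default 24000).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `"spike_train"`.
#' @export
simulate_spike_trains <- function(psth_profile, n_trials, trial_length,
                                  refractory = 1, fs_grid = 24000,
                                  seed = NULL) {
  if (refractory < 0) stop("refractory must be nonnegative")
  if (!is.null(seed)) withr::local_seed(seed)
  dt_ms <- 1000 / fs_grid
  grid <- seq(0, trial_length - dt_ms, by = dt_ms)
  rate <- eval_rate_profile(psth_profile, grid)
  p <- rate * dt_ms / 1000
  if (any(p > 1)) stop("rate too high for the simulation grid")
  nb <- length(grid)
  times <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    hit <- stats::runif(nb) < p
    tt <- grid[hit]
    if (refractory > 0 && length(tt) > 1) {
      keep <- logical(length(tt))
      last <- -Inf
      for (i in seq_along(tt)) {
        if (tt[i] - last >= refractory) {
          keep[i] <- TRUE
          last <- tt[i]
        }
      }
      tt <- tt[keep]
    }
    times[[tr]] <- tt
  }
  spike_train(times)
}

# Stereotyped biphasic extracellular spike waveform (negative peak first),
# sampled at fs; returns list(offsets in samples relative to the negative
# peak, values scaled to unit negative peak).
spike_waveform_template <- function(fs) {
  t <- seq(-0.6, 1.0, by = 1000 / fs)  # ms around the negative peak
  w <- -exp(-t^2 / (2 * 0.1^2)) + 0.45 * exp(-(t - 0.45)^2 / (2 * 0.22^2))
  list(offsets = round(t * fs / 1000), values = w)
}

#' Simulate a full synthetic session
#'
#' Generates per-trial EEG (nV) and micro-electrode (uV) arrays with the
#' generative structure the analysis chain assumes: the EEG is band-limited
#' noise (3-3000 Hz, scaled so its 800-3000 Hz component has SD
#' `noise_sd_hf`), plus the evoked template at the stimulus time, plus one
#' copy of the per-spike kernel inserted at every true spike time. The
#' kernel is sampled at the EEG rate and inserted with fractional delay via
#' linear interpolation, so no sub-sample structure beyond linear
#' interpolation is implied. The unit channel holds Gaussian noise plus a
#' stereotyped biphasic spike waveform at each spike. Ground truth (spike
#' times, kernel, depth) is recorded in the `truth` field.
#'
#' @param config A `"session_config"`.
#' @return An object of class `"session"`: a list with `eeg`
#'   (trials x samples, nV), `unit` (trials x samples, uV), `fs_eeg`,
#'   `fs_unit`, `stim_time`, `trial_length`, `spikes` (a `"spike_train"`),
#'   `truth` and `config`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$rng_seed)) withr::local_seed(config$rng_seed)
  n_tr <- config$n_trials
  fs_e <- config$fs_eeg
  n_eeg <- floor(config$trial_length * fs_e / 1000)
  n_unit <- floor(config$trial_length * config$fs_unit / 1000)

  spikes <- if (!is.null(config$spikes)) {
    if (config$spikes$n_trials != n_tr)
      stop("supplied spike train does not match n_trials")
    config$spikes
  } else {
    simulate_spike_trains(config$psth_profile, n_tr, config$trial_length,
                          config$refractory, fs_grid = config$fs_unit)
  }

  # EEG noise: white -> wideband; scale fixed so the HF band has the
  # configured SD in expectation (computed from the exact filter masks).
  wide <- wideband()
  freqs <- dft_freqs(n_eeg, fs_e)
  m_wide <- band_mask(freqs, wide)
  m_hf <- band_mask(freqs, hf_band())
  gain_hf <- sqrt(mean((m_wide * m_hf)^2))
  sigma_w <- if (config$noise_sd_hf > 0) config$noise_sd_hf / gain_hf else 0
  eeg <- if (sigma_w > 0) {
    filter_trials(matrix(stats::rnorm(n_tr * n_eeg, sd = sigma_w),
                         nrow = n_tr), fs_e, wide)
  } else {
    matrix(0, n_tr, n_eeg)
  }

  if (!is.null(config$sep_template)) {
    s0 <- floor(config$stim_time * fs_e / 1000) + 1L
    len <- min(length(config$sep_template), n_eeg - s0 + 1L)
    if (len > 0)
      eeg[, s0:(s0 + len - 1L)] <- eeg[, s0:(s0 + len - 1L)] +
        rep(config$sep_template[seq_len(len)], each = n_tr)
  }

  if (!is.null(config$kernel)) {
    hw <- config$kernel_halfwidth
    k_lags <- seq(-hw, hw, by = 1000 / fs_e)
    k_vals <- mexhat_eval(config$kernel, k_lags)
    for (tr in seq_len(n_tr)) {
      for (t0 in spikes$times[[tr]]) {
        j1 <- max(1L, ceiling((t0 - hw) * fs_e / 1000) + 1L)
        j2 <- min(n_eeg, floor((t0 + hw) * fs_e / 1000) + 1L)
        if (j1 > j2) next
        lag <- (j1:j2 - 1L) * 1000 / fs_e - t0
        eeg[tr, j1:j2] <- eeg[tr, j1:j2] +
          stats::approx(k_lags, k_vals, xout = lag, yleft = 0, yright = 0)$y
      }
    }
  }

  unit <- matrix(if (config$unit_noise_sd_uV > 0)
    stats::rnorm(n_tr * n_unit, sd = config$unit_noise_sd_uV) else 0,
    nrow = n_tr, ncol = n_unit)
  wf <- spike_waveform_template(config$fs_unit)
  for (tr in seq_len(n_tr)) {
    ctr <- round(spikes$times[[tr]] * config$fs_unit / 1000) + 1L
    for (c0 in ctr) {
      j <- c0 + wf$offsets
      ok <- j >= 1 & j <= n_unit
      unit[tr, j[ok]] <- unit[tr, j[ok]] + config$spike_amp_uV * wf$values[ok]
    }
  }

  structure(
    list(eeg = eeg, unit = unit, fs_eeg = fs_e, fs_unit = config$fs_unit,
         stim_time = config$stim_time, trial_length = config$trial_length,
         spikes = spikes,
         truth = list(spikes = spikes, kernel = config$kernel,
                      depth_mm = config$depth_mm),
         config = config),
    class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf(
    "Synthetic session: %d trials x %.0f ms, EEG %g Hz, unit %g Hz, %d spikes\n",
    nrow(x$eeg), x$trial_length, x$fs_eeg, x$fs_unit, n_spikes(x$spikes)))
  invisible(x)
}

#' Expected in-band embedded kernel waveform
#'
#' Computes, deterministically, the waveform the spike-triggered average
#' converges to for a given per-spike kernel: the kernel is embedded in a
#' noiseless session at every spike phase the micro-electrode grid allows
#' relative to the EEG grid, passed through the same filter / upsample /
#' extract chain as real data, and averaged. Sampling at the EEG rate and
#' band-pass filtering attenuate a sub-millisecond kernel, so this
#' "effective" waveform - not the analytic Mexican hat - is the correct
#' recovery target for the pipeline.
#'
#' @param kernel A `"mexican_hat"` kernel (nV).
#' @param fs_eeg,fs_unit EEG and spike-grid sampling rates in Hz.
#' @param fs_sta Analysis rate in Hz (default 10000).
#' @param half_window STA half window in ms.
#' @param filter Optional `"filter_spec"` applied before extraction
#'   (default the 800-3000 Hz preset); `NULL` for none.
#' @return An `"sta"` holding the expected embedded waveform.
#' @export
embedded_kernel_sta <- function(kernel, fs_eeg = 6000, fs_unit = 24000,
                                fs_sta = 10000, half_window = 3,
                                filter = hf_band()) {
  n_phase <- max(1L, round(fs_unit / fs_eeg))
  spacing <- 8 * half_window
  t0 <- spacing * seq_len(n_phase) + (seq_len(n_phase) - 1) * 1000 / fs_unit
  trial_len <- spacing * (n_phase + 1)
  cfg <- session_config(
    n_trials = 1, trial_length = trial_len, fs_eeg = fs_eeg,
    fs_unit = fs_unit, noise_sd_hf = 0, kernel = kernel,
    psth_profile = 0, sep_template = NULL, unit_noise_sd_uV = 0,
    spikes = spike_train(list(t0)), kernel_halfwidth = half_window)
  ses <- simulate_session(cfg)
  eeg <- if (!is.null(filter)) filter_trials(ses$eeg, fs_eeg, filter)
         else ses$eeg
  up <- upsample_trials(eeg, fs_eeg, fs_sta)
  eeg_sta(extract_segments(up, ses$spikes, half_window, fs_sta))
}

#' Simulate a pair of spike trains with Gaussian cross-correlation
#'
#' Generates two stationary Poisson trains of equal rate sharing a common
#' pool of "mother" events; each shared event is inserted into both trains
#' with independent Gaussian jitter. The resulting excess cross-correlogram
#' is Gaussian with peak approximately `A_xcf` (coincidences/s) and
#' half-amplitude width approximately `T_xcf` (ms).
#'
#' @param rate Firing rate of each train in spikes/s.
#' @param A_xcf Desired cross-correlogram peak excess in coincidences/s.
#' @param T_xcf Desired half-amplitude width (jitter) in ms.
#' @param duration Recording duration in s.
#' @param seed Optional integer seed.
#' @return A list with `train1`, `train2` (sorted spike times in ms),
#'   `shared_rate` (rate of shared events, spikes/s) and `jitter_sd_ms`.
#' @export
simulate_correlated_pair <- function(rate, A_xcf, T_xcf, duration,
                                     seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  if (A_xcf < 0) stop("A_xcf must be nonnegative")
  if (T_xcf <= 0) stop("T_xcf must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  sigma_ms <- T_xcf / (4 * sqrt(log(2)))
  frac <- A_xcf * sqrt(4 * pi) * (sigma_ms / 1000)
  if (frac > 1)
    stop("infeasible A_xcf: implied shared-event rate exceeds the firing rate")
  r_sh <- frac * rate
  dur_ms <- duration * 1000
  shared <- stats::runif(stats::rpois(1, r_sh * duration), 0, dur_ms)
  one_train <- function() {
    ind <- stats::runif(stats::rpois(1, (rate - r_sh) * duration), 0, dur_ms)
    tt <- c(ind, shared + stats::rnorm(length(shared), sd = sigma_ms))
    sort(tt[tt >= 0 & tt <= dur_ms])
  }
  list(train1 = one_train(), train2 = one_train(),
       shared_rate = r_sh, jitter_sd_ms = sigma_ms)
}

#' Empirical cross-correlogram of two spike trains
#'
#' Conditional rate of train-2 spikes around train-1 spikes, in spikes/s
#' per lag bin (uncorrected for the baseline rate).
#'
#' @param t1,t2 Sorted spike times in ms.
#' @param bin_ms Lag bin width in ms.
#' @param max_lag_ms Maximum |lag| in ms.
#' @return A data.frame with columns `lag_ms` (bin centres) and `rate`
#'   (coincidences/s per trigger spike).
#' @export
cross_correlogram <- function(t1, t2, bin_ms = 1, max_lag_ms = 50) {
  edges <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  lo <- findInterval(t1 - max_lag_ms, t2)
  hi <- findInterval(t1 + max_lag_ms, t2)
  cnt <- hi - lo
  if (sum(cnt) == 0) {
    counts <- rep(0, length(edges) - 1)
  } else {
    idx <- sequence(cnt) + rep(lo, cnt)
    lags <- t2[idx] - rep(t1, cnt)
    counts <- graphics::hist(lags, breaks = edges, plot = FALSE)$counts
  }
  data.frame(lag_ms = edges[-length(edges)] + bin_ms / 2,
             rate = counts / (length(t1) * bin_ms / 1000))
}
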