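make_psth <- function(rate, bin_width = 0.1, t0 = 0) {
  structure(list(
    bin_edges = t0 + seq(0, length(rate) * bin_width, by = bin_width),
    rate = rate, bin_width = bin_width, n_trials = 1L), class = "psth")
}

make_sta <- function(mean, fs = 10000, half_window = 3) {
  hw <- round(half_window * fs / 1000)
  new_sta((-hw:hw) / fs * 1000, mean, rep(0, length(mean)), 100)
}

test_that("burst prediction is a correctly aligned convolution and linear", {
  hat <- mexhat_from_amp_width(60, 0.45, 0.05)
  lags <- seq(-3, 3, by = 0.1)
  kern <- mexhat_eval(hat, lags)
  sta <- make_sta(kern)

  # single unit-mass bin at t0: prediction is the kernel shifted to t0
  rate <- rep(0, 400)
  rate[200] <- 1  # bin centred at 19.95 ms
  p <- predict_burst(make_psth(rate), sta)
  expect_equal(p$time[200], 19.95)
  expect_equal(p$mean[200 + (-30:30)], kern, tolerance = 1e-9)
  expect_lt(max(abs(p$mean[1:150])), 1e-9)

  # two identical cells average to the single-cell prediction
  p2 <- predict_burst(list(make_psth(rate), make_psth(rate)),
                      list(sta, sta))
  expect_equal(p2$mean, p$mean, tolerance = 1e-12)
  expect_equal(p2$n_cells, 2)

  # linearity: doubling every PSTH doubles the prediction
  pd <- predict_burst(make_psth(2 * rate), sta)
  expect_equal(pd$mean, 2 * p$mean, tolerance = 1e-12)

  # bin width must match the STA sampling interval
  bad <- make_psth(rate, bin_width = 1)
  expect_error(predict_burst(bad, sta), "bin width")
})

test_that("comb-driven prediction oscillates at the comb frequency", {
  # unit masses repeating every 1.667 ms (600 Hz) convolved with a
  # kernel whose own spectrum peaks near 600 Hz (T ~ 1.84 ms): by the
  # convolution theorem the prediction's multitaper spectrum peaks at
  # the 600 Hz comb line
  b600 <- 8 / (2 * pi * 0.6)^2           # spectral peak at 0.6 / ms
  hat <- mexican_hat(1, b600, 0)
  sta <- make_sta(mexhat_eval(hat, seq(-3, 3, by = 0.1)))
  rate <- rep(0, 500)
  rate[round(seq(100, 400, by = 50 / 3))] <- 1
  p <- predict_burst(make_psth(rate), sta)
  ps <- multitaper_psd(p$mean, 10000, bandwidth = 300)
  in_band <- ps$freqs > 50
  pk <- ps$freqs[in_band][which.max(ps$power[in_band])]
  expect_lt(abs(pk - 600), 160)
})

test_that("prediction spectrum factorizes into PSTH and STA spectra", {
  hat <- mexhat_from_amp_width(60, 0.45, 0.05)
  kern <- mexhat_eval(hat, seq(-3, 3, by = 0.1))
  sta <- make_sta(kern)
  rate <- rep(0, 400)
  rate[seq(120, 280, by = 17)] <- c(1, 0.8, 0.9, 0.7, 0.6, 0.5, 0.4,
                                    0.3, 0.25, 0.2)
  p <- predict_burst(make_psth(rate), sta)
  # pad to the full-convolution length; magnitude spectra are invariant
  # to the "same"-mode alignment shift
  L <- length(rate) + length(kern) - 1
  P <- Mod(stats::fft(c(p$mean, rep(0, L - length(p$mean)))))^2
  A <- Mod(stats::fft(c(rate, rep(0, L - length(rate)))))^2
  B <- Mod(stats::fft(c(kern, rep(0, L - length(kern)))))^2
  prod <- A * B
  sel <- prod > 1e-6 * max(prod)
  expect_lt(max(abs(P[sel] - prod[sel]) / prod[sel]), 0.01)
})

test_that("bootstrap band brackets the point estimate and is deterministic", {
  lags <- seq(-3, 3, by = 0.1)
  kern <- mexhat_eval(mexhat_from_amp_width(200, 0.45, 0.05), lags)
  rate <- rep(0, 300)
  rate[140:160] <- 0.2
  cells <- withr::with_seed(81, lapply(1:5, function(i) {
    seg <- matrix(stats::rnorm(200 * 61, sd = 30), 200) +
      rep(kern * stats::runif(1, 0.5, 1.5), each = 200)
    attr(seg, "lags") <- lags
    list(segments = seg, psth = make_psth(rate))
  }))
  b1 <- burst_bootstrap_ci(cells, n_boot = 200, seed = 82)
  b2 <- burst_bootstrap_ci(cells, n_boot = 200, seed = 82)
  expect_identical(b1$ci_lo, b2$ci_lo)
  expect_true(all(b1$ci_lo <= b1$ci_hi))
  inside <- mean(b1$mean >= b1$ci_lo & b1$mean <= b1$ci_hi)
  expect_gte(inside, 0.9)

  # single cell, zero EEG noise: the band collapses
  seg0 <- matrix(rep(kern, each = 50), 50)
  attr(seg0, "lags") <- lags
  b0 <- burst_bootstrap_ci(list(list(segments = seg0,
                                     psth = make_psth(rate))),
                           n_boot = 50, seed = 83)
  expect_true(all(b0$ci_hi - b0$ci_lo < 1e-9))
})

test_that("neuron-count estimation is exact on scaled copies and scale-free", {
  lags <- seq(-3, 3, by = 0.1)
  kern <- mexhat_eval(mexhat_from_amp_width(60, 0.45, 0.05), lags)
  rate <- rep(0, 300)
  rate[100:200] <- 0.1
  p <- predict_burst(make_psth(rate), make_sta(kern))
  expect_equal(estimate_neuron_count(200 * p$mean, p), 200, tolerance = 1e-9)
  expect_equal(estimate_neuron_count(p$mean, p), 1, tolerance = 1e-12)
  # scale freedom
  e1 <- estimate_neuron_count(37 * p$mean, p)
  e2 <- estimate_neuron_count(74 * p$mean, p)
  expect_equal(e2 / e1, 2, tolerance = 1e-12)
  expect_error(estimate_neuron_count(p$mean, predict_burst(
    make_psth(rep(0, 300)), make_sta(kern))), "zero amplitude")
})

test_that("forward-simulated multi-cell burst recovers the true cell count", {
  # N_true identical cells firing a driven comb embed N_true kernel
  # copies per volley; the recorded/predicted ratio recovers N_true
  n_true <- 50
  k <- calibrated_kernel(200)
  prof <- evoked_psth_profile(base_rate = 0, early_rate = 0,
                              burst_rate = 250, late_rate = 0)
  # population spikes: n_true cells drawn from the same profile
  all_trains <- lapply(1:n_true, function(i)
    simulate_spike_trains(prof, n_trials = 120, trial_length = 60,
                          seed = 84 + i))
  merged <- spike_train(lapply(1:120, function(tr)
    sort(unlist(lapply(all_trains, function(s) s$times[[tr]])))))
  cfg <- session_config(n_trials = 120, trial_length = 60, kernel = k,
                        psth_profile = prof, sep_template = NULL,
                        noise_sd_hf = 100, unit_noise_sd_uV = 0,
                        spike_amp_uV = 0, spikes = merged, rng_seed = 85,
                        refractory = 0)
  ses <- simulate_session(cfg)
  hf <- filter_trials(ses$eeg, ses$fs_eeg, hf_band())
  recorded <- colMeans(upsample_trials(hf, 6000, 10000))
  rec_time <- (seq_along(recorded) - 1) / 10

  # population-averaged single-cell prediction: each cell's PSTH
  # convolved with the (shared) in-band kernel, then averaged
  sta1 <- embedded_kernel_sta(k)
  psths <- lapply(all_trains, compute_psth, bin_width = 0.1,
                  window = c(0, 60))
  pred <- predict_burst(psths, rep(list(sta1), n_true))
  est <- estimate_neuron_count(
    stats::approx(rec_time, recorded, xout = pred$time)$y, pred,
    window = c(5, 25))
  expect_lt(abs(est - n_true) / n_true, 0.2)
})
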