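test_that("spike simulation honours rate, refractoriness and determinism", {
  # zero rate: no spikes anywhere
  st0 <- simulate_spike_trains(0, 50, 300, seed = 31)
  expect_equal(n_spikes(st0), 0L)

  # Poisson count statistics: lambda = 20 sp/s over 1000 trials x 90 ms
  st <- simulate_spike_trains(20, 1000, 90, refractory = 1, seed = 32)
  mu <- 20 * 0.09 * 1000
  expect_lt(abs(n_spikes(st) - mu), 3 * sqrt(mu))

  # absolute refractory period enforced in every trial
  st_hi <- simulate_spike_trains(300, 100, 200, refractory = 2, seed = 33)
  isis <- unlist(lapply(st_hi$times, diff))
  expect_gte(min(isis), 2)

  # determinism: identical seeds give identical trains
  a <- simulate_spike_trains(50, 20, 100, seed = 34)
  b <- simulate_spike_trains(50, 20, 100, seed = 34)
  expect_identical(a$times, b$times)

  # negative rates rejected
  expect_error(simulate_spike_trains(function(t) t - 100, 5, 300, seed = 1),
               "nonnegative")
})

test_that("empirical PSTH of simulated trains converges to the rate profile", {
  prof <- evoked_psth_profile()
  st <- simulate_spike_trains(prof, 4000, 300, refractory = 0, seed = 35)
  p <- compute_psth(st, 5, c(100, 300))
  centres <- p$bin_edges[-length(p$bin_edges)] + 2.5
  expected <- vapply(centres, function(tc)
    mean(prof(seq(tc - 2.5, tc + 2.5, by = 0.01))) * 5 / 1000, numeric(1))
  se <- sqrt(expected / 4000)
  expect_true(all(abs(p$rate - expected) < 4.5 * se))
  # late window is exactly stationary at the configured rate
  expect_true(all(abs(prof(seq(201, 289, by = 0.5)) - 20) < 1e-12))
})

test_that("session generator embeds kernels losslessly and calibrates noise", {
  # zero noise, grid-aligned spikes: every extracted segment equals the
  # upsampled sampled kernel
  k <- mexhat_from_amp_width(60, 0.45, 0.05)
  spk <- spike_train(rep(list(50), 8))  # 50 ms: on the 6 kHz and 10 kHz grids
  cfg <- session_config(n_trials = 8, trial_length = 100, noise_sd_hf = 0,
                        kernel = k, psth_profile = 0, sep_template = NULL,
                        unit_noise_sd_uV = 0, spikes = spk, rng_seed = 36)
  ses <- simulate_session(cfg)
  up <- upsample_trials(ses$eeg, 6000, 10000)
  seg <- extract_segments(up, ses$spikes, 3, 10000)
  expect_equal(nrow(seg), 8)
  k_lags <- seq(-3, 3, by = 1000 / 6000)
  expected <- stats::approx(k_lags, mexhat_eval(k, k_lags),
                            xout = seq(-3, 3, by = 0.1))$y
  for (i in 1:8) expect_equal(unname(seg[i, ]), expected, tolerance = 1e-9)

  # high-frequency noise calibration: SD in the 800-3000 Hz band close
  # to the configured 700 nV
  ns <- make_noise_session(37, n_trials = 60, trial_length = 400, rate = 0)
  hf <- filter_trials(ns$eeg, 6000, hf_band())
  expect_equal(stats::sd(as.vector(hf)), 700, tolerance = 0.02)

  # determinism and degenerate input
  s1 <- simulate_session(session_config(n_trials = 3, trial_length = 50,
                                        rng_seed = 38))
  s2 <- simulate_session(session_config(n_trials = 3, trial_length = 50,
                                        rng_seed = 38))
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$unit, s2$unit)
  expect_error(session_config(n_trials = 0), "n_trials")
  expect_error(session_config(trial_length = 4, kernel_halfwidth = 3),
               "kernel support")
})

test_that("full-pipeline STA recovers an embedded 400 nV kernel within sampling error", {
  ses <- make_kernel_session(39)
  chain <- hf_chain(ses)
  expect_gte(nrow(chain$segments), 2000)
  sta <- eeg_sta(chain$segments)
  # mean-of-iid-segments error bound: per-lag SEM ~ sigma_band/sqrt(n);
  # peak-to-peak combines two lags, hence the sqrt(2)
  sem_bound <- 3 * 700 * sqrt(2) / sqrt(nrow(chain$segments))
  expect_lt(abs(peak_to_peak(sta) - 400), sem_bound)
})

test_that("correlated pair generator matches its target cross-correlogram", {
  # independence: flat correlogram at the baseline rate
  ind <- simulate_correlated_pair(30, 0, 17, 400, seed = 40)
  cc <- cross_correlogram(ind$train1, ind$train2, bin_ms = 2,
                          max_lag_ms = 40)
  se <- sqrt(30 * length(ind$train1) * 0.002) / (length(ind$train1) * 0.002)
  expect_true(all(abs(cc$rate - 30) < 4.5 * se))

  # strong correlation regime: fitted Gaussian peak within 2 SE of target
  pair <- simulate_correlated_pair(20, 2, 5, 600, seed = 41)
  cc2 <- cross_correlogram(pair$train1, pair$train2, bin_ms = 1,
                           max_lag_ms = 30)
  fit <- stats::nls(rate ~ base + a * exp(-lag_ms^2 / b), data = cc2,
                    start = list(base = 20, a = 2, b = 20))
  co <- summary(fit)$coefficients
  expect_lt(abs(co["a", "Estimate"] - 2), 2 * co["a", "Std. Error"])
  # half-amplitude width near the 5 ms target (within 20%)
  expect_equal(2 * sqrt(co["b", "Estimate"] * log(2)), 5, tolerance = 0.2)

  # weak-and-broad regime of the literature values is feasible and seeded
  p1 <- simulate_correlated_pair(20, 0.008, 17, 60, seed = 42)
  p2 <- simulate_correlated_pair(20, 0.008, 17, 60, seed = 42)
  expect_identical(p1$train1, p2$train1)
  expect_identical(p1$train2, p2$train2)

  # infeasible correlation rejected
  expect_error(simulate_correlated_pair(1, 100, 17, 10), "infeasible")
})
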