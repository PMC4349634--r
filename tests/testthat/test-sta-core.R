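test_that("segment extraction obeys grid arithmetic and boundary rules", {
  eeg <- matrix(rep(seq_len(200), 4), nrow = 4, byrow = TRUE)
  spikes <- data.frame(trial = c(1, 2, 3), time_ms = c(10, 0.5, 19))
  seg <- extract_segments(eeg, spikes, half_window = 3, fs = 10000)
  # 61 inclusive samples per segment at 10 kHz and +/-3 ms
  expect_equal(ncol(seg), 61)
  lags <- attr(seg, "lags")
  expect_equal(lags[1], -3)
  expect_equal(lags[61], 3)
  expect_equal(lags[31], 0)
  # spikes whose window exceeds the trial (0.5 ms and 19 ms here) drop
  expect_equal(nrow(seg), 1)
  expect_equal(unname(seg[1, ]), seq(101 - 30, 101 + 30))

  none <- extract_segments(eeg, data.frame(trial = 1, time_ms = 0.1),
                           3, 10000)
  expect_equal(nrow(none), 0)
})

test_that("averaging gives exact means, SEM scaling and linearity", {
  # identical segments: mean = segment, SEM = 0
  seg <- matrix(rep(c(1, -2, 3), each = 5), nrow = 5)
  s <- eeg_sta(seg)
  expect_equal(s$mean, c(1, -2, 3))
  expect_equal(s$sem, c(0, 0, 0))
  expect_equal(s$n_segments, 5)

  # opposite pairs cancel
  a <- c(4, -1, 2)
  expect_equal(eeg_sta(rbind(a, -a))$mean, c(0, 0, 0))

  # SEM of kernel + iid noise close to sigma/sqrt(n)
  n <- 400
  sigma <- 7
  kern <- sin(seq(0, 2 * pi, length.out = 21))
  segs <- withr::with_seed(51, matrix(stats::rnorm(n * 21, sd = sigma), n) +
                             rep(kern, each = n))
  s2 <- eeg_sta(segs)
  expect_true(all(abs(s2$sem - sigma / sqrt(n)) < 0.2 * sigma / sqrt(n)))

  # STA is linear in the EEG
  e1 <- withr::with_seed(52, matrix(stats::rnorm(5 * 300), 5))
  e2 <- withr::with_seed(53, matrix(stats::rnorm(5 * 300), 5))
  sp <- data.frame(trial = 1:5, time_ms = c(10, 12, 14, 16, 18))
  m1 <- eeg_sta(extract_segments(e1, sp, 3, 10000))$mean
  m2 <- eeg_sta(extract_segments(e2, sp, 3, 10000))$mean
  m12 <- eeg_sta(extract_segments(2 * e1 - 0.5 * e2, sp, 3, 10000))$mean
  expect_equal(m12, 2 * m1 - 0.5 * m2, tolerance = 1e-12)

  expect_error(eeg_sta(matrix(numeric(0), 0, 61)), "at least one")
})

test_that("shift predictor captures stimulus-locked structure and nulls spike-locked structure", {
  # EEG identical across trials: shuffling is a no-op
  tone <- sin(2 * pi * (1:600) / 40)
  eeg_same <- matrix(rep(tone, 10), nrow = 10, byrow = TRUE)
  sp <- spike_train(rep(list(c(15, 35)), 10))
  sta <- eeg_sta(extract_segments(eeg_same, sp, 3, 10000))
  pred <- shift_predictor(eeg_same, sp, 3, 10000, n_shuffles = 5, seed = 54)
  expect_equal(pred$mean, sta$mean, tolerance = 1e-12)
  # and baseline correction then yields the zero waveform
  corr <- baseline_correct(sta, pred)
  expect_true(all(abs(corr$mean) < 1e-12))
  expect_true(corr$baseline_corrected)
  # additivity: corrected + predictor = original
  expect_equal(corr$mean + pred$mean, sta$mean, tolerance = 1e-12)

  # spike-locked kernel in trial-independent noise: predictor flat
  ses <- make_kernel_session(55, n_trials = 60, trial_length = 300,
                             rate = 25)
  chain <- hf_chain(ses)
  sta2 <- eeg_sta(chain$segments)
  pred2 <- shift_predictor(chain$up, chain$pruned, 3, 10000,
                           n_shuffles = 100, seed = 56)
  pred2 <- confidence_band(pred2)
  # unshuffled STA carries the kernel; predictor peak-to-peak far below
  expect_gt(peak_to_peak(sta2), 3 * peak_to_peak(pred2))
  # predictor stays within its own 99% band around zero at most lags
  inside <- mean(pred2$mean > -2.58 * pred2$sem &
                   pred2$mean < 2.58 * pred2$sem)
  expect_gt(inside, 0.9)

  expect_error(shift_predictor(eeg_same[1, , drop = FALSE], sp),
               "at least 2")
  bad <- new_sta(1:5, rep(0, 5), rep(0, 5), 1)
  expect_error(baseline_correct(sta, bad), "lag grids")
})

test_that("confidence band scales as SEM and peak-to-peak is exact on known shapes", {
  s <- new_sta(seq(-3, 3, by = 0.1), rep(0, 61), rep(1, 61), 100)
  b <- confidence_band(s)
  expect_equal(b$band$hi, rep(2.58, 61))
  expect_equal(b$band$lo, rep(-2.58, 61))
  s0 <- confidence_band(new_sta(1:3, c(0, 0, 0), c(0, 0, 0), 2))
  expect_true(all(s0$band$hi - s0$band$lo == 0))

  # band half-width halves when segments quadruple (1/sqrt(n) scaling)
  segs <- withr::with_seed(57, matrix(stats::rnorm(4000 * 21), 4000))
  sem_n <- eeg_sta(segs[1:500, ])$sem
  sem_4n <- eeg_sta(segs[1:2000, ])$sem
  expect_equal(mean(sem_n / sem_4n), 2, tolerance = 0.1)

  # peak-to-peak: constants, ramps and the Mexican hat closed form
  expect_equal(peak_to_peak(rep(5, 10)), 0)
  expect_equal(peak_to_peak(seq(2, 9, length.out = 15)), 7)
  hat <- mexhat_from_amp_width(60, 0.45, 0.05)
  w <- mexhat_eval(hat, seq(-3, 3, by = 1e-4))
  expect_equal(peak_to_peak(w), 60 * (1 + 2 * exp(-1.5)), tolerance = 1e-6)
  expect_error(peak_to_peak(w, seq(-3, 3, by = 1e-4), c(-5, 5)), "outside")
})

test_that("peak bootstrap test is significant for embedded kernels and deterministic", {
  ses <- make_kernel_session(58, n_trials = 150, trial_length = 300,
                             rate = 35, target_p2p = 400)
  chain <- hf_chain(ses)
  pred <- shift_predictor(chain$up, chain$pruned, 3, 10000,
                          n_shuffles = 30, seed = 59, keep_segments = TRUE)
  t1 <- peak_bootstrap_test(chain$segments, pred$segments, n_boot = 1000,
                            seed = 60)
  t2 <- peak_bootstrap_test(chain$segments, pred$segments, n_boot = 1000,
                            seed = 60)
  expect_lt(t1$p, 0.01)
  expect_identical(t1$p, t2$p)
  expect_gt(t1$peak, t1$peak_shuffled)
  expect_error(
    peak_bootstrap_test(chain$segments, pred$segments,
                        peak_window = c(-10, 10)), "outside")
})

test_that("grouped covariation detects proportional amplitudes and stays null when independent", {
  n <- 150
  base_w <- sin(seq(0, 2 * pi, length.out = 31))
  base_s <- cos(seq(0, 2 * pi, length.out = 61))
  gains <- seq(0.5, 2, length.out = n)
  wf <- outer(gains, base_w)
  sg <- outer(0.3 * gains, base_s)
  res <- grouped_covariation(wf, sg, "amplitude", 15)
  expect_equal(nrow(res$groups), 15)
  expect_equal(res$r, 1, tolerance = 1e-9)

  # 150 spikes in 15 groups: 10 per group
  expect_equal(unname(table(rep(1:15, each = 150 %/% 15)))[1], 10)

  # independent amplitudes: |r| small, p > 0.05 in most seeded runs
  pvals <- withr::with_seed(61, vapply(1:100, function(i) {
    wf_i <- outer(sample(gains), base_w) +
      matrix(stats::rnorm(n * 31, sd = 0.05), n)
    sg_i <- matrix(stats::rnorm(n * 61, sd = 1), n)
    grouped_covariation(wf_i, sg_i, "amplitude", 15)$p
  }, numeric(1)))
  expect_gte(mean(pvals > 0.05), 0.9)

  # pooled-percentile variant uses Spearman
  expect_equal(grouped_covariation(wf, sg, "pooled_percentile", 10)$method,
               "spearman")
  expect_error(grouped_covariation(wf, sg, "amplitude", 1), "at least 2")
  expect_error(grouped_covariation(wf, sg, "time", 10), "requires times")
})

test_that("induced RMS matches constants and iid noise levels", {
  m <- matrix(3, 7, 11)
  expect_equal(induced_rms(-m), rep(3, 11))
  expect_equal(induced_rms(matrix(numeric(0), 0, 5)), rep(0, 5))
  x <- withr::with_seed(62, matrix(stats::rnorm(3000 * 20, sd = 2.5), 3000))
  expect_true(all(abs(induced_rms(x) - 2.5) < 0.05 * 2.5))
})
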