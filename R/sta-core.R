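#' Spike-triggered average container
#'
#' @param lags Lag axis in ms (0 = the spike's first negative peak).
#' @param mean Mean waveform in nV per lag.
#' @param sem Standard error of the mean in nV per lag.
#' @param n_segments Number of averaged segments.
#' @param predictor_mean Optional shift-predictor mean per lag.
#' @param band Optional list with `lo` and `hi` confidence limits per lag.
#' @param baseline_corrected Whether the shift predictor has been
#'   subtracted.
#' @return An object of class `"sta"`.
#' @export
new_sta <- function(lags, mean, sem, n_segments, predictor_mean = NULL,
                    band = NULL, baseline_corrected = FALSE) {
  stopifnot(length(lags) == length(mean), length(sem) == length(mean))
  structure(
    list(lags = lags, mean = mean, sem = sem, n_segments = n_segments,
         predictor_mean = predictor_mean, band = band,
         baseline_corrected = baseline_corrected),
    class = "sta")
}

#' @export
print.sta <- function(x, ...) {
  cat(sprintf(
    "EEG-STA: %d segments, lags %g..%g ms, peak-to-peak %.3g nV%s\n",
    x$n_segments, min(x$lags), max(x$lags), peak_to_peak(x),
    if (x$baseline_corrected) " (baseline-corrected)" else ""))
  invisible(x)
}

#' Extract spike-triggered EEG segments
#'
#' Cuts a window of `half_window` ms on both sides (inclusive endpoints)
#' around each spike's first negative peak from the per-trial EEG, which
#' must already be sampled (upsampled) at `fs`. Spikes whose window exceeds
#' the trial are dropped. Spikes should already be pruned with the matching
#' minimum separation (6 ms for the +/-3 ms window, 30 ms for +/-15 ms) so
#' that no segment contains a neighbouring spike.
#'
#' @param eeg_trials Trials-by-samples EEG matrix at `fs` (nV).
#' @param spikes A `"spike_train"` or a data.frame with `trial`, `time_ms`.
#' @param half_window Half window in ms (default 3).
#' @param fs Sampling rate of `eeg_trials` in Hz (default 10000).
#' @return A segments matrix (one row per retained spike) with attributes
#'   `lags` (ms) and `fs`; zero rows when no spike is retainable.
#' @export
extract_segments <- function(eeg_trials, spikes, half_window = 3,
                             fs = 10000) {
  stopifnot(is.matrix(eeg_trials))
  df <- if (inherits(spikes, "spike_train")) as_spike_df(spikes) else spikes
  stopifnot(all(c("trial", "time_ms") %in% names(df)))
  hw <- round(half_window * fs / 1000)
  lags <- (-hw:hw) / fs * 1000
  centre <- round(df$time_ms * fs / 1000) + 1L
  ok <- centre - hw >= 1L & centre + hw <= ncol(eeg_trials) &
    df$trial >= 1L & df$trial <= nrow(eeg_trials)
  centre <- centre[ok]
  trial <- df$trial[ok]
  if (length(centre) == 0) {
    seg <- matrix(numeric(0), nrow = 0, ncol = 2 * hw + 1)
  } else {
    cols <- outer(centre, -hw:hw, "+")
    idx <- (cols - 1L) * nrow(eeg_trials) + trial  # column-major linear index
    seg <- matrix(eeg_trials[idx], nrow = length(centre))
  }
  attr(seg, "lags") <- lags
  attr(seg, "fs") <- fs
  seg
}

#' Average spike-triggered segments into an EEG-STA
#'
#' @param segments A segments matrix from [extract_segments()].
#' @return An `"sta"` with per-lag mean and SEM across segments.
#' @export
eeg_sta <- function(segments) {
  n <- nrow(segments)
  if (is.null(n) || n < 1) stop("need at least one segment")
  m <- colMeans(segments)
  sem <- if (n > 1) {
    ss <- colSums(segments^2) - n * m^2
    sqrt(pmax(ss, 0) / (n - 1)) / sqrt(n)
  } else {
    rep(0, length(m))
  }
  new_sta(seg_lags(segments), m, sem, n)
}

seg_lags <- function(segments) {
  lg <- attr(segments, "lags")
  if (is.null(lg)) lg <- seq_len(ncol(segments))
  lg
}

#' Shift predictor: trial-shuffled spike-triggered average
#'
#' Builds the null EEG-STA expected from stimulus-locked structure alone.
#' For each of `n_shuffles` shuffles, every spike keeps its within-trial
#' latency but is reassigned to a uniformly drawn *different* trial;
#' segments are re-extracted and averaged. The predictor is the mean over
#' all shuffles. The per-lag SEM is computed across the pooled shuffled
#' segments with `n = ` the number of segments entering a single STA, so
#' that the 2.58-SEM confidence band refers to one STA's sampling noise.
#'
#' @inheritParams extract_segments
#' @param n_shuffles Number of trial shuffles (default 100).
#' @param seed Optional integer seed.
#' @param keep_segments If `TRUE`, also return the pooled shuffled
#'   segments (memory grows with `n_shuffles`).
#' @return An `"sta"` whose `mean` is the shift predictor; extra fields
#'   `shuffle_stas` (n_shuffles x lags matrix) and, if requested,
#'   `segments`.
#' @export
shift_predictor <- function(eeg_trials, spikes, half_window = 3, fs = 10000,
                            n_shuffles = 100, seed = NULL,
                            keep_segments = FALSE) {
  if (nrow(eeg_trials) < 2) stop("shift predictor needs at least 2 trials")
  df <- if (inherits(spikes, "spike_train")) as_spike_df(spikes) else spikes
  if (!is.null(seed)) withr::local_seed(seed)
  n_tr <- nrow(eeg_trials)
  acc_sum <- NULL
  acc_ssq <- NULL
  total <- 0L
  shuffle_stas <- NULL
  pooled <- if (keep_segments) vector("list", n_shuffles) else NULL
  for (s in seq_len(n_shuffles)) {
    u <- sample.int(n_tr - 1L, nrow(df), replace = TRUE)
    df_s <- df
    df_s$trial <- u + (u >= df$trial)  # uniform over trials != own
    seg <- extract_segments(eeg_trials, df_s, half_window, fs)
    if (nrow(seg) == 0) next
    if (is.null(acc_sum)) {
      acc_sum <- colSums(seg)
      acc_ssq <- colSums(seg^2)
      shuffle_stas <- matrix(NA_real_, n_shuffles, ncol(seg))
    } else {
      acc_sum <- acc_sum + colSums(seg)
      acc_ssq <- acc_ssq + colSums(seg^2)
    }
    shuffle_stas[s, ] <- colMeans(seg)
    total <- total + nrow(seg)
    if (keep_segments) pooled[[s]] <- seg
  }
  if (total == 0L) stop("no retainable spikes in any shuffle")
  m <- acc_sum / total
  n_per_sta <- total / n_shuffles
  pooled_sd <- sqrt(pmax(acc_ssq - total * m^2, 0) / (total - 1))
  hw <- round(half_window * fs / 1000)
  out <- new_sta((-hw:hw) / fs * 1000, m, pooled_sd / sqrt(n_per_sta),
                 n_segments = round(n_per_sta))
  out$n_shuffles <- n_shuffles
  out$shuffle_stas <- shuffle_stas
  if (keep_segments) {
    segs <- do.call(rbind, pooled)
    attr(segs, "lags") <- out$lags
    attr(segs, "fs") <- fs
    out$segments <- segs
  }
  out
}

#' Subtract the shift predictor from an EEG-STA (baseline correction)
#'
#' Evoked responses introduce potential shifts that contaminate the
#' EEG-STA even for spikes unrelated to the EEG; subtracting the shift
#' predictor removes this stimulus-locked baseline. By convention this
#' correction is *not* applied to STAs computed in the late stationary
#' window or to wideband spectra; that exception is the caller's contract,
#' and the `baseline_corrected` flag records what was done.
#'
#' @param sta The EEG-STA (`"sta"`).
#' @param predictor The shift predictor (`"sta"`), on the same lag grid.
#' @return The corrected `"sta"` with `baseline_corrected = TRUE` and
#'   `predictor_mean` stored.
#' @export
baseline_correct <- function(sta, predictor) {
  stopifnot(inherits(sta, "sta"), inherits(predictor, "sta"))
  if (length(sta$lags) != length(predictor$lags) ||
      max(abs(sta$lags - predictor$lags)) > 1e-9)
    stop("lag grids of STA and predictor do not match")
  out <- sta
  out$mean <- sta$mean - predictor$mean
  out$predictor_mean <- predictor$mean
  out$baseline_corrected <- TRUE
  out
}

#' Pointwise confidence band from segment SEM
#'
#' The 99% band used for shuffled EEG-STAs: the per-lag mean plus/minus
#' `level_multiplier` times the per-lag SEM across spike-triggered
#' segments (2.58 SEM gives 99% normal coverage).
#'
#' @param sta An `"sta"` (typically the shift predictor).
#' @param level_multiplier Band half-width in SEM units (default 2.58).
#' @return The `"sta"` with `band = list(lo, hi)` filled in.
#' @export
confidence_band <- function(sta, level_multiplier = 2.58) {
  stopifnot(inherits(sta, "sta"))
  sta$band <- list(lo = sta$mean - level_multiplier * sta$sem,
                   hi = sta$mean + level_multiplier * sta$sem)
  sta
}

#' Peak-to-peak amplitude of a waveform
#'
#' @param x An `"sta"` or numeric waveform.
#' @param lags Lag axis (required when `x` is numeric and `window` given).
#' @param window Optional length-2 lag window in ms.
#' @return `max - min` of the waveform within the window, in nV.
#' @export
peak_to_peak <- function(x, lags = NULL, window = NULL) {
  if (inherits(x, "sta")) {
    lags <- x$lags
    x <- x$mean
  }
  if (!is.null(window)) {
    if (is.null(lags)) stop("window requires a lag axis")
    if (window[1] < min(lags) - 1e-9 || window[2] > max(lags) + 1e-9)
      stop("window outside the lag grid")
    x <- x[lags >= window[1] & lags <= window[2]]
  }
  if (length(x) == 0) return(0)
  max(x) - min(x)
}

# bootstrap STA means: draw n_draw segments with replacement from the rows
# of `segments`, n_boot times; returns n_boot x lags matrix
boot_stas <- function(segments, n_draw, n_boot) {
  n <- nrow(segments)
  w <- stats::rmultinom(n_boot, n_draw, rep(1 / n, n))
  crossprod(w, segments) / n_draw
}

#' Bootstrap test for EEG-STA peaks against the trial-shuffle null
#'
#' Tests whether the maximal absolute EEG-STA amplitude within a lag
#' window exceeds what trial shuffling produces. The null distribution of
#' peak amplitudes is estimated from `n_boot` shuffled EEG-STAs, each
#' formed from a random combination (drawn with replacement, segment
#' count conserved) of the shuffled-trigger segments; the p-value is the
#' fraction of these replicates in which the shuffled-STA peak exceeds
#' the observed unshuffled-STA peak. This comparison is exactly level
#' under the null because the observed STA and each replicate average the
#' same number of segments. No multiple-comparison correction is applied.
#'
#' @param segments Unshuffled spike-triggered segments matrix.
#' @param shuffled_segments Pooled shuffled segments matrix (same lag
#'   grid; may contain more rows).
#' @param peak_window Lag window in ms (default `c(-0.3, 0.5)`).
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Optional integer seed.
#' @return A list with `p`, the observed `peak` and `peak_shuffled`
#'   (both nV), and `n_boot`.
#' @export
peak_bootstrap_test <- function(segments, shuffled_segments,
                                peak_window = c(-0.3, 0.5), n_boot = 5000,
                                seed = NULL) {
  lags <- seg_lags(segments)
  if (peak_window[1] < min(lags) - 1e-9 || peak_window[2] > max(lags) + 1e-9)
    stop("peak window outside the lag grid")
  if (!is.null(seed)) withr::local_seed(seed)
  sel <- lags >= peak_window[1] & lags <= peak_window[2]
  n <- nrow(segments)
  b2 <- boot_stas(shuffled_segments, n, n_boot)
  pk2 <- apply(abs(b2[, sel, drop = FALSE]), 1, max)
  pk1 <- max(abs(colMeans(segments)[sel]))
  list(p = mean(pk2 > pk1),
       peak = pk1,
       peak_shuffled = max(abs(colMeans(shuffled_segments)[sel])),
       n_boot = n_boot)
}

#' Covariation of spike-waveform and EEG-STA amplitudes across groups
#'
#' Splits spikes into equally-sized ordered groups, averages the spike
#' waveforms and the spike-triggered EEG segments within each group, and
#' correlates the group-averaged peak-to-peak spike amplitude with the
#' group-averaged STA amplitude. A positive correlation may indicate
#' electrical cross-talk between the recording pathways; its absence
#' supports a volume-conducted spike contribution.
#'
#' @param waveforms Spike waveform snippets, one row per spike (uV).
#' @param segments Spike-triggered EEG segments, one row per spike (nV),
#'   in the same spike order.
#' @param grouping `"amplitude"` (order by spike peak-to-peak, Pearson),
#'   `"time"` (order by occurrence, Pearson) or `"pooled_percentile"`
#'   (amplitude percentiles, Spearman).
#' @param n_groups Number of equally-sized groups (>= 2, <= number of
#'   spikes). Spikes beyond the largest multiple of `n_groups` are
#'   dropped from the tail of the ordering.
#' @param times Spike times (any monotone ordering key); required for
#'   `grouping = "time"`.
#' @return A list with `groups` (data.frame of per-group amplitudes), `r`
#'   and `p`.
#' @export
grouped_covariation <- function(waveforms, segments,
                                grouping = c("amplitude", "time",
                                             "pooled_percentile"),
                                n_groups, times = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(nrow(waveforms) == nrow(segments))
  n <- nrow(waveforms)
  if (n_groups < 2) stop("n_groups must be at least 2")
  if (n_groups > n) stop("n_groups cannot exceed the number of spikes")
  spike_amp <- apply(waveforms, 1, function(w) max(w) - min(w))
  ord <- switch(grouping,
                amplitude = order(spike_amp),
                pooled_percentile = order(spike_amp),
                time = {
                  if (is.null(times)) stop("grouping by time requires times")
                  order(times)
                })
  g <- n %/% n_groups
  ord <- ord[seq_len(g * n_groups)]
  grp <- rep(seq_len(n_groups), each = g)
  amp_w <- amp_s <- numeric(n_groups)
  for (k in seq_len(n_groups)) {
    rows <- ord[grp == k]
    amp_w[k] <- peak_to_peak(colMeans(waveforms[rows, , drop = FALSE]))
    amp_s[k] <- peak_to_peak(colMeans(segments[rows, , drop = FALSE]))
  }
  method <- if (grouping == "pooled_percentile") "spearman" else "pearson"
  ct <- suppressWarnings(stats::cor.test(amp_w, amp_s, method = method))
  list(groups = data.frame(group = seq_len(n_groups),
                           spike_amp = amp_w, sta_amp = amp_s),
       r = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Induced (non-phase-locked) power: per-time RMS across trials
#'
#' Root of the trial-averaged squared signal at each time point. Unlike
#' the trial average, the RMS does not cancel oscillations whose phase is
#' incoherent across trials, so it exposes stimulus-induced activity.
#'
#' @param eeg_trials Trials-by-samples matrix.
#' @param cols Optional column subset.
#' @return Numeric vector of per-time RMS values (0s when no trials).
#' @export
induced_rms <- function(eeg_trials, cols = NULL) {
  stopifnot(is.matrix(eeg_trials))
  if (!is.null(cols)) eeg_trials <- eeg_trials[, cols, drop = FALSE]
  if (nrow(eeg_trials) == 0) return(rep(0, ncol(eeg_trials)))
  sqrt(colMeans(eeg_trials^2))
}
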