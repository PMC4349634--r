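#' Predict the evoked high-frequency EEG burst from PSTHs and EEG-STAs
#'
#' Replaces every expected spike by the cell's spike-triggered EEG
#' average: each cell's PSTH (expected spikes per trial per 0.1 ms bin) is
#' convolved with that cell's EEG-STA (nV per spike at 10 kHz, so the STA
#' sample interval equals the PSTH bin width), and the per-cell
#' predictions are averaged to approximate the mean population response.
#' The convolution is aligned so that STA lag 0 falls on the spike bin
#' ("same" mode), which preserves burst peak latencies. Because the PSTH
#' is in expected spikes per bin and the STA in nV per spike, the
#' prediction is in nV with no extra factors.
#'
#' @param psths A list of `"psth"` objects (or a single one), bin width
#'   equal to the STA sample interval.
#' @param stas A list of `"sta"` objects (or a single one), same length.
#' @return An object of class `"burst_prediction"`: `time` (ms,
#'   post-stimulus bin centres), `mean` (nV), `per_cell` (cells x time
#'   matrix), `n_cells`.
#' @export
predict_burst <- function(psths, stas) {
  if (inherits(psths, "psth")) psths <- list(psths)
  if (inherits(stas, "sta")) stas <- list(stas)
  stopifnot(length(psths) == length(stas), length(psths) >= 1)
  preds <- vector("list", length(psths))
  for (i in seq_along(psths)) {
    p <- psths[[i]]
    s <- stas[[i]]
    stopifnot(inherits(p, "psth"), inherits(s, "sta"))
    dt <- if (length(s$lags) > 1) s$lags[2] - s$lags[1] else p$bin_width
    if (abs(dt - p$bin_width) > 1e-9)
      stop("PSTH bin width must equal the STA sample interval")
    preds[[i]] <- conv_same(p$rate, s$mean, which.min(abs(s$lags)))
  }
  per_cell <- do.call(rbind, preds)
  p1 <- psths[[1]]
  time <- p1$bin_edges[-length(p1$bin_edges)] + p1$bin_width / 2
  structure(
    list(time = time, mean = colMeans(per_cell), per_cell = per_cell,
         n_cells = length(psths)),
    class = "burst_prediction")
}

# linear convolution of x with kernel k, cropped so that kernel index i0
# (1-based) aligns with each sample of x
conv_same <- function(x, k, i0) {
  full <- stats::convolve(x, rev(k), type = "open")  # length n + m - 1
  full[i0:(i0 + length(x) - 1)]
}

#' @export
print.burst_prediction <- function(x, ...) {
  cat(sprintf(
    "Predicted EEG burst: %d cells, %g-%g ms, peak-to-peak %.3g nV\n",
    x$n_cells, min(x$time), max(x$time), max(x$mean) - min(x$mean)))
  invisible(x)
}

#' Bootstrap confidence band for the predicted burst
#'
#' Accounts for both EEG-STA estimation noise and the limited sampling of
#' neurons. Per replicate: cells are resampled with replacement to the
#' original count; each sampled cell's STA is recomputed from its
#' spike-triggered segments resampled with replacement (segment count
#' conserved); each is convolved with the cell's PSTH and the results
#' averaged. The band is the pointwise 5th/95th percentile over
#' `n_boot` replicates.
#'
#' @param cells A list, one element per cell, each a list with `segments`
#'   (spike-triggered segments matrix from [extract_segments()]) and
#'   `psth` (a `"psth"`).
#' @param n_boot Number of replicates (default 500).
#' @param seed Optional integer seed.
#' @return A `"burst_prediction"` with `ci_lo` and `ci_hi` added.
#' @export
burst_bootstrap_ci <- function(cells, n_boot = 500, seed = NULL) {
  stopifnot(length(cells) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  n_cells <- length(cells)
  point <- predict_burst(lapply(cells, `[[`, "psth"),
                         lapply(cells, function(cl) eeg_sta(cl$segments)))
  i0 <- lapply(cells, function(cl) {
    lg <- seg_lags(cl$segments)
    which.min(abs(lg))
  })
  reps <- matrix(0, n_boot, length(point$time))
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n_cells, n_cells, replace = TRUE)
    acc <- 0
    for (ci in pick) {
      seg <- cells[[ci]]$segments
      m <- colMeans(seg[sample.int(nrow(seg), nrow(seg), replace = TRUE),
                        , drop = FALSE])
      acc <- acc + conv_same(cells[[ci]]$psth$rate, m, i0[[ci]])
    }
    reps[b, ] <- acc / n_cells
  }
  point$ci_lo <- apply(reps, 2, stats::quantile, probs = 0.05, names = FALSE)
  point$ci_hi <- apply(reps, 2, stats::quantile, probs = 0.95, names = FALSE)
  point$n_boot <- n_boot
  point
}

#' Estimate the number of contributing neurons from burst amplitudes
#'
#' The single-cell prediction scales linearly with the number of active
#' neurons, so the ratio of the recorded to the predicted burst
#' peak-to-peak amplitude is a rough estimate of how many cells generate
#' the observed signal.
#'
#' @param recorded Recorded burst waveform (nV), or a `"burst_prediction"`.
#' @param predicted Predicted burst (`"burst_prediction"` or numeric, nV).
#' @param time Time axis in ms shared by both (taken from the prediction
#'   when available).
#' @param window Optional length-2 time window in ms.
#' @return The amplitude ratio (estimated neuron count).
#' @export
estimate_neuron_count <- function(recorded, predicted, time = NULL,
                                  window = NULL) {
  if (inherits(predicted, "burst_prediction")) {
    if (is.null(time)) time <- predicted$time
    predicted <- predicted$mean
  }
  if (inherits(recorded, "burst_prediction")) recorded <- recorded$mean
  p2p_rec <- peak_to_peak(recorded, time, window)
  p2p_pred <- peak_to_peak(predicted, time, window)
  if (p2p_pred == 0) stop("predicted burst has zero amplitude")
  p2p_rec / p2p_pred
}
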