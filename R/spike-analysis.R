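#' Threshold spike detection with negative-peak alignment
#'
#' Detects extracellular action potentials by amplitude thresholding: the
#' threshold is `threshold_sd` times a robust estimate of the background
#' noise SD (median absolute deviation scaled for Gaussian consistency,
#' which resists contamination by the spikes themselves). Each excursion of
#' the trace below the negative threshold is reported at its first negative
#' peak. A train containing any interspike interval below 1 ms is flagged
#' `qc$isi_violation`, since such intervals indicate poor isolation.
#'
#' @param trace Numeric vector, one continuous trace or trial (uV).
#' @param fs Sampling rate in Hz.
#' @param threshold_sd Threshold in robust noise SDs (default 2, > 0).
#' @param snippet_halfwidth Half-width in ms of the waveform snippets
#'   extracted around each peak (default 1).
#' @return A `"spike_train"` with one trial; `waveforms` holds the aligned
#'   snippets, and `qc$isi_violation` is `TRUE` when any ISI < 1 ms.
#' @export
detect_and_align <- function(trace, fs, threshold_sd = 2,
                             snippet_halfwidth = 1) {
  if (!all(is.finite(trace))) stop("trace must be finite")
  if (threshold_sd <= 0) stop("threshold_sd must be positive")
  noise_sd <- stats::mad(trace)
  thr <- threshold_sd * noise_sd
  below <- which(trace < -thr)
  if (noise_sd == 0 || length(below) == 0)
    return(spike_train(list(numeric(0)),
                       qc = list(isi_violation = FALSE)))
  # group suprathreshold samples into events separated by >= 0.2 ms
  gap <- max(1L, round(0.2 * fs / 1000))
  brk <- which(diff(below) > gap)
  starts <- c(below[1], below[brk + 1])
  ends <- c(below[brk], below[length(below)])
  # the event's deepest sample is the (first) negative peak for the
  # standard biphasic extracellular waveform
  peaks <- mapply(function(s, e) s + which.min(trace[s:e]) - 1L,
                  starts, ends)
  times <- (peaks - 1) * 1000 / fs
  hw <- max(1L, round(snippet_halfwidth * fs / 1000))
  wf <- t(vapply(peaks, function(p) {
    j <- (p - hw):(p + hw)
    out <- rep(NA_real_, length(j))
    ok <- j >= 1 & j <= length(trace)
    out[ok] <- trace[j[ok]]
    out
  }, numeric(2L * hw + 1L)))
  spike_train(list(times), waveforms = wf,
              qc = list(isi_violation = any(diff(times) < 1)))
}

#' Detect spikes on every trial of a session's unit channel
#'
#' @param session A `"session"`.
#' @param threshold_sd Threshold in robust noise SDs.
#' @return A `"spike_train"` across all trials.
#' @export
detect_session_spikes <- function(session, threshold_sd = 2) {
  stopifnot(inherits(session, "session"))
  per_trial <- lapply(seq_len(nrow(session$unit)), function(tr)
    detect_and_align(session$unit[tr, ], session$fs_unit, threshold_sd))
  spike_train(lapply(per_trial, function(s) s$times[[1]]),
              qc = list(isi_violation =
                          any(vapply(per_trial,
                                     function(s) isTRUE(s$qc$isi_violation),
                                     logical(1)))))
}

#' Remove spikes closer than a minimum separation
#'
#' Returns the subset of spike times in which every retained spike is at
#' least `min_isi` away from its nearest neighbour in the *original* train:
#' both members of any close pair are removed, because a neighbouring spike
#' on either side would contaminate the spike-triggered EEG segment.
#' Separations exactly equal to `min_isi` are retained. Pruning is
#' idempotent.
#'
#' @param times Sorted spike times in ms.
#' @param min_isi Minimum separation in ms.
#' @return The pruned times.
#' @examples
#' prune_min_separation(c(0, 5, 20), 6)  # both members of the 0/5 pair go
#' @export
prune_min_separation <- function(times, min_isi) {
  if (length(times) <= 1) return(times)
  gaps <- diff(times)
  close_before <- c(FALSE, gaps < min_isi)
  close_after <- c(gaps < min_isi, FALSE)
  times[!(close_before | close_after)]
}

#' Post-stimulus time histogram
#'
#' Bins pooled spike times into contiguous half-open bins `[t, t + bin)`
#' and normalizes by the number of trials, giving expected spikes per trial
#' per bin. Rates in spikes/s are available as `rate / bin_width * 1000`.
#'
#' @param train A `"spike_train"`.
#' @param bin_width Bin width in ms (> 0).
#' @param window Length-2 window in ms; bins tile `[window[1], window[2])`.
#' @return An object of class `"psth"`: `bin_edges` (ms), `rate` (spikes
#'   per trial per bin), `bin_width`, `n_trials`.
#' @export
compute_psth <- function(train, bin_width, window) {
  stopifnot(inherits(train, "spike_train"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing length-2 interval")
  edges <- seq(window[1], window[2], by = bin_width)
  if (abs(edges[length(edges)] - window[2]) > 1e-9)
    edges <- c(edges, edges[length(edges)] + bin_width)
  pooled <- unlist(train$times, use.names = FALSE)
  pooled <- pooled[pooled >= window[1] & pooled < edges[length(edges)]]
  idx <- findInterval(pooled, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(
    list(bin_edges = edges, rate = counts / train$n_trials,
         bin_width = bin_width, n_trials = train$n_trials),
    class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms over [%g, %g) ms, %d trials\n",
              length(x$rate), x$bin_width, x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n_trials))
  invisible(x)
}

#' Kolmogorov-Smirnov test of spike-time uniformity
#'
#' Tests whether spike times pooled across trials are uniformly distributed
#' over a window, as expected when the firing rate is stationary (e.g. in
#' the late post-stimulus window once evoked rate fluctuations have
#' decayed).
#'
#' @param pooled_times Spike times in ms (pooled across trials).
#' @param window Length-2 interval in ms.
#' @return A list with the KS statistic `D` and `p` value.
#' @export
uniformity_test <- function(pooled_times, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing length-2 interval")
  x <- pooled_times[pooled_times >= window[1] & pooled_times <= window[2]]
  if (length(x) < 2) stop("need at least 2 spikes in the window")
  kt <- suppressWarnings(
    stats::ks.test(x, "punif", min = window[1], max = window[2]))
  list(D = unname(kt$statistic), p = kt$p.value)
}
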