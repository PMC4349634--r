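#' Per-trial spike train container
#'
#' Holds spike times (ms, relative to the stimulus / trial start) for one
#' cell across trials, optionally with waveform snippets aligned to the
#' first negative peak and quality-control flags.
#'
#' @param times A list with one sorted numeric vector of spike times (ms)
#'   per trial.
#' @param cell_id Identifier for the cell.
#' @param waveforms Optional matrix of waveform snippets (one row per
#'   spike, pooled over trials in trial order), in uV.
#' @param qc Optional named list of QC flags (e.g. `isi_violation`,
#'   `waveform_inconsistency`).
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(times, cell_id = 1L, waveforms = NULL, qc = list()) {
  stopifnot(is.list(times))
  times <- lapply(times, function(tt) {
    tt <- as.numeric(tt)
    if (is.unsorted(tt, strictly = FALSE)) tt <- sort(tt)
    tt
  })
  structure(list(times = times, n_trials = length(times), cell_id = cell_id,
                 waveforms = waveforms, qc = qc),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- n_spikes(x)
  cat(sprintf("Spike train (cell %s): %d spikes over %d trials\n",
              as.character(x$cell_id), n, x$n_trials))
  if (isTRUE(x$qc$isi_violation)) cat("  QC: interspike-interval violation\n")
  invisible(x)
}

#' Total number of spikes in a train
#' @param train A `"spike_train"`.
#' @return Integer count.
#' @export
n_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  sum(lengths(train$times))
}

#' Convert a spike train to a long-format table
#'
#' @param train A `"spike_train"`.
#' @return A data.frame with columns `cell_id`, `trial`, `time_ms`.
#' @export
as_spike_df <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  data.frame(
    cell_id = train$cell_id,
    trial = rep(seq_along(train$times), lengths(train$times)),
    time_ms = unlist(train$times, use.names = FALSE))
}

#' Build a spike train from a long-format table
#'
#' @param df A data.frame with columns `trial` and `time_ms` (and
#'   optionally `cell_id`).
#' @param n_trials Total number of trials (defaults to `max(trial)`).
#' @return A `"spike_train"`.
#' @export
spike_train_from_df <- function(df, n_trials = NULL) {
  stopifnot(all(c("trial", "time_ms") %in% names(df)))
  if (is.null(n_trials)) n_trials <- max(df$trial, 0L)
  times <- split(df$time_ms, factor(df$trial, levels = seq_len(n_trials)))
  cell <- if ("cell_id" %in% names(df) && nrow(df)) df$cell_id[1] else 1L
  spike_train(lapply(times, sort), cell_id = cell)
}

#' Apply minimum-separation pruning to every trial of a train
#'
#' @param train A `"spike_train"`.
#' @param min_isi Minimum separation in ms.
#' @return A pruned `"spike_train"` (waveforms are dropped).
#' @seealso [prune_min_separation()]
#' @export
prune_train <- function(train, min_isi) {
  stopifnot(inherits(train, "spike_train"))
  spike_train(lapply(train$times, prune_min_separation, min_isi = min_isi),
              cell_id = train$cell_id, qc = train$qc)
}
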