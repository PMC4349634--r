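#' Log-spaced frequency grid
#'
#' Frequencies equidistant on a logarithmic scale with
#' `freqs_per_octave` points per octave (consecutive grid frequencies have
#' the constant ratio `2^(1/freqs_per_octave)`).
#'
#' @param f_min Lowest frequency in Hz (> 0; a logarithmic grid cannot
#'   start at 0).
#' @param f_max Highest frequency in Hz.
#' @param freqs_per_octave Grid density (default 8).
#' @return Increasing numeric vector of frequencies in Hz.
#' @export
log_freq_grid <- function(f_min, f_max, freqs_per_octave = 8) {
  if (f_min <= 0) stop("f_min must be positive")
  if (f_max <= f_min) stop("f_max must exceed f_min")
  n_oct <- log2(f_max / f_min)
  f_min * 2^(seq(0, n_oct, by = 1 / freqs_per_octave))
}

# Hann-windowed projection of x onto sine/cosine at frequency f, with the
# signal truncated to an integer number of periods; returns squared
# amplitude (signal units squared).
truncated_hann_power <- function(x, fs, f) {
  dur <- length(x) / fs
  n_per <- floor(dur * f)
  if (n_per < 1) return(NA_real_)
  len <- min(length(x), floor(n_per / f * fs))
  if (len < 2) return(NA_real_)
  xx <- x[seq_len(len)]
  w <- 0.5 * (1 - cos(2 * pi * (0:(len - 1)) / len))
  t <- (0:(len - 1)) / fs
  xc <- sum(xx * w * cos(2 * pi * f * t))
  xs <- sum(xx * w * sin(2 * pi * f * t))
  (2 * sqrt(xc^2 + xs^2) / sum(w))^2
}

#' Log-spaced spectrum with truncated Hanning windows
#'
#' Spectral estimator designed for short waveforms such as EEG-STAs. For
#' each frequency on a log-spaced grid (8 per octave by default) the
#' signal is truncated to an integer multiple of the period (which
#' minimizes leakage), multiplied by a Hanning window of that length, and
#' projected directly onto a sine and cosine at that frequency. The power
#' is the squared amplitude of the projection, normalized by the window
#' gain so that a unit sine at a grid frequency yields power 1. The
#' spectrum is finally smoothed by a moving average over the grid spanning
#' half an octave (`[f * 2^-1/4, f * 2^1/4]`).
#'
#' @param x Signal samples.
#' @param fs Sampling rate in Hz.
#' @param freqs_per_octave Grid density (default 8).
#' @param f_min Lowest grid frequency; default `2 / duration` (two full
#'   periods must fit). Values below that are rejected.
#' @param smooth Apply the half-octave moving average (default `TRUE`).
#' @return An object of class `"spectrum_estimate"`: `freqs` (Hz),
#'   `power` (signal units squared), `smoothed`.
#' @export
logspaced_spectrum <- function(x, fs, freqs_per_octave = 8, f_min = NULL,
                               smooth = TRUE) {
  dur <- length(x) / fs
  if (is.null(f_min)) f_min <- 2 / dur
  if (f_min < 2 / dur - 1e-12)
    stop("f_min below 2/duration: not enough periods in the signal")
  freqs <- log_freq_grid(f_min, fs / 2, freqs_per_octave)
  power <- vapply(freqs, function(f) truncated_hann_power(x, fs, f),
                  numeric(1))
  ok <- !is.na(power)
  freqs <- freqs[ok]
  power <- power[ok]
  if (smooth) power <- half_octave_smooth(freqs, power)
  structure(list(freqs = freqs, power = power, smoothed = smooth),
            class = "spectrum_estimate")
}

half_octave_smooth <- function(freqs, power) {
  vapply(seq_along(freqs), function(i) {
    sel <- freqs >= freqs[i] * 2^(-1 / 4) & freqs <= freqs[i] * 2^(1 / 4)
    mean(power[sel])
  }, numeric(1))
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("Spectrum estimate: %d frequencies, %g-%g Hz%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              if (isTRUE(x$smoothed)) " (half-octave smoothed)" else ""))
  invisible(x)
}

# projection matrix implementing logspaced_spectrum for many waveforms at
# once: returns list(freqs, C, S, inv_gain) with C, S of size F x L
logspec_basis <- function(L, fs, freqs_per_octave = 8, f_min = NULL) {
  dur <- L / fs
  if (is.null(f_min)) f_min <- 2 / dur
  freqs <- log_freq_grid(f_min, fs / 2, freqs_per_octave)
  C <- S <- matrix(0, length(freqs), L)
  gain <- numeric(length(freqs))
  keep <- logical(length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    n_per <- floor(dur * f)
    len <- min(L, floor(n_per / f * fs))
    if (n_per < 1 || len < 2) next
    keep[i] <- TRUE
    w <- 0.5 * (1 - cos(2 * pi * (0:(len - 1)) / len))
    t <- (0:(len - 1)) / fs
    C[i, seq_len(len)] <- w * cos(2 * pi * f * t)
    S[i, seq_len(len)] <- w * sin(2 * pi * f * t)
    gain[i] <- sum(w) / 2
  }
  list(freqs = freqs[keep], C = C[keep, , drop = FALSE],
       S = S[keep, , drop = FALSE], gain = gain[keep])
}

# spectra (rows = waveforms) through a precomputed basis; optional smoothing
logspec_apply <- function(waves, basis, smooth = TRUE) {
  xc <- waves %*% t(basis$C)
  xs <- waves %*% t(basis$S)
  p <- (sqrt(xc^2 + xs^2) / rep(basis$gain, each = nrow(waves)))^2
  if (smooth) p <- t(apply(p, 1, function(row)
    half_octave_smooth(basis$freqs, row)))
  p
}

#' Bootstrap frequency-wise test of spectral differences
#'
#' Tests, per grid frequency, whether the spectrum of the unshuffled
#' EEG-STA differs from what trial shuffling produces. `n_boot` spectra
#' are computed from STAs of random samples (drawn with replacement,
#' segment count conserved) of the shuffled-trigger segments; the
#' two-tailed p-value per frequency is twice the smaller of the fractions
#' of bootstrap spectra above/below the unshuffled spectrum.
#'
#' @param segments Unshuffled spike-triggered segments matrix.
#' @param shuffled_segments Pooled shuffled segments matrix.
#' @param fs Sampling rate of the segments in Hz.
#' @param n_boot Number of bootstrap spectra (default 500; below 100 a
#'   warning is issued).
#' @param freqs_per_octave Grid density (default 8).
#' @param seed Optional integer seed.
#' @return A list with `freqs`, `p` (two-tailed per frequency),
#'   `observed` (unshuffled smoothed spectrum) and `n_boot`.
#' @export
spectral_bootstrap_test <- function(segments, shuffled_segments, fs,
                                    n_boot = 500, freqs_per_octave = 8,
                                    seed = NULL) {
  if (nrow(segments) == 0 || nrow(shuffled_segments) == 0)
    stop("both segment sets must be non-empty")
  if (n_boot < 100) warning("n_boot below 100 gives coarse p-values")
  if (!is.null(seed)) withr::local_seed(seed)
  basis <- logspec_basis(ncol(segments), fs, freqs_per_octave)
  obs <- logspec_apply(matrix(colMeans(segments), 1), basis)[1, ]
  b <- boot_stas(shuffled_segments, nrow(segments), n_boot)
  bp <- logspec_apply(b, basis)
  hi <- colMeans(bp >= rep(obs, each = n_boot))
  lo <- colMeans(bp <= rep(obs, each = n_boot))
  p <- pmin(2 * pmin(hi, lo), 1)
  list(freqs = basis$freqs, p = p, observed = obs, n_boot = n_boot)
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal formulation; returns an N x K matrix of orthonormal tapers.
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  u <- ev$vectors[, seq_len(k), drop = FALSE]
  # sign convention: nonnegative mean (even orders) / positive initial slope
  for (j in seq_len(k)) {
    s <- sum(u[, j])
    if (abs(s) > 1e-12) {
      if (s < 0) u[, j] <- -u[, j]
    } else if (u[2, j] - u[1, j] < 0) {
      u[, j] <- -u[, j]
    }
  }
  u
}

#' Multitaper power spectral density
#'
#' Slepian-taper PSD with a stated spectral concentration bandwidth. The
#' `bandwidth` argument is the full concentration bandwidth `2W` in Hz;
#' the time-bandwidth product is `NW = duration * W` and the taper count
#' is `floor(2 NW) - 1`. The estimate is one-sided and integrates to the
#' signal variance (`sum(power) * df ~ var(x)`).
#'
#' @param x Signal samples (length >= 8).
#' @param fs Sampling rate in Hz.
#' @param bandwidth Full concentration bandwidth in Hz (default 600).
#' @return A `"spectrum_estimate"` with `freqs` (Hz, 0..Nyquist) and
#'   `power` (signal units squared per Hz); extra fields `n_tapers`, `nw`.
#' @export
multitaper_psd <- function(x, fs, bandwidth = 600) {
  n <- length(x)
  if (n < 8) stop("signal too short for multitaper estimation")
  W <- bandwidth / 2
  nw <- n / fs * W
  if (nw < 1)
    stop("bandwidth incompatible with signal duration (NW < 1)")
  k <- max(1L, floor(2 * nw) - 1L)
  u <- dpss_tapers(n, nw, k)
  spec <- matrix(0, n, k)
  for (j in seq_len(k))
    spec[, j] <- Mod(stats::fft(u[, j] * x))^2 / fs
  two_sided <- rowMeans(spec)
  n_half <- floor(n / 2) + 1L
  one <- two_sided[seq_len(n_half)]
  mult <- rep(2, n_half)
  mult[1] <- 1
  if (n %% 2 == 0) mult[n_half] <- 1
  structure(
    list(freqs = (seq_len(n_half) - 1) * fs / n, power = one * mult,
         smoothed = FALSE, n_tapers = k, nw = nw),
    class = "spectrum_estimate")
}

#' Fast/slow band-power ratio (desynchronization index)
#'
#' Ratio of power in a fast band (default 15-75 Hz) to a slow band
#' (default 1-10 Hz), computed from the periodogram. In the awake,
#' desynchronized cortical state this ratio is high. The evoked average
#' should be subtracted from the input beforehand.
#'
#' @param x Signal samples (evoked average already removed).
#' @param fs Sampling rate in Hz.
#' @param fast_band,slow_band Length-2 frequency bands in Hz.
#' @return The fast/slow band-power ratio.
#' @export
desync_ratio <- function(x, fs, fast_band = c(15, 75),
                         slow_band = c(1, 10)) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- abs(dft_freqs(n, fs))
  band_power <- function(b) sum(p[f >= b[1] & f <= b[2]])
  band_power(fast_band) / band_power(slow_band)
}
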