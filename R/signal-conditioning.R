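#' Band-pass filter specification with Gaussian-smoothed transitions
#'
#' Describes a zero-phase Fourier-domain band-pass filter. The frequency
#' response is the ideal band indicator convolved with a Gaussian whose
#' half-width at half-maximum is `transition_halfwidth`; the response is 0.5
#' at each cutoff and the smooth transitions suppress ringing in the impulse
#' response. Leave `f_lo` or `f_hi` as `NULL` for high-/low-pass variants.
#'
#' @param f_lo Lower cutoff in Hz, or `NULL`.
#' @param f_hi Upper cutoff in Hz, or `NULL`.
#' @param transition_halfwidth Gaussian half-width at half-maximum in Hz
#'   (default 117).
#' @return An object of class `"filter_spec"`.
#' @examples
#' hf_band()        # 800-3000 Hz high-frequency preset
#' wideband()       # 3-3000 Hz wideband preset
#' @export
filter_spec <- function(f_lo = NULL, f_hi = NULL, transition_halfwidth = 117) {
  if (is.null(f_lo) && is.null(f_hi))
    stop("at least one of f_lo, f_hi must be given")
  if (!is.null(f_lo) && f_lo < 0) stop("f_lo must be nonnegative")
  if (!is.null(f_hi) && f_hi <= 0) stop("f_hi must be positive")
  if (!is.null(f_lo) && !is.null(f_hi) && f_lo >= f_hi)
    stop("f_lo must be below f_hi")
  if (transition_halfwidth <= 0) stop("transition_halfwidth must be positive")
  structure(list(f_lo = f_lo, f_hi = f_hi,
                 transition_halfwidth = transition_halfwidth),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
hf_band <- function() filter_spec(800, 3000)

#' @rdname filter_spec
#' @export
wideband <- function() filter_spec(3, 3000)

# Gaussian-smoothed band mask evaluated at (possibly negative) frequencies.
band_mask <- function(freqs, spec) {
  sigma <- spec$transition_halfwidth / sqrt(2 * log(2))
  af <- abs(freqs)
  if (!is.null(spec$f_lo) && !is.null(spec$f_hi)) {
    stats::pnorm((af - spec$f_lo) / sigma) - stats::pnorm((af - spec$f_hi) / sigma)
  } else if (!is.null(spec$f_lo)) {
    stats::pnorm((af - spec$f_lo) / sigma)
  } else {
    stats::pnorm((spec$f_hi - af) / sigma)
  }
}

#' Zero-phase Fourier-domain band-pass filter
#'
#' Filters a signal by multiplying its discrete Fourier transform with the
#' Gaussian-smoothed band mask of `spec` and transforming back. The mask is
#' real and even in frequency, so the filter is non-causal and exactly
#' phase-preserving. No padding is applied (the DFT is circular); analysis
#' windows should be extracted after filtering whole trials so that
#' wrap-around at the trial edges does not reach them.
#'
#' @param x Numeric signal (one trial).
#' @param fs Sampling rate in Hz; must satisfy `fs >= 2 * f_hi`.
#' @param spec A `"filter_spec"`.
#' @return Filtered signal, same length as `x`.
#' @export
fourier_bandpass <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x))
  if (!all(is.finite(x))) stop("signal must be finite")
  check_band(spec, fs)
  n <- length(x)
  m <- band_mask(dft_freqs(n, fs), spec)
  Re(stats::fft(stats::fft(x) * m, inverse = TRUE)) / n
}

#' Filter every trial of a trials-by-samples matrix
#'
#' @param trials Numeric matrix, one trial per row.
#' @inheritParams fourier_bandpass
#' @return Matrix of the same shape.
#' @export
filter_trials <- function(trials, fs, spec) {
  stopifnot(is.matrix(trials), inherits(spec, "filter_spec"))
  check_band(spec, fs)
  n <- ncol(trials)
  m <- band_mask(dft_freqs(n, fs), spec)
  y <- stats::mvfft(t(trials)) * m
  t(Re(stats::mvfft(y, inverse = TRUE)) / n)
}

check_band <- function(spec, fs) {
  top <- if (!is.null(spec$f_hi)) spec$f_hi else spec$f_lo
  if (top > fs / 2) stop("band edge exceeds the Nyquist frequency")
  invisible(TRUE)
}

dft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  ifelse(f > fs / 2, f - fs, f)
}

#' Linear-interpolation upsampling
#'
#' Evaluates the piecewise-linear interpolant of `x` on the output-rate grid
#' spanning the same time interval. The output has
#' `floor((n - 1) * fs_out / fs_in) + 1` samples.
#'
#' @param x Numeric signal.
#' @param fs_in Input sampling rate in Hz.
#' @param fs_out Output sampling rate in Hz (`>= fs_in`).
#' @return Upsampled signal.
#' @export
upsample_linear <- function(x, fs_in, fs_out) {
  if (length(x) == 0) stop("empty input")
  if (fs_out < fs_in) stop("fs_out must be >= fs_in (no decimation)")
  n <- length(x)
  if (n == 1) return(x)
  n_out <- floor((n - 1) * fs_out / fs_in) + 1
  t_in <- (0:(n - 1)) / fs_in
  t_out <- pmin((0:(n_out - 1)) / fs_out, t_in[n])
  stats::approx(t_in, x, xout = t_out)$y
}

#' Upsample every trial of a trials-by-samples matrix
#'
#' @param trials Numeric matrix, one trial per row.
#' @inheritParams upsample_linear
#' @return Matrix with the same number of rows and the upsampled number of
#'   columns.
#' @export
upsample_trials <- function(trials, fs_in, fs_out) {
  stopifnot(is.matrix(trials))
  n <- ncol(trials)
  if (n == 0) stop("empty input")
  if (fs_out < fs_in) stop("fs_out must be >= fs_in (no decimation)")
  n_out <- floor((n - 1) * fs_out / fs_in) + 1
  pos <- (0:(n_out - 1)) * fs_in / fs_out  # in units of input samples
  pos <- pmin(pos, n - 1)
  i0 <- pmin(floor(pos), n - 2)
  frac <- pos - i0
  trials[, i0 + 1, drop = FALSE] * rep(1 - frac, each = nrow(trials)) +
    trials[, i0 + 2, drop = FALSE] * rep(frac, each = nrow(trials))
}
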