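#' Closed-form spike-triggered EEG contribution of a correlated population
#'
#' If `N` neurons each contribute a Mexican-hat kernel `g(t)` to the surface
#' EEG and each is correlated with the trigger neuron according to a Gaussian
#' cross-correlogram `f(t)`, the expected spike-triggered average contributed
#' by the population is `N * (f * g)(t)` (convolution over time). Because the
#' Mexican hat is the negative second derivative of a Gaussian, the
#' convolution is again a Mexican hat with
#' \deqn{b_c = b_{xcf} + b_{STA}, \qquad
#'   A_c = \frac{2\sqrt{\pi}\, N\, a_{xcf}\, a_{STA}
#'         \sqrt{b_{xcf} b_{STA}}}{(b_{xcf}+b_{STA})^{3/2}}, \qquad
#'   T_c = \sqrt{6 (b_{xcf} + b_{STA})}.}
#' Rates are converted from coincidences/s to 1/ms internally so that the
#' amplitude comes out in nV when `a_STA` is in nV ms^2.
#'
#' @param hat A `"mexican_hat"` kernel (single-neuron EEG contribution).
#' @param xcf A `"gaussian_xcf"` cross-correlogram.
#' @param N Number of contributing neurons (>= 0).
#' @return An object of class `"correlation_sta"`: fields `N`, `A_cSTA` (nV),
#'   `T_cSTA` (ms) and `hat`, a `"mexican_hat"` holding the full waveform
#'   (evaluate it with [mexhat_eval()]).
#' @examples
#' hat <- mexhat_from_amp_width(60, 0.45, 0.05)
#' xcf <- gaussian_from_peak_width(0.008, 17)
#' cs <- correlation_sta_closed_form(hat, xcf, N = 1e7)
#' c(cs$A_cSTA, cs$T_cSTA)  # ~0.51 nV, ~25 ms
#' @export
correlation_sta_closed_form <- function(hat, xcf, N) {
  stopifnot(inherits(hat, "mexican_hat"), inherits(xcf, "gaussian_xcf"))
  if (!is.numeric(N) || length(N) != 1L || N < 0)
    stop("N must be a single nonnegative number")
  a_x <- xcf$a_xcf / 1000  # coincidences/s -> 1/ms
  b_x <- xcf$b_xcf
  b_s <- hat$b_sta
  b_c <- b_x + b_s
  a_c <- N * a_x * hat$a_sta * sqrt(pi * b_x * b_s / b_c)
  out_hat <- mexican_hat(a_c, b_c, hat$t_sta)
  structure(
    list(N = N, A_cSTA = out_hat$A_STA, T_cSTA = out_hat$T_STA, hat = out_hat),
    class = "correlation_sta")
}

#' @export
print.correlation_sta <- function(x, ...) {
  cat(sprintf("Correlation STA (N = %.3g neurons): A = %.3g nV, T = %.3g ms\n",
              x$N, x$A_cSTA, x$T_cSTA))
  invisible(x)
}

#' Sweep the correlation-STA amplitude and width over spike jitter
#'
#' Evaluates the closed-form population contribution for a range of
#' cross-correlogram widths (spike jitters), keeping the peak coincidence
#' rate fixed. The width of the resulting waveform grows monotonically with
#' jitter while its amplitude peaks at `jitter = T_STA / sqrt(3)` and decays
#' beyond it, so broad correlations contribute negligibly.
#'
#' @param hat A `"mexican_hat"` single-neuron kernel.
#' @param A_xcf Peak excess coincidence rate (coincidences/s).
#' @param N Number of contributing neurons.
#' @param jitter_grid Cross-correlogram half-amplitude widths in ms (> 0).
#' @return A data.frame with columns `jitter_ms`, `amplitude_nV`, `width_ms`.
#' @export
jitter_sweep <- function(hat, A_xcf, N, jitter_grid) {
  if (any(jitter_grid <= 0)) stop("jitter values must be positive")
  res <- lapply(jitter_grid, function(j) {
    cs <- correlation_sta_closed_form(hat, gaussian_from_peak_width(A_xcf, j), N)
    c(amplitude_nV = cs$A_cSTA, width_ms = cs$T_cSTA)
  })
  res <- do.call(rbind, res)
  data.frame(jitter_ms = jitter_grid,
             amplitude_nV = res[, "amplitude_nV"],
             width_ms = res[, "width_ms"])
}

#' Fit a Mexican-hat kernel to an averaged waveform
#'
#' Least-squares fit of the triphasic Mexican-hat model to a spike-triggered
#' average, using Levenberg-Marquardt with a positivity bound on the squared
#' width. The initial guess is derived from the waveform's extrema unless
#' supplied.
#'
#' @param waveform Waveform samples (nV).
#' @param lags Lag axis in ms, same length as `waveform`.
#' @param initial Optional `"mexican_hat"` initial guess.
#' @return The fitted `"mexican_hat"`, with attributes `residual_rms` and
#'   `fit` (the underlying `nlsLM` object).
#' @export
fit_mexican_hat <- function(waveform, lags, initial = NULL) {
  stopifnot(length(waveform) == length(lags))
  if (stats::sd(waveform) == 0)
    stop("degenerate input: waveform has no variance, cannot fit")
  if (is.null(initial)) {
    i_pk <- which.max(abs(waveform))
    t0 <- lags[i_pk]
    A0 <- abs(waveform[i_pk])
    # side-lobe separation from the two minima flanking the main peak
    lo <- which.min(waveform[lags < t0])
    hi <- which(lags > t0)[which.min(waveform[lags > t0])]
    T0 <- if (length(lo) && length(hi)) lags[hi] - lags[lo] else diff(range(lags)) / 4
    if (!is.finite(T0) || T0 <= 0) T0 <- diff(range(lags)) / 4
    initial <- mexhat_from_amp_width(max(A0, .Machine$double.eps), T0, t0)
  }
  if (diff(range(lags)) < 3 * initial$T_STA)
    stop("waveform must cover at least 3 widths of the initial guess")
  df <- data.frame(t = lags, y = waveform)
  fit <- minpack.lm::nlsLM(
    y ~ (a / b) * (2 - 4 * (t - t0)^2 / b) * exp(-(t - t0)^2 / b),
    data = df,
    start = list(a = initial$a_sta, b = initial$b_sta, t0 = initial$t_sta),
    lower = c(a = -Inf, b = .Machine$double.eps, t0 = min(lags)),
    upper = c(a = Inf, b = Inf, t0 = max(lags)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  out <- mexican_hat(cf[["a"]], cf[["b"]], cf[["t0"]])
  attr(out, "residual_rms") <- sqrt(mean(stats::resid(fit)^2))
  attr(out, "fit") <- fit
  out
}
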