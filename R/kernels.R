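#' Mexican-hat parameterization of the single-spike EEG kernel
#'
#' The average EEG deflection accompanying a single cortical action potential
#' is well described by a "Mexican hat": a zero-mean triphasic function
#' proportional to the negative second derivative of a Gaussian,
#' \deqn{g(t) = \frac{a}{b}\left(2 - \frac{4 (t-t_0)^2}{b}\right)
#'   e^{-(t-t_0)^2 / b},}
#' with scale `a` (nV ms^2), squared-width `b` (ms^2) and peak latency `t_0`
#' (ms). The central peak has amplitude `A = 2 a / b` (nV) and the two
#' negative side lobes are separated by `T = sqrt(6 b)` (ms). `mexhat_from_amp_width()`
#' builds the kernel from the observable amplitude/width pair; `mexican_hat()`
#' builds it directly from `(a, b, t0)`.
#'
#' @param A_STA Central peak amplitude in nV (> 0).
#' @param T_STA Side-lobe separation (width) in ms (> 0).
#' @param t_STA Peak latency in ms (default 0).
#' @return An object of class `"mexican_hat"`: a list with fields `a_sta`,
#'   `b_sta`, `t_sta` and the derived `A_STA` (nV) and `T_STA` (ms).
#' @examples
#' hat <- mexhat_from_amp_width(A_STA = 60, T_STA = 0.45, t_STA = 0.05)
#' hat$A_STA                      # 60 nV
#' mexhat_eval(hat, hat$t_sta)    # equals A_STA at the peak
#' @export
mexhat_from_amp_width <- function(A_STA, T_STA, t_STA = 0) {
  stopifnot(is.numeric(A_STA), is.numeric(T_STA), is.numeric(t_STA))
  if (A_STA <= 0 || T_STA <= 0)
    stop("amplitude and width of a Mexican-hat kernel must be positive")
  b <- T_STA^2 / 6
  a <- A_STA * b / 2
  mexican_hat(a, b, t_STA)
}

#' @param a_sta Scale parameter in nV ms^2.
#' @param b_sta Squared width parameter in ms^2 (> 0).
#' @param t_sta Peak latency in ms.
#' @rdname mexhat_from_amp_width
#' @export
mexican_hat <- function(a_sta, b_sta, t_sta = 0) {
  if (b_sta <= 0) stop("b_sta must be positive")
  structure(
    list(a_sta = a_sta, b_sta = b_sta, t_sta = t_sta,
         A_STA = 2 * a_sta / b_sta, T_STA = sqrt(6 * b_sta)),
    class = "mexican_hat")
}

#' Evaluate a Mexican-hat kernel
#'
#' @param hat A `"mexican_hat"` object.
#' @param t Times in ms.
#' @return Kernel values in nV.
#' @export
mexhat_eval <- function(hat, t) {
  stopifnot(inherits(hat, "mexican_hat"))
  u <- (t - hat$t_sta)^2 / hat$b_sta
  (hat$a_sta / hat$b_sta) * (2 - 4 * u) * exp(-u)
}

#' @export
print.mexican_hat <- function(x, ...) {
  cat(sprintf("Mexican-hat kernel: A = %.3g nV, T = %.3g ms, t0 = %.3g ms\n",
              x$A_STA, x$T_STA, x$t_sta))
  invisible(x)
}

#' Gaussian cross-correlogram of a weakly synchronized neuron pair
#'
#' Pairwise spike synchrony in cortex is weak and broad; the excess
#' coincidence rate around a trigger spike is modelled as a Gaussian,
#' \deqn{f(t) = a\, e^{-t^2 / b},}
#' parameterized by the peak excess rate `A_xcf = a` (coincidences/s) and the
#' half-amplitude width (jitter) `T_xcf = 2 sqrt(b ln 2)` (ms).
#'
#' @param A_xcf Peak excess coincidence rate, coincidences/s (>= 0).
#' @param T_xcf Half-amplitude width (jitter) in ms (> 0).
#' @return An object of class `"gaussian_xcf"`: fields `a_xcf`
#'   (coincidences/s), `b_xcf` (ms^2) and the derived `A_xcf`, `T_xcf`.
#' @examples
#' xcf <- gaussian_from_peak_width(A_xcf = 0.008, T_xcf = 17)
#' xcf$b_xcf  # (17/2)^2 / ln 2
#' @export
gaussian_from_peak_width <- function(A_xcf, T_xcf) {
  if (A_xcf < 0) stop("A_xcf must be nonnegative")
  if (T_xcf <= 0) stop("T_xcf must be positive")
  b <- (T_xcf / 2)^2 / log(2)
  structure(
    list(a_xcf = A_xcf, b_xcf = b, A_xcf = A_xcf, T_xcf = T_xcf),
    class = "gaussian_xcf")
}

#' Evaluate a Gaussian cross-correlogram
#'
#' @param xcf A `"gaussian_xcf"` object.
#' @param t Lags in ms.
#' @return Excess coincidence rate in coincidences/s.
#' @export
gaussian_xcf_eval <- function(xcf, t) {
  stopifnot(inherits(xcf, "gaussian_xcf"))
  xcf$a_xcf * exp(-t^2 / xcf$b_xcf)
}

#' @export
print.gaussian_xcf <- function(x, ...) {
  cat(sprintf("Gaussian cross-correlogram: A = %.3g coinc/s, T = %.3g ms\n",
              x$A_xcf, x$T_xcf))
  invisible(x)
}
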