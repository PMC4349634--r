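#' Source-electrode distance for a bipolar epidural montage
#'
#' For a source at depth `h` below the midpoint of two surface electrodes
#' separated by `d`, the distance from the source to either electrode is
#' `r = sqrt(h^2 + d^2 / 4)`.
#'
#' @param h Source depth in mm (>= 0).
#' @param d Electrode separation in mm (>= 0).
#' @return Distance `r` in mm.
#' @examples
#' electrode_distance(2.18, 10)  # ~5.455 mm
#' @export
electrode_distance <- function(h, d) {
  if (any(h < 0) || any(d < 0)) stop("h and d must be nonnegative")
  sqrt(h^2 + d^2 / 4)
}

#' Dipole-approximation epidural potential of a single action potential
#'
#' Far-field potential of a current dipole in a homogeneous medium,
#' \deqn{V = \kappa \frac{\eta}{4\pi} \frac{Q \cos\theta}{r^2},}
#' where `Q` is the dipole moment, `eta` the tissue resistivity, `theta`
#' the angle from the dipole axis and `r` the source-electrode distance.
#' The boundary factor `kappa` (default 4) accounts for the resistivity
#' boundary at the skull opening and the bipolar electrode montage.
#' Computing in Ohm mm, nA mm and mm yields nV with no further constants;
#' `eta` is accepted in the conventional Ohm m and converted internally.
#'
#' @param Q Dipole moment in nA mm (>= 0).
#' @param eta Tissue resistivity in Ohm m (> 0).
#' @param theta Angle from the dipole axis in radians (default 0).
#' @param h,d Source depth and electrode separation in mm (used to derive
#'   `r` unless `r` is given directly).
#' @param r Source-electrode distance in mm (> 0).
#' @param boundary_factor Dimensionless boundary/montage factor (default 4).
#' @return Potential in nV.
#' @examples
#' dipole_potential(Q = 0.78, eta = 2.47, theta = 0, h = 2.18, d = 10)
#' @export
dipole_potential <- function(Q, eta, theta = 0, h = NULL, d = NULL,
                             r = NULL, boundary_factor = 4) {
  if (any(Q < 0)) stop("Q must be nonnegative")
  if (eta <= 0) stop("eta must be positive")
  if (boundary_factor <= 0) stop("boundary_factor must be positive")
  if (is.null(r)) {
    if (is.null(h) || is.null(d)) stop("give either r or both h and d")
    r <- electrode_distance(h, d)
  }
  if (any(r <= 0)) stop("r must be positive")
  eta_mm <- eta * 1000  # Ohm m -> Ohm mm
  boundary_factor * eta_mm / (4 * pi) * Q * cos(theta) / r^2
}

#' Extrapolate epidural spike correlates to the human scalp
#'
#' Scales an epidural single-spike amplitude range down by the observed
#' scalp-versus-epidural burst attenuation and by the larger number of
#' responding neurons in the human cortex (both default 10, i.e. a
#' combined factor 100).
#'
#' @param V_lo,V_hi Epidural amplitude bounds in nV.
#' @param burst_attenuation Scalp/epidural burst amplitude ratio (> 0).
#' @param neuron_ratio Human/macaque responding-population ratio (> 0).
#' @return Length-2 numeric: the scaled `(lo, hi)` bounds in nV.
#' @export
scalp_extrapolation <- function(V_lo, V_hi, burst_attenuation = 10,
                                neuron_ratio = 10) {
  if (burst_attenuation <= 0 || neuron_ratio <= 0)
    stop("scaling factors must be positive")
  c(V_lo, V_hi) / (burst_attenuation * neuron_ratio)
}

#' Amplitude signal-to-noise ratio in decibels
#'
#' `10 log10(signal / noise)` on amplitudes, the convention used when
#' quoting spike-correlate detectability (e.g. 0.7 nV against 300 nV of
#' amplifier noise gives about -26 dB).
#'
#' @param signal_amp,noise_amp Amplitudes in the same units (> 0).
#' @return SNR in dB.
#' @export
snr_db <- function(signal_amp, noise_amp) {
  if (any(signal_amp <= 0) || any(noise_amp <= 0))
    stop("amplitudes must be positive")
  10 * log10(signal_amp / noise_amp)
}

#' Broadband amplifier noise over a frequency band
#'
#' Converts a noise spectral density (nV per sqrt Hz) into an RMS
#' amplitude over a band of the given width.
#'
#' @param density_nv_sqrthz Noise density in nV/sqrt(Hz).
#' @param band_hz Band width in Hz.
#' @return RMS noise amplitude in nV.
#' @export
noise_over_band <- function(density_nv_sqrthz = 10, band_hz = 1000) {
  if (density_nv_sqrthz < 0 || band_hz < 0) stop("inputs must be nonnegative")
  density_nv_sqrthz * sqrt(band_hz)
}
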