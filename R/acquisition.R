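#' Acquisition parameters for a 31P FID
#'
#' Bundles the spectrometer settings needed to interpret a free induction
#' decay: the 31P carrier frequency, the number of complex samples, the dwell
#' time, and the chemical-shift reference convention (phosphocreatine at
#' 0 ppm).
#'
#' The defaults describe a 3 T whole-body system: at 2.89 T the 31P Larmor
#' frequency is close to 49.9 MHz, and 1024 complex points at a 0.25 ms dwell
#' give a 4 kHz sweep, i.e. about \[-40, +40\] ppm around the carrier --
#' comfortably covering the \[-20, +10\] ppm range where brain phosphorus
#' metabolites resonate.
#'
#' @param spectrometer_freq 31P Larmor frequency in MHz. One ppm of chemical
#'   shift corresponds to `spectrometer_freq` Hz.
#' @param n_points Number of complex time-domain samples (>= 64).
#' @param dwell_time Sampling interval in seconds; the spectral width is
#'   `1/dwell_time` Hz.
#' @param reference_shift Chemical shift assigned to the reference resonance,
#'   in ppm (PCr = 0 by convention).
#'
#' @return An object of class `p31_acq`: a list with the four fields above.
#' @examples
#' acq <- acq_params()
#' ppm_to_hz(1, acq)
#' @export
acq_params <- function(spectrometer_freq = 49.9,
                       n_points = 1024L,
                       dwell_time = 0.25e-3,
                       reference_shift = 0) {
  if (!is.numeric(spectrometer_freq) || spectrometer_freq <= 0) {
    abort("`spectrometer_freq` must be a positive number (MHz).")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 64L) {
    abort("`n_points` must be an integer >= 64.")
  }
  if (!is.numeric(dwell_time) || dwell_time <= 0) {
    abort("`dwell_time` must be a positive number (seconds).")
  }
  sw_ppm <- (1 / dwell_time) / spectrometer_freq
  if (sw_ppm < 30) {
    abort(sprintf(
      "Spectral width %.1f ppm does not cover the 31P range [-20, +10] ppm.",
      sw_ppm
    ))
  }
  structure(
    list(
      spectrometer_freq = spectrometer_freq,
      n_points = n_points,
      dwell_time = dwell_time,
      reference_shift = reference_shift
    ),
    class = "p31_acq"
  )
}

#' @export
print.p31_acq <- function(x, ...) {
  cat(sprintf(
    "<p31_acq> %.3f MHz, %d pts, dwell %.4g ms (sweep %.0f Hz)\n",
    x$spectrometer_freq, x$n_points, x$dwell_time * 1e3, 1 / x$dwell_time
  ))
  invisible(x)
}

#' Convert a chemical shift to a frequency offset
#'
#' A shift of `delta` ppm corresponds to an offset of
#' `delta * spectrometer_freq` Hz from the reference frequency. The sign
#' convention is the usual NMR one: positive ppm means a positive frequency
#' offset, and it is used consistently by [synthesize_fid()] and
#' [fit_spectrum()].
#'
#' @param delta Chemical shift(s) in ppm, relative to the reference.
#' @param acq A [acq_params()] object.
#' @return Frequency offset(s) in Hz.
#' @examples
#' ppm_to_hz(-8.3, acq_params()) # NAD(H) offset at 49.9 MHz
#' @export
ppm_to_hz <- function(delta, acq) {
  stopifnot(inherits(acq, "p31_acq"))
  if (!is.numeric(delta) || any(!is.finite(delta))) {
    abort("`delta` must be finite numeric (ppm).")
  }
  delta * acq$spectrometer_freq
}

#' @rdname ppm_to_hz
#' @param freq Frequency offset(s) in Hz.
#' @export
hz_to_ppm <- function(freq, acq) {
  stopifnot(inherits(acq, "p31_acq"))
  if (!is.numeric(freq) || any(!is.finite(freq))) {
    abort("`freq` must be finite numeric (Hz).")
  }
  freq / acq$spectrometer_freq
}

# Time axis (seconds) of an acquisition, starting at t = 0.
time_axis <- function(acq) {
  (seq_len(acq$n_points) - 1) * acq$dwell_time
}
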