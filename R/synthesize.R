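#' Synthesize a free induction decay from Lorentzian components
#'
#' Evaluates the time-domain model
#' \deqn{y(t_n) = \sum_k a_k w_k e^{i\phi_k} e^{(-d_k + 2\pi i f_k) t_n}}
#' where \eqn{a_k} is the component amplitude, \eqn{w_k} its relative weight
#' within a multiplet, \eqn{\phi_k} its phase, \eqn{d_k} the Lorentzian
#' decay rate (1/s) and \eqn{f_k} the frequency offset in Hz obtained from
#' the chemical shift via [ppm_to_hz()]. Independent Gaussian noise of
#' standard deviation `noise_sd` is added to the real and imaginary channel
#' of every sample.
#'
#' @param components A component tibble with columns `shift_ppm`, `damping`,
#'   `amplitude`, `phase` and optionally `relative_weight` (default 1), e.g.
#'   from [make_components()].
#' @param acq An [acq_params()] object.
#' @param noise_sd Noise standard deviation per channel (a.u.), >= 0.
#' @param seed Optional integer; if given, the noise stream is seeded so the
#'   same call reproduces the identical signal.
#'
#' @return A `p31_fid`: list with `samples` (complex vector of length
#'   `acq$n_points`), `acq`, and `truth` (the component table).
#' @examples
#' basis <- build_basis()
#' comps <- make_components(basis, c(PCr = 1))
#' fid <- synthesize_fid(comps, basis_acq(basis))
#' fid$samples[1] # = 1 + 0i at t = 0
#' @export
synthesize_fid <- function(components, acq, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(acq, "p31_acq"))
  if (!is.data.frame(components) || nrow(components) == 0) {
    abort("`components` must be a non-empty data frame.")
  }
  req <- c("shift_ppm", "damping", "amplitude", "phase")
  miss <- setdiff(req, names(components))
  if (length(miss)) abort(paste0("Missing component columns: ", paste(miss, collapse = ", ")))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a single number >= 0.")
  }
  if (any(components$damping <= 0)) abort("Component dampings must be > 0.")
  w <- components$relative_weight %||% rep(1, nrow(components))

  t <- time_axis(acq)
  f <- ppm_to_hz(components$shift_ppm, acq)
  y <- model_signal(t, components$amplitude * w, components$damping, f,
                    components$phase)
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(as.integer(seed))
    y <- y + complex(
      real = rnorm(length(y), sd = noise_sd),
      imaginary = rnorm(length(y), sd = noise_sd)
    )
  }
  new_fid(y, acq, truth = components)
}

# Core model evaluation: sum of damped complex sinusoids.
# amp here is the per-line amplitude (entity amplitude x weight).
model_signal <- function(t, amp, damping, freq_hz, phase) {
  y <- complex(real = rep(0, length(t)))
  for (k in seq_along(amp)) {
    if (amp[k] == 0) next
    y <- y + amp[k] * exp(complex(imaginary = phase[k])) *
      exp((-damping[k] + 2i * pi * freq_hz[k]) * t)
  }
  y
}

new_fid <- function(samples, acq, truth = NULL) {
  if (length(samples) != acq$n_points) {
    abort("FID length does not match acq$n_points.")
  }
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples)))) {
    abort("FID contains non-finite samples.")
  }
  structure(list(samples = samples, acq = acq, truth = truth),
            class = "p31_fid")
}

#' @export
print.p31_fid <- function(x, ...) {
  cat(sprintf("<p31_fid> %d complex pts, dwell %.4g ms%s\n",
              length(x$samples), x$acq$dwell_time * 1e3,
              if (!is.null(x$truth)) ", with truth" else ""))
  invisible(x)
}

#' Discrete spectrum of a FID
#'
#' Fourier-transforms the FID and returns a tidy table with the frequency
#' axis in both Hz and ppm (reference at 0 ppm, decreasing-ppm convention
#' left-to-right when plotted with [autoplot.p31_fid()]).
#'
#' @param fid A `p31_fid`.
#' @return A tibble with columns `ppm`, `hz`, `real`, `imag`, `mag`,
#'   ordered by decreasing ppm.
#' @export
fid_spectrum <- function(fid) {
  stopifnot(inherits(fid, "p31_fid"))
  n <- length(fid$samples)
  x <- fft(fid$samples)
  m <- seq_len(n) - 1
  fr <- m / (n * fid$acq$dwell_time)
  fr <- ifelse(m > n / 2, fr - 1 / fid$acq$dwell_time, fr)
  out <- tibble(
    ppm = hz_to_ppm(fr, fid$acq),
    hz = fr,
    real = Re(x),
    imag = Im(x),
    mag = Mod(x)
  )
  arrange(out, desc(.data$ppm))
}

#' @describeIn fid_spectrum Magnitude-spectrum plot of a FID (and its truth
#'   component positions, when present).
#' @param object,... `p31_fid`; further arguments ignored.
#' @method autoplot p31_fid
#' @export
autoplot.p31_fid <- function(object, ...) {
  sp <- fid_spectrum(object)
  p <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$ppm, y = .data$mag)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "|spectrum| (a.u.)")
  if (!is.null(object$truth)) {
    p <- p + ggplot2::geom_vline(
      data = object$truth[object$truth$amplitude > 0, ],
      ggplot2::aes(xintercept = .data$shift_ppm),
      linetype = 3, colour = "grey50"
    )
  }
  p
}

#' Read and write FID containers
#'
#' The on-disk container is a plain two-column CSV (`real`, `imag`; one row
#' per time point) accompanied by a JSON sidecar `<path>.json` holding the
#' acquisition metadata (`freq_mhz`, `dwell_s`, `n_points`,
#' `reference_shift`) and, optionally, the ground-truth component table of a
#' synthetic signal.
#'
#' @param fid A `p31_fid`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_fid()` returns `path` invisibly; `read_fid()` returns a
#'   `p31_fid`.
#' @export
write_fid <- function(fid, path) {
  stopifnot(inherits(fid, "p31_fid"))
  utils::write.csv(
    data.frame(real = Re(fid$samples), imag = Im(fid$samples)),
    path, row.names = FALSE
  )
  meta <- list(
    freq_mhz = fid$acq$spectrometer_freq,
    dwell_s = fid$acq$dwell_time,
    n_points = fid$acq$n_points,
    reference_shift = fid$acq$reference_shift
  )
  if (!is.null(fid$truth)) meta$truth <- fid$truth
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fid
#' @export
read_fid <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("Missing metadata sidecar: ", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dat <- utils::read.csv(path)
  acq <- acq_params(
    spectrometer_freq = meta$freq_mhz,
    n_points = meta$n_points,
    dwell_time = meta$dwell_s,
    reference_shift = meta$reference_shift %||% 0
  )
  truth <- if (!is.null(meta$truth)) as_tibble(meta$truth) else NULL
  new_fid(complex(real = dat$real, imaginary = dat$imag), acq, truth = truth)
}
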