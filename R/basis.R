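#' Default chemical-shift table for the 31P brain spectrum
#'
#' One row per spectral entity (metabolite or multiplet), with its centre
#' shift relative to PCr = 0 ppm and whether the shift is held fixed during
#' fitting. PCr defines the reference and is fixed at 0.00 ppm; the
#' macromolecule baseline component (MM) is fixed at 2.2 ppm and NAD(H) at
#' -8.3 ppm -- these two are included as prior knowledge to stabilise the
#' fit of the crowded phosphodiester and alpha-ATP regions, but are excluded
#' from reporting by default (see [fit_spectrum()]).
#'
#' The remaining positions are literature-typical values for human brain at
#' 3 T and are tunable: phosphoethanolamine (PE) 6.78, phosphocholine (PC)
#' 6.24, inorganic phosphate (Pi) 4.82, glycerophosphoethanolamine (GPE)
#' 3.50, glycerophosphocholine (GPC) 2.94, gamma-ATP -2.48, alpha-ATP -7.52
#' ppm. The beta-ATP default of -16.75 ppm is chosen so that the basis
#' position coincides with the default magnesium calibration
#' ([mg_cal()]) evaluated at a brain-typical free Mg2+ of ~0.105 mMol,
#' keeping the spectral model and the Mg2+ read-out mutually consistent.
#'
#' @return A tibble with columns `metabolite`, `shift_ppm`, `fixed`.
#' @examples
#' default_shift_table()
#' @export
default_shift_table <- function() {
  tibble(
    metabolite = c(
      "PE", "PC", "Pi", "GPE", "GPC", "MM", "PCr",
      "ATP_gamma", "ATP_alpha", "NADH", "ATP_beta"
    ),
    shift_ppm = c(6.78, 6.24, 4.82, 3.50, 2.94, 2.2, 0.00,
                  -2.48, -7.52, -8.3, -16.75),
    fixed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
              FALSE, FALSE, TRUE, FALSE)
  )
}

# Entities that make up each reporting group.
.group_members <- list(
  PME  = c("PE", "PC"),
  PDE  = c("GPE", "GPC"),
  Pi   = "Pi",
  PCr  = "PCr",
  ATP  = c("ATP_gamma", "ATP_alpha", "ATP_beta"),
  MM   = "MM",
  NADH = "NADH"
)

#' Build the 15-component Lorentzian basis set
#'
#' Constructs the standard fitting model for the in vivo 31P brain spectrum:
#' 15 Lorentzian-shaped exponentially decaying sinusoids. Eight entities are
#' singlets (PE, PC, Pi, GPE, GPC, MM, PCr, NAD(H)); ATP contributes two
#' doublets (gamma, alpha) and one triplet (beta) through J-coupling to its
#' neighbouring phosphate groups. Doublet lines are split symmetrically by
#' the J-coupling with weights 1:1; the triplet has lines at centre and
#' centre +/- J with weights 1:2:1. Weights are normalised to sum to one
#' within each multiplet, so an entity's amplitude parameter equals the
#' total area of its multiplet -- which makes the ATP convention "sum the
#' three multiplets and divide by three" unambiguous (see [atp_total()]).
#'
#' @param acq An [acq_params()] object (used to express the J-splitting,
#'   given in Hz, on the ppm axis).
#' @param shifts A shift table like [default_shift_table()]: columns
#'   `metabolite`, `shift_ppm`, `fixed`, one row per entity.
#' @param j_coupling Scalar J-coupling in Hz applied to all ATP multiplets.
#'   The spacing between adjacent multiplet lines equals `j_coupling`.
#'
#' @return A `p31_basis`: a tibble with one row per sinusoid component and
#'   columns `component`, `metabolite`, `multiplet`, `center_ppm`,
#'   `offset_hz`, `shift_ppm`, `relative_weight`, `fixed`. Attributes carry
#'   the acquisition, the J-coupling and the reporting-group map.
#' @examples
#' basis <- build_basis(acq_params())
#' nrow(basis) # 15
#' @export
build_basis <- function(acq = acq_params(),
                        shifts = default_shift_table(),
                        j_coupling = 16.3) {
  stopifnot(inherits(acq, "p31_acq"))
  if (!is.numeric(j_coupling) || j_coupling <= 0) {
    abort("`j_coupling` must be a positive number (Hz).")
  }
  required <- default_shift_table()$metabolite
  if (!is.data.frame(shifts) ||
      !all(c("metabolite", "shift_ppm", "fixed") %in% names(shifts))) {
    abort("`shifts` must have columns metabolite, shift_ppm, fixed.")
  }
  if (anyDuplicated(shifts$metabolite)) {
    abort("Duplicate metabolite names in the shift table.")
  }
  missing <- setdiff(required, shifts$metabolite)
  if (length(missing)) {
    abort(paste0("Shift table is missing: ", paste(missing, collapse = ", ")))
  }

  multiplet_of <- function(m) {
    if (grepl("^ATP_", m)) m else NA_character_
  }
  rows <- purrr::map(required, function(m) {
    sh <- shifts[match(m, shifts$metabolite), ]
    if (identical(m, "ATP_beta")) {
      k <- c(-1, 0, 1)
      w <- c(1, 2, 1) / 4
    } else if (grepl("^ATP_", m)) {
      k <- c(-0.5, 0.5)
      w <- c(1, 1) / 2
    } else {
      k <- 0
      w <- 1
    }
    tibble(
      component = if (length(k) == 1) m else paste0(m, "_", seq_along(k)),
      metabolite = m,
      multiplet = multiplet_of(m),
      center_ppm = sh$shift_ppm,
      offset_hz = k * j_coupling,
      relative_weight = w,
      fixed = sh$fixed
    )
  })
  out <- bind_rows(rows)
  out$shift_ppm <- out$center_ppm + hz_to_ppm(out$offset_hz, acq)
  out <- out[order(-out$shift_ppm), ]
  out <- as_tibble(out)
  attr(out, "acq") <- acq
  attr(out, "j_coupling") <- j_coupling
  attr(out, "groups") <- .group_members
  class(out) <- c("p31_basis", class(out))
  out
}

#' @export
print.p31_basis <- function(x, ...) {
  cat(sprintf("<p31_basis> %d components, J = %.1f Hz\n",
              nrow(x), attr(x, "j_coupling")))
  NextMethod()
}

basis_acq <- function(basis) attr(basis, "acq")
basis_groups <- function(basis) attr(basis, "groups")

# Entity-level view of a basis: one row per metabolite with its centre
# shift, fixed flag and number of lines.
basis_entities <- function(basis) {
  basis %>%
    group_by(.data$metabolite) %>%
    summarise(
      center_ppm = .data$center_ppm[1],
      fixed = .data$fixed[1],
      n_lines = dplyr::n(),
      .groups = "drop"
    )
}

#' Expand entity parameters into per-line synthesis components
#'
#' Turns per-entity amplitudes (multiplet areas), dampings, phases and
#' optional shift overrides into the per-sinusoid component table consumed
#' by [synthesize_fid()]. Lines within a multiplet inherit the entity's
#' damping and phase, and split the amplitude according to their normalised
#' weights.
#'
#' @param basis A [build_basis()] object.
#' @param amplitudes Named numeric: area per entity (a.u.). Entities not
#'   named get amplitude 0.
#' @param damping Named or scalar numeric: Lorentzian decay rate(s) in 1/s.
#' @param phase Named or scalar numeric: phase(s) in radians.
#' @param shift_overrides Optional named numeric of centre shifts (ppm) that
#'   replace the basis defaults (used e.g. to encode pH into the Pi position
#'   and free Mg2+ into the beta-ATP position).
#'
#' @return A component tibble with columns `component`, `metabolite`,
#'   `shift_ppm`, `damping`, `amplitude`, `phase`, `relative_weight`.
#' @export
make_components <- function(basis, amplitudes, damping = 20, phase = 0,
                            shift_overrides = NULL) {
  stopifnot(inherits(basis, "p31_basis"))
  ents <- unique(basis$metabolite)
  amp <- setNames(rep(0, length(ents)), ents)
  if (!is.null(names(amplitudes))) {
    bad <- setdiff(names(amplitudes), ents)
    if (length(bad)) abort(paste0("Unknown entity: ", paste(bad, collapse = ", ")))
    amp[names(amplitudes)] <- amplitudes
  } else {
    abort("`amplitudes` must be a named numeric vector.")
  }
  expand <- function(x, default) {
    out <- setNames(rep(default, length(ents)), ents)
    if (length(x) == 1 && is.null(names(x))) {
      out[] <- x
    } else if (!is.null(names(x))) {
      out[names(x)] <- x
    }
    out
  }
  dmp <- expand(damping, 20)
  phs <- expand(phase, 0)
  ctr <- setNames(basis_entities(basis)$center_ppm, basis_entities(basis)$metabolite)
  if (!is.null(shift_overrides)) {
    bad <- setdiff(names(shift_overrides), ents)
    if (length(bad)) abort(paste0("Unknown entity: ", paste(bad, collapse = ", ")))
    ctr[names(shift_overrides)] <- shift_overrides
  }
  acq <- basis_acq(basis)
  tibble(
    component = basis$component,
    metabolite = basis$metabolite,
    shift_ppm = unname(ctr[basis$metabolite] + hz_to_ppm(basis$offset_hz, acq)),
    damping = unname(dmp[basis$metabolite]),
    amplitude = unname(amp[basis$metabolite]),
    phase = unname(phs[basis$metabolite]),
    relative_weight = basis$relative_weight
  )
}
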