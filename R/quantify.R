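#' Calibration constants for pH and free magnesium
#'
#' `ph_cal()` parameterises the Henderson--Hasselbalch relation between
#' intracellular pH and the chemical shift of inorganic phosphate relative
#' to PCr,
#' \deqn{pH = pK + \log_{10}\frac{\delta_{Pi} - \delta_{acid}}
#'                               {\delta_{base} - \delta_{Pi}},}
#' with the widely used in vivo constants pK = 6.75, acid limit 3.27 ppm
#' (fully protonated H2PO4-) and base limit 5.69 ppm (fully deprotonated
#' HPO4 2-). These are cited-literature defaults, not values this package
#' derives.
#'
#' `mg_cal()` parameterises the monotone relation between the beta-ATP
#' chemical shift and free Mg2+: the shift interpolates between the limiting
#' positions of Mg-free ATP (`delta_free`, default -18.58 ppm) and fully
#' Mg-complexed ATP (`delta_sat`, default -15.74 ppm), and the complexed
#' fraction \eqn{\phi} follows a one-site binding curve with apparent
#' dissociation constant `kd_mM` (default 10^-4.24 M = 0.0575 mMol):
#' \deqn{\phi = \frac{\delta - \delta_{free}}{\delta_{sat} - \delta_{free}},
#'  \qquad [Mg^{2+}] = K_d \frac{\phi}{1 - \phi}.}
#' Different calibration variants of these constants circulate; the
#' package's testable contract is exact forward/inverse consistency, with
#' the constants fully configurable.
#'
#' @param pK,delta_acid,delta_base pH calibration constants (ppm for the
#'   limits); `delta_acid < delta_base` required.
#' @param delta_free,delta_sat,kd_mM Mg calibration constants: limiting
#'   beta-ATP shifts (ppm) and apparent Kd (mMol).
#' @return A named list of constants.
#' @export
ph_cal <- function(pK = 6.75, delta_acid = 3.27, delta_base = 5.69) {
  if (!(delta_acid < delta_base)) abort("`delta_acid` must be < `delta_base`.")
  list(pK = pK, delta_acid = delta_acid, delta_base = delta_base)
}

#' @rdname ph_cal
#' @export
mg_cal <- function(delta_free = -18.58, delta_sat = -15.74,
                   kd_mM = 10^(-4.24) * 1e3) {
  if (!(delta_free < delta_sat)) abort("`delta_free` must be < `delta_sat`.")
  if (kd_mM <= 0) abort("`kd_mM` must be > 0.")
  list(delta_free = delta_free, delta_sat = delta_sat, kd_mM = kd_mM)
}

#' Intracellular pH from the Pi chemical shift
#'
#' Strictly increasing in the shift over the open interval
#' (`delta_acid`, `delta_base`); [pi_shift_from_ph()] is the exact algebraic
#' inverse.
#'
#' @param delta_pi Pi chemical shift(s) in ppm relative to PCr.
#' @param cal Constants from [ph_cal()].
#' @return pH value(s).
#' @examples
#' ph_from_pi_shift(pi_shift_from_ph(7.092)) # roundtrip
#' @export
ph_from_pi_shift <- function(delta_pi, cal = ph_cal()) {
  if (any(delta_pi <= cal$delta_acid | delta_pi >= cal$delta_base)) {
    abort(sprintf(
      "Pi shift outside the calibration range (%.2f, %.2f) ppm.",
      cal$delta_acid, cal$delta_base
    ))
  }
  cal$pK + log10((delta_pi - cal$delta_acid) / (cal$delta_base - delta_pi))
}

#' @rdname ph_from_pi_shift
#' @param ph pH value(s).
#' @export
pi_shift_from_ph <- function(ph, cal = ph_cal()) {
  u <- 10^(ph - cal$pK)
  (cal$delta_acid + cal$delta_base * u) / (1 + u)
}

#' Free magnesium from the beta-ATP chemical shift
#'
#' Strictly increasing in the shift over the open interval
#' (`delta_free`, `delta_sat`); [beta_shift_from_mg()] is the exact inverse.
#'
#' @param delta_beta beta-ATP centre shift(s) in ppm relative to PCr.
#' @param cal Constants from [mg_cal()].
#' @return Free Mg2+ concentration(s) in mMol.
#' @examples
#' mg_from_beta_shift(beta_shift_from_mg(0.109)) # roundtrip
#' @export
mg_from_beta_shift <- function(delta_beta, cal = mg_cal()) {
  if (any(delta_beta <= cal$delta_free | delta_beta >= cal$delta_sat)) {
    abort(sprintf(
      "beta-ATP shift outside the calibration range (%.2f, %.2f) ppm.",
      cal$delta_free, cal$delta_sat
    ))
  }
  phi <- (delta_beta - cal$delta_free) / (cal$delta_sat - cal$delta_free)
  cal$kd_mM * phi / (1 - phi)
}

#' @rdname mg_from_beta_shift
#' @param mg Free Mg2+ concentration(s) in mMol, > 0.
#' @export
beta_shift_from_mg <- function(mg, cal = mg_cal()) {
  if (any(mg <= 0)) abort("`mg` must be > 0 (mMol).")
  phi <- mg / (mg + cal$kd_mM)
  cal$delta_free + phi * (cal$delta_sat - cal$delta_free)
}

#' Total ATP area
#'
#' The three ATP multiplets (gamma, alpha, beta) each integrate to the full
#' ATP moiety's area, so the reported ATP area is their sum divided by
#' three.
#'
#' @param areas Named numeric with entries `ATP_gamma`, `ATP_alpha`,
#'   `ATP_beta` (multiplet areas), or a `p31_fit`.
#' @return The ATP area. A value of zero is flagged with a
#'   `"degenerate"` attribute.
#' @examples
#' atp_total(c(ATP_gamma = 1, ATP_alpha = 2, ATP_beta = 3)) # 2
#' @export
atp_total <- function(areas) {
  if (inherits(areas, "p31_fit")) {
    est <- areas$estimates
    areas <- setNames(est$amplitude, est$metabolite)
  }
  need <- c("ATP_gamma", "ATP_alpha", "ATP_beta")
  if (!all(need %in% names(areas))) {
    abort("`areas` must name ATP_gamma, ATP_alpha and ATP_beta.")
  }
  out <- sum(areas[need]) / 3
  if (out == 0) attr(out, "degenerate") <- TRUE
  out
}

.ratio_names <- c("PCr_ATP", "Pi_ATP", "PCr_Pi", "PME_PDE", "PME_ATP",
                  "PME_Pi", "PME_PCr", "PDE_ATP", "PDE_Pi", "PDE_PCr")

#' The ten reported metabolite ratios
#'
#' Computes PCr/ATP, Pi/ATP, PCr/Pi, PME/PDE, PME/ATP, PME/Pi, PME/PCr,
#' PDE/ATP, PDE/Pi and PDE/PCr from reporting-group areas. The set is
#' internally consistent by construction: e.g. PCr/Pi equals
#' (PCr/ATP)/(Pi/ATP), and all ratios are invariant to a global rescaling
#' of the areas.
#'
#' @param areas Named numeric with entries `PME`, `PDE`, `Pi`, `PCr`, `ATP`
#'   (ATP already summed and divided by three), or a `p31_fit`.
#' @return A one-row tibble with the ten ratios (columns named e.g.
#'   `PCr_ATP`). Zero denominators yield `NA` entries and an `undefined`
#'   attribute listing the affected ratios; such voxels are excluded
#'   downstream rather than imputed.
#' @examples
#' compute_ratios(c(PME = 0.54, PDE = 0.45, Pi = 0.41, PCr = 1.24, ATP = 1))
#' @export
compute_ratios <- function(areas) {
  if (inherits(areas, "p31_fit")) areas <- areas$group_areas
  need <- c("PME", "PDE", "Pi", "PCr", "ATP")
  if (!all(need %in% names(areas))) {
    abort("`areas` must name PME, PDE, Pi, PCr and ATP.")
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(
    PCr_ATP = safe_div(areas[["PCr"]], areas[["ATP"]]),
    Pi_ATP  = safe_div(areas[["Pi"]], areas[["ATP"]]),
    PCr_Pi  = safe_div(areas[["PCr"]], areas[["Pi"]]),
    PME_PDE = safe_div(areas[["PME"]], areas[["PDE"]]),
    PME_ATP = safe_div(areas[["PME"]], areas[["ATP"]]),
    PME_Pi  = safe_div(areas[["PME"]], areas[["Pi"]]),
    PME_PCr = safe_div(areas[["PME"]], areas[["PCr"]]),
    PDE_ATP = safe_div(areas[["PDE"]], areas[["ATP"]]),
    PDE_Pi  = safe_div(areas[["PDE"]], areas[["Pi"]]),
    PDE_PCr = safe_div(areas[["PDE"]], areas[["PCr"]])
  )
  undefined <- names(out)[vapply(out, is.na, logical(1))]
  if (length(undefined)) attr(out, "undefined") <- undefined
  out
}

#' Quantify a fitted spectrum into the twelve reported metrics
#'
#' Derives the ten metabolite ratios from the fitted group areas, pH from
#' the fitted Pi chemical shift and free Mg2+ from the fitted beta-ATP
#' centre shift. MM and NAD(H) are fitted but take no part in the reported
#' quantities.
#'
#' @param fit A `p31_fit`.
#' @param ph_constants,mg_constants Calibrations ([ph_cal()], [mg_cal()]).
#' @return A one-row tibble: the ten ratio columns plus `pH` and `Mg`
#'   (mMol). Shifts outside their calibration domain yield `NA` with a
#'   warning rather than an error, since a cohort run must survive the odd
#'   degenerate voxel.
#' @export
quantify_fit <- function(fit, ph_constants = ph_cal(), mg_constants = mg_cal()) {
  stopifnot(inherits(fit, "p31_fit"))
  ratios <- compute_ratios(fit$group_areas)
  delta_pi <- fit$estimates$shift_ppm[fit$estimates$metabolite == "Pi"]
  delta_beta <- fit$estimates$shift_ppm[fit$estimates$metabolite == "ATP_beta"]
  ph <- tryCatch(ph_from_pi_shift(delta_pi, ph_constants),
                 error = function(e) NA_real_)
  mg <- tryCatch(mg_from_beta_shift(delta_beta, mg_constants),
                 error = function(e) NA_real_)
  if (is.na(ph) || is.na(mg)) {
    warning("Shift outside calibration range; pH/Mg set to NA.", call. = FALSE)
  }
  mutate(ratios, pH = ph, Mg = mg)
}

.metric_names <- c(.ratio_names, "pH", "Mg")
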