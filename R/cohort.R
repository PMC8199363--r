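#' Regional truth table of the twelve reported metrics
#'
#' Reference mean and SD of each metric (ten ratios, pH, Mg2+ in mMol) for
#' the six region classes, used as the default generating distribution of
#' the synthetic cohort. Six metrics are generated directly as primaries --
#' the four ATP-normalised ratios (PCr/ATP, Pi/ATP, PME/ATP, PDE/ATP), pH
#' and Mg2+ -- because ten ratios of five underlying areas are algebraically
#' dependent: the remaining six ratios are derived per voxel from the
#' primaries (e.g. PCr/Pi = (PCr/ATP)/(Pi/ATP)), so their cohort means are
#' matched approximately rather than exactly. The `primary` column records
#' which is which.
#'
#' @return A tibble with columns `region`, `metric`, `mean`, `sd`,
#'   `primary`.
#' @export
region_truth <- function() {
  regions <- region_levels()
  vals <- list(
    #              CE            T2            adj           dist          contra        healthy
    PCr_ATP = list(c(1.24, 0.24), c(1.30, 0.22), c(1.32, 0.24), c(1.30, 0.22), c(1.30, 0.23), c(1.29, 0.22)),
    PCr_Pi  = list(c(3.56, 1.56), c(4.09, 1.33), c(4.21, 1.43), c(4.32, 1.31), c(4.11, 1.08), c(3.91, 0.97)),
    Pi_ATP  = list(c(0.41, 0.18), c(0.35, 0.14), c(0.35, 0.16), c(0.32, 0.10), c(0.33, 0.10), c(0.34, 0.08)),
    PME_PDE = list(c(1.29, 0.60), c(1.06, 0.46), c(0.97, 0.30), c(0.90, 0.21), c(0.85, 0.23), c(0.85, 0.23)),
    PME_ATP = list(c(0.54, 0.16), c(0.48, 0.11), c(0.50, 0.15), c(0.48, 0.13), c(0.47, 0.13), c(0.49, 0.12)),
    PME_Pi  = list(c(1.50, 0.68), c(1.47, 0.49), c(1.55, 0.55), c(1.58, 0.52), c(1.45, 0.42), c(1.46, 0.44)),
    PME_PCr = list(c(0.44, 0.13), c(0.37, 0.07), c(0.38, 0.09), c(0.37, 0.07), c(0.36, 0.07), c(0.38, 0.08)),
    PDE_ATP = list(c(0.45, 0.11), c(0.48, 0.12), c(0.53, 0.13), c(0.55, 0.13), c(0.57, 0.13), c(0.59, 0.13)),
    PDE_Pi  = list(c(1.27, 0.51), c(1.52, 0.57), c(1.67, 0.59), c(1.80, 0.52), c(1.77, 0.47), c(1.76, 0.50)),
    PDE_PCr = list(c(0.37, 0.10), c(0.38, 0.09), c(0.41, 0.09), c(0.43, 0.09), c(0.44, 0.09), c(0.46, 0.10)),
    pH      = list(c(7.092, 0.07), c(7.089, 0.06), c(7.066, 0.05), c(7.050, 0.04), c(7.049, 0.04), c(7.045, 0.02)),
    Mg      = list(c(0.109, 0.01), c(0.103, 0.03), c(0.105, 0.02), c(0.103, 0.02), c(0.106, 0.02), c(0.103, 0.01))
  )
  primary <- c("PCr_ATP", "Pi_ATP", "PME_ATP", "PDE_ATP", "pH", "Mg")
  purrr::imap(vals, function(v, metric) {
    tibble(
      region = regions,
      metric = metric,
      mean = purrr::map_dbl(v, 1),
      sd = purrr::map_dbl(v, 2),
      primary = metric %in% primary
    )
  }) %>% bind_rows()
}

#' Synthetic diffusion-MRI marginals per region
#'
#' Mean and SD of ADC (10^-3 mm2/s), b1000 (s/mm2) and FA (unitless) for
#' the regions in which diffusion metrics are measured (contrast-enhancing,
#' T2-hyperintense, adjacent). These marginals are synthetic,
#' physiologically plausible defaults -- the diffusion summary statistics
#' are not part of the regional truth table -- and only their rank
#' correlations with the spectroscopy metrics (see [correlation_spec()])
#' carry reference values.
#'
#' @return A tibble with columns `region`, `metric`, `mean`, `sd`.
#' @export
dwi_truth <- function() {
  tibble(
    region = rep(c("contrast_enhancing", "t2_hyperintense", "adjacent"), each = 3),
    metric = rep(c("ADC", "b1000", "FA"), 3),
    mean = c(1.00, 280, 0.15,
             1.40, 260, 0.15,
             0.85, 230, 0.30),
    sd = c(0.25, 60, 0.05,
           0.30, 60, 0.05,
           0.15, 40, 0.08)
  )
}

#' Default MRS--DWI rank-correlation specification
#'
#' The per-region Spearman correlations the synthetic cohort imposes
#' between diffusion metrics and spectroscopy metrics: in the
#' contrast-enhancing region ADC correlates negatively with PCr/ATP (-0.45)
#' and PME/PDE (-0.33), FA positively with PCr/ATP (0.37), b1000 positively
#' with PME/PDE (0.33) and pH (0.46); in the T2-hyperintense region ADC
#' with PME/PDE (0.34); in the adjacent region b1000 with PCr/Pi (-0.37)
#' and PCr/ATP (0.44), and FA with Mg2+ (0.46).
#'
#' @return A tibble with columns `region`, `dwi_metric`, `mrs_metric`,
#'   `rho`.
#' @export
correlation_spec <- function() {
  tibble(
    region = c(rep("contrast_enhancing", 5), "t2_hyperintense",
               rep("adjacent", 3)),
    dwi_metric = c("ADC", "ADC", "FA", "b1000", "b1000",
                   "ADC", "b1000", "b1000", "FA"),
    mrs_metric = c("PCr_ATP", "PME_PDE", "PCr_ATP", "PME_PDE", "pH",
                   "PME_PDE", "PCr_Pi", "PCr_ATP", "Mg"),
    rho = c(-0.45, -0.33, 0.37, 0.33, 0.46, 0.34, -0.37, 0.44, 0.46)
  )
}

#' Synthetic-cohort configuration
#'
#' Bundles everything [generate_cohort()] needs. The defaults are the study
#' conditions the cohort emulates: 32 subjects, 3 voxels per region per
#' subject in each of the six region classes, spectra synthesised at an SNR
#' of 20 (PCr spectral peak over spectral noise SD), and a 20% rate of
#' voxels violating the tissue-fraction rules.
#'
#' @param n_subjects Number of subjects.
#' @param voxels_per_region Voxels per region per subject.
#' @param regions Region labels to generate (subset of [region_levels()]).
#' @param snr Spectral signal-to-noise ratio of the synthesised FIDs
#'   (PCr peak magnitude over spectral noise SD); `Inf` for noiseless.
#' @param qc_violation_rate Expected fraction of voxels generated with
#'   tissue fractions that violate the inclusion rules.
#' @param truth Regional truth table, see [region_truth()].
#' @param dwi DWI marginals, see [dwi_truth()].
#' @param correlations Rank-correlation spec, see [correlation_spec()].
#' @param acq,basis Acquisition and basis set for FID synthesis.
#' @param ph_constants,mg_constants Calibrations used to encode pH and Mg2+
#'   as Pi and beta-ATP shifts (and to decode them after fitting).
#' @param damping_mean Mean Lorentzian decay rate (1/s) of the synthetic
#'   resonances; per-voxel, per-entity rates vary log-normally (10%) around
#'   it.
#' @param mm_amplitude,nadh_amplitude MM and NAD(H) areas relative to the
#'   ATP area.
#' @return A `p31_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 32,
                          voxels_per_region = 3,
                          regions = region_levels(),
                          snr = 20,
                          qc_violation_rate = 0.2,
                          truth = region_truth(),
                          dwi = dwi_truth(),
                          correlations = correlation_spec(),
                          acq = acq_params(),
                          basis = build_basis(acq),
                          ph_constants = ph_cal(),
                          mg_constants = mg_cal(),
                          damping_mean = 20,
                          mm_amplitude = 0.25,
                          nadh_amplitude = 0.15) {
  stopifnot(n_subjects >= 1, voxels_per_region >= 1)
  if (!all(regions %in% region_levels())) abort("Unknown region label.")
  if (any(truth$sd <= 0)) abort("Truth-table SDs must be > 0.")
  if (any(abs(correlations$rho) >= 1)) abort("|rho| must be < 1.")
  if (!is.numeric(snr) || snr <= 0) abort("`snr` must be > 0 (or Inf).")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      voxels_per_region = as.integer(voxels_per_region),
      regions = regions,
      snr = snr,
      qc_violation_rate = qc_violation_rate,
      truth = truth,
      dwi = dwi,
      correlations = correlations,
      acq = acq,
      basis = basis,
      ph_constants = ph_constants,
      mg_constants = mg_constants,
      damping_mean = damping_mean,
      mm_amplitude = mm_amplitude,
      nadh_amplitude = nadh_amplitude
    ),
    class = "p31_cohort_config"
  )
}

# Quantile of a normal truncated to [lo, hi].
qtnorm <- function(p, mean, sd, lo = -Inf, hi = Inf) {
  pa <- pnorm((lo - mean) / sd)
  pb <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(pa + p * (pb - pa))
}

# Physiological truncation bounds per metric for the generator marginals.
metric_bounds <- function(metric) {
  switch(metric,
    pH = c(6.8, 7.4),
    Mg = c(0.04, 0.5),
    c(0, Inf) # ratios: positive
  )
}

# Normal scores of a sample (Gaussianised mid-ranks).
normal_scores <- function(x) qnorm((rank(x) - 0.5) / length(x))

#' Draw per-voxel truth metrics for one region
#'
#' Samples the six primary metrics (four ATP-normalised ratios, pH, Mg2+)
#' from truncated-normal marginals with the configured regional means and
#' SDs (ratios truncated at 0, pH and Mg2+ to their physiological /
#' calibration-representable bands), derives the six dependent ratios, and
#' attaches diffusion metrics through a Gaussian copula that imposes the
#' configured Spearman correlations (target Pearson correlation on the
#' latent scale via 2 sin(pi rho / 6); several targets per diffusion
#' variable are combined by solving the normal-score system, so each pair's
#' marginal rank correlation is preserved).
#'
#' @param config A [cohort_config()].
#' @param region One region label.
#' @param n Number of voxels to draw.
#' @param seed Optional integer seed (bit-identical draws when fixed).
#' @return A tibble with the twelve metric columns plus `ADC`, `b1000`,
#'   `FA` (NA for regions without diffusion marginals).
#' @export
sample_region_metrics <- function(config, region, n, seed = NULL) {
  stopifnot(inherits(config, "p31_cohort_config"))
  if (!region %in% unique(config$truth$region)) {
    abort(paste0("Unknown region: ", region))
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  primaries <- c("PCr_ATP", "Pi_ATP", "PME_ATP", "PDE_ATP", "pH", "Mg")
  tt <- config$truth %>% filter(.data$region == !!region)

  draw_one <- function(metric) {
    row <- tt[tt$metric == metric, ]
    b <- metric_bounds(metric)
    qtnorm(pnorm(rnorm(n)), row$mean, row$sd, b[1], b[2])
  }
  out <- purrr::map(primaries, draw_one) %>% setNames(primaries) %>% as_tibble()
  out <- out %>% mutate(
    PCr_Pi  = .data$PCr_ATP / .data$Pi_ATP,
    PME_PDE = .data$PME_ATP / .data$PDE_ATP,
    PME_Pi  = .data$PME_ATP / .data$Pi_ATP,
    PME_PCr = .data$PME_ATP / .data$PCr_ATP,
    PDE_Pi  = .data$PDE_ATP / .data$Pi_ATP,
    PDE_PCr = .data$PDE_ATP / .data$PCr_ATP
  )
  out <- out[, .metric_names]

  dwi_rows <- config$dwi %>% filter(.data$region == !!region)
  for (dm in c("ADC", "b1000", "FA")) {
    marg <- dwi_rows[dwi_rows$metric == dm, ]
    if (nrow(marg) == 0) {
      out[[dm]] <- NA_real_
      next
    }
    spec <- config$correlations %>%
      filter(.data$region == !!region, .data$dwi_metric == dm)
    if (nrow(spec) == 0 || n < 8) {
      # tiny samples cannot support the rank-correlation structure
      z <- rnorm(n)
    } else {
      zt <- vapply(spec$mrs_metric, function(m) normal_scores(out[[m]]),
                   numeric(n))
      zt <- matrix(zt, nrow = n)
      rho_p <- 2 * sin(pi * spec$rho / 6)
      # small ridge keeps near-collinear score matrices invertible
      sig <- stats::cor(zt) + diag(1e-8, ncol(zt))
      beta <- solve(sig, rho_p)
      btsb <- drop(crossprod(beta, sig %*% beta))
      if (btsb >= 1) {
        # small-sample score correlations can render the exact system
        # infeasible; attenuate all loadings proportionally
        beta <- beta * sqrt((1 - 1e-3) / btsb)
        btsb <- 1 - 1e-3
      }
      v_eps <- 1 - btsb
      z <- drop(zt %*% beta) + sqrt(v_eps) * rnorm(n)
      z <- z / sd(z)
    }
    out[[dm]] <- qtnorm(pnorm(z), marg$mean, marg$sd, 0, Inf)
  }
  out
}

#' Encode a metric vector as ground-truth spectral components
#'
#' The inverse of the quantification chain: ATP-normalised ratios become
#' areas (ATP area = `scale`, PME split 45:55 over PC:PE, PDE split evenly
#' over GPC:GPE), pH becomes the Pi chemical shift via [pi_shift_from_ph()],
#' and Mg2+ becomes the beta-ATP centre shift via [beta_shift_from_mg()].
#' Running [fit_spectrum()] + [quantify_fit()] on a noiseless FID built from
#' the result returns the input metrics. Metric vectors whose derived
#' ratios contradict the primaries (beyond 1e-6 relative) are rejected.
#'
#' @param metrics A one-row data frame (or named list) with the twelve
#'   metric entries.
#' @param config A [cohort_config()] supplying basis, calibrations and
#'   nuisance amplitudes.
#' @param scale Global amplitude scale (the ATP area, a.u.).
#' @param damping Named or scalar decay rate(s) (1/s) for the components.
#' @return A component tibble for [synthesize_fid()].
#' @export
metrics_to_components <- function(metrics, config = cohort_config(),
                                  scale = 1, damping = NULL) {
  m <- as.list(metrics)
  need <- .metric_names
  miss <- setdiff(need, names(m))
  if (length(miss)) abort(paste0("Missing metrics: ", paste(miss, collapse = ", ")))
  consistent <- function(derived, num, den) {
    abs(m[[derived]] - m[[num]] / m[[den]]) <= 1e-6 * abs(m[[derived]])
  }
  checks <- c(
    consistent("PCr_Pi", "PCr_ATP", "Pi_ATP"),
    consistent("PME_PDE", "PME_ATP", "PDE_ATP"),
    consistent("PME_Pi", "PME_ATP", "Pi_ATP"),
    consistent("PME_PCr", "PME_ATP", "PCr_ATP"),
    consistent("PDE_Pi", "PDE_ATP", "Pi_ATP"),
    consistent("PDE_PCr", "PDE_ATP", "PCr_ATP")
  )
  if (!all(checks)) {
    abort("Inconsistent ratio set: derived ratios contradict the ATP-normalised primaries.")
  }
  amps <- c(
    PC = 0.45 * m$PME_ATP, PE = 0.55 * m$PME_ATP,
    GPC = 0.5 * m$PDE_ATP, GPE = 0.5 * m$PDE_ATP,
    Pi = m$Pi_ATP, PCr = m$PCr_ATP,
    ATP_gamma = 1, ATP_alpha = 1, ATP_beta = 1,
    MM = config$mm_amplitude, NADH = config$nadh_amplitude
  ) * scale
  make_components(
    config$basis,
    amplitudes = amps,
    damping = damping %||% config$damping_mean,
    phase = 0,
    shift_overrides = c(
      Pi = pi_shift_from_ph(m$pH, config$ph_constants),
      ATP_beta = beta_shift_from_mg(m$Mg, config$mg_constants)
    )
  )
}

#' Noise level for a target spectral SNR
#'
#' Converts a target SNR (PCr spectral peak magnitude over spectral noise
#' SD) into the per-channel time-domain noise SD for [synthesize_fid()]:
#' the spectral noise SD of white complex time-domain noise of SD sigma is
#' sigma * sqrt(N) under the unnormalised DFT.
#'
#' @param components Component tibble of the noiseless signal.
#' @param acq Acquisition parameters.
#' @param snr Target SNR (> 0; `Inf` gives 0 noise).
#' @return Time-domain noise SD (a.u.).
#' @export
snr_to_noise_sd <- function(components, acq, snr) {
  if (!is.finite(snr)) return(0)
  clean <- synthesize_fid(components, acq)
  peak <- max(fid_spectrum(clean)$mag)
  (peak / snr) / sqrt(acq$n_points)
}

# Tissue fractions for one voxel; violators break the 2/3 desired-tissue
# rule or (in contrast-enhancing tissue) the 1/3 necrosis rule.
draw_tissue_fractions <- function(region, violate) {
  if (!violate) {
    desired <- runif(1, 0.70, 0.90)
    necrosis <- if (region == "contrast_enhancing") runif(1, 0, 0.08) else 0
  } else if (region == "contrast_enhancing" && runif(1) < 0.5) {
    # heavily necrotic tumor voxel: tissue rule passes, necrosis rule fails
    desired <- runif(1, 0.70, 0.85)
    necrosis <- runif(1, 0.35, 0.45)
  } else {
    desired <- runif(1, 0.40, 2 / 3)
    necrosis <- if (region == "contrast_enhancing") runif(1, 0, 0.08) else 0
  }
  csf <- runif(1, 0, max(0, min(0.02, 1 - desired)))
  tibble(frac_desired = desired, frac_necrosis = necrosis, frac_csf = csf)
}

#' Generate a synthetic MRSI cohort
#'
#' For every subject, region and voxel: draws truth metrics from the
#' regional truth table ([sample_region_metrics()]), encodes them as
#' spectral components ([metrics_to_components()]) with a log-normally
#' varying global amplitude (SD 20%) and per-entity dampings (SD 10% around
#' `damping_mean`), synthesises a noisy FID at the configured SNR, draws
#' tissue fractions such that about `qc_violation_rate` of voxels violate
#' the inclusion rules, and attaches the diffusion metrics. Truth values
#' are retained in `truth_*` columns for recovery testing.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @return A tibble (class `p31_cohort`) with one row per voxel: ids,
#'   region, tissue fractions, `truth_*` metric columns, `ADC`, `b1000`,
#'   `FA`, and a `fid` list-column of `p31_fid` objects.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "p31_cohort_config"))
  n_vox <- config$n_subjects * config$voxels_per_region
  if (n_vox == 0 || length(config$regions) == 0) {
    abort("Zero voxels requested.")
  }
  withr::local_seed(as.integer(seed))

  rows <- purrr::imap(setNames(config$regions, config$regions), function(region, nm) {
    k <- match(region, region_levels())
    metrics <- sample_region_metrics(config, region, n_vox,
                                     seed = as.integer(seed) + 1000L * k)
    met <- metrics[, .metric_names]
    dwi <- metrics[, c("ADC", "b1000", "FA")]
    scale <- exp(rnorm(n_vox, 0, 0.2))
    violate <- runif(n_vox) < config$qc_violation_rate

    vox <- purrr::map(seq_len(n_vox), function(i) {
      dampings <- config$damping_mean *
        exp(rnorm(length(unique(config$basis$metabolite)), 0, 0.1))
      names(dampings) <- unique(config$basis$metabolite)
      comps <- metrics_to_components(met[i, ], config,
                                     scale = scale[i], damping = dampings)
      sigma <- snr_to_noise_sd(comps, config$acq, config$snr)
      fid <- synthesize_fid(comps, config$acq, noise_sd = sigma,
                            seed = as.integer(seed) + 1000L * k + i)
      fr <- draw_tissue_fractions(region, violate[i])
      dplyr::bind_cols(
        tibble(
          subject_id = sprintf("S%02d", ((i - 1) %/% config$voxels_per_region) + 1),
          voxel_id = sprintf("%s_%03d", region, i),
          region = region
        ),
        fr,
        setNames(met[i, ], paste0("truth_", names(met))),
        tibble(truth_scale = scale[i]),
        dwi[i, ],
        tibble(fid = list(fid))
      )
    })
    bind_rows(vox)
  })
  out <- bind_rows(rows)
  class(out) <- c("p31_cohort", class(out))
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write cohort FIDs to a directory
#'
#' @param cohort A `p31_cohort`.
#' @param dir Output directory; one CSV + JSON sidecar per voxel, named by
#'   `voxel_id`.
#' @return `dir`, invisibly.
#' @export
write_cohort_fids <- function(cohort, dir) {
  stopifnot(inherits(cohort, "p31_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  purrr::walk2(cohort$fid, cohort$voxel_id, function(f, id) {
    write_fid(f, file.path(dir, paste0(id, ".csv")))
  })
  invisible(dir)
}
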