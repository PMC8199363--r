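#' Fit and quantify every voxel of a cohort
#'
#' Runs [fit_spectrum()] and [quantify_fit()] on each FID of a cohort table
#' and binds the twelve metric estimates plus fit diagnostics to the voxel
#' rows.
#'
#' @param cohort A `p31_cohort` from [generate_cohort()] (or any tibble
#'   with a `fid` list-column).
#' @param basis,prior Basis and prior knowledge for the fits; default to
#'   the cohort config's basis and its standard prior.
#' @param ph_constants,mg_constants Calibrations for the pH and Mg2+
#'   read-out.
#' @param thresholds Spectrum-quality thresholds, see [qc_thresholds()].
#' @return The cohort tibble with metric columns, `relative_residual`,
#'   `converged`, `spectrum_ok` and `spectrum_reason` added.
#' @export
fit_cohort <- function(cohort,
                       basis = NULL,
                       prior = NULL,
                       ph_constants = ph_cal(),
                       mg_constants = mg_cal(),
                       thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(cohort), "fid" %in% names(cohort))
  config <- attr(cohort, "config")
  basis <- basis %||% (if (!is.null(config)) config$basis else build_basis())
  prior <- prior %||% fit_prior(basis)
  if (is.null(ph_constants) || is.null(mg_constants)) {
    abort("quantify stage: pH and Mg calibration constants are required.")
  }
  res <- purrr::map(cohort$fid, function(f) {
    fit <- fit_spectrum(f, basis, prior)
    qf <- quality_flag(fit, thresholds)
    metrics <- suppressWarnings(quantify_fit(fit, ph_constants, mg_constants))
    dplyr::bind_cols(
      metrics,
      tibble(
        relative_residual = fit$relative_residual,
        residual_ratio = fit$residual_ratio,
        converged = fit$converged,
        spectrum_ok = qf$accept,
        spectrum_reason = if (qf$accept) "ok" else paste(qf$reasons, collapse = ";")
      )
    )
  }) %>% bind_rows()
  out <- dplyr::bind_cols(as_tibble(cohort), res)
  class(out) <- class(cohort)
  for (a in c("config", "seed")) attr(out, a) <- attr(cohort, a)
  out
}

#' Per-region, per-metric ROUT screen
#'
#' Applies [rout_outliers()] to every metric sample within every region and
#' masks flagged values to `NA`, mirroring a statistics workflow in which
#' outliers are removed from each analysed sample before testing.
#'
#' @param cohort A quantified cohort table (metric columns present).
#' @param metrics Metric columns to screen.
#' @param q ROUT FDR rate in percent.
#' @return The tibble with flagged values set to `NA` and a logical
#'   `any_outlier` column marking rows that lost at least one value.
#' @export
screen_outliers <- function(cohort, metrics = .metric_names, q = 1) {
  stopifnot(is.data.frame(cohort), "region" %in% names(cohort))
  metrics <- intersect(metrics, names(cohort))
  out <- cohort %>%
    group_by(.data$region) %>%
    mutate(across(all_of(metrics), function(v) {
      ok <- !is.na(v)
      if (sum(ok) >= 3) {
        keep <- rout_outliers(v[ok], q = q)
        v[ok][!keep] <- NA_real_
      }
      v
    })) %>%
    ungroup()
  before <- as.matrix(cohort[metrics])
  after <- as.matrix(out[metrics])
  out$any_outlier <- rowSums(is.na(after) & !is.na(before)) > 0
  class(out) <- class(cohort)
  for (a in c("config", "seed")) attr(out, a) <- attr(cohort, a)
  out
}

#' Spearman correlations of a cohort per the correlation specification
#'
#' @param cohort Quantified, QC-passed cohort table.
#' @param spec A [correlation_spec()]-style tibble (`region`, `dwi_metric`,
#'   `mrs_metric`).
#' @return A tibble of [spearman_cor()] rows, one per spec entry with at
#'   least 4 complete pairs, with the target `rho_target` attached.
#' @export
cohort_correlations <- function(cohort, spec = correlation_spec()) {
  purrr::map(seq_len(nrow(spec)), function(j) {
    s <- spec[j, ]
    sub <- cohort %>% filter(.data$region == s$region)
    x <- sub[[s$dwi_metric]]
    y <- sub[[s$mrs_metric]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 4) return(NULL)
    spearman_cor(x[ok], y[ok],
                 variable_pair = c(s$dwi_metric, s$mrs_metric),
                 region = s$region) %>%
      mutate(rho_target = s$rho %||% NA_real_)
  }) %>% bind_rows()
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' One reproducible end-to-end run: generate (or accept) a cohort, fit and
#' quantify every voxel, apply the voxel inclusion rules and the spectrum
#' quality screen, remove outliers with ROUT, and produce the regional
#' descriptive table, Kruskal--Wallis + Dunn group comparisons per metric,
#' and the Spearman correlation table. A manifest records the seed, the
#' package version, the main configuration values and (when `out_dir` is
#' given) an MD5 content hash per written file; rerunning with the same
#' seed and configuration reproduces the metric tables bit-identically.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the whole run.
#' @param cohort Optionally, a pre-generated `p31_cohort` (then `seed` only
#'   labels the manifest).
#' @param rout_q ROUT FDR rate in percent.
#' @param out_dir Optional directory; writes `cohort.csv`,
#'   `regional_table.csv`, `comparisons.json`, `correlations.csv`,
#'   `manifest.json`.
#' @return A `p31_run` list: `cohort` (all voxels, quantified), `analysis`
#'   (included voxels after QC + outlier screen), `exclusions`, `regional`
#'   (long table), `comparisons` (list of `p31_group_comparison`),
#'   `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, cohort = NULL,
                         rout_q = 1, out_dir = NULL) {
  stopifnot(inherits(config, "p31_cohort_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config, seed = seed)
  quantified <- fit_cohort(cohort,
                           basis = config$basis,
                           ph_constants = config$ph_constants,
                           mg_constants = config$mg_constants)
  quantified <- apply_inclusion_rules(quantified)
  excl <- exclusion_summary(quantified)
  analysis <- quantified %>% filter(.data$included, .data$spectrum_ok)
  analysis <- screen_outliers(analysis, q = rout_q)

  regional <- regional_table(analysis)
  metrics_present <- intersect(.metric_names, names(analysis))
  comparisons <- purrr::map(
    setNames(metrics_present, metrics_present),
    function(m) {
      dat <- analysis %>% filter(!is.na(.data[[m]]))
      if (length(unique(dat$region)) < 2) return(NULL)
      kruskal_dunn(dat, m, "region")
    }
  )
  comparisons <- comparisons[!vapply(comparisons, is.null, logical(1))]
  correlations <- cohort_correlations(analysis, config$correlations)

  manifest <- list(
    package = "phosfit",
    version = as.character(utils::packageVersion("phosfit")),
    seed = as.integer(seed),
    n_subjects = config$n_subjects,
    voxels_per_region = config$voxels_per_region,
    regions = config$regions,
    snr = config$snr,
    qc_violation_rate = config$qc_violation_rate,
    rout_q = rout_q,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  run <- structure(
    list(cohort = quantified, analysis = analysis, exclusions = excl,
         regional = regional, comparisons = comparisons,
         correlations = correlations, manifest = manifest),
    class = "p31_run"
  )
  if (!is.null(out_dir)) run <- write_run(run, out_dir)
  run
}

#' @export
print.p31_run <- function(x, ...) {
  cat(sprintf(
    "<p31_run> %d voxels (%d analysed), %d regions, seed %d\n",
    nrow(x$cohort), nrow(x$analysis),
    length(unique(x$cohort$region)), x$manifest$seed
  ))
  invisible(x)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  drop_fid <- function(d) d[setdiff(names(d), "fid")]
  paths <- c(
    cohort = file.path(out_dir, "cohort.csv"),
    regional = file.path(out_dir, "regional_table.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    comparisons = file.path(out_dir, "comparisons.json")
  )
  utils::write.csv(drop_fid(run$cohort), paths["cohort"], row.names = FALSE)
  utils::write.csv(run$regional, paths["regional"], row.names = FALSE)
  utils::write.csv(run$correlations, paths["correlations"], row.names = FALSE)
  comp <- purrr::map(run$comparisons, function(cmp) {
    list(H = cmp$H, df = cmp$df, p_value = cmp$p_value,
         pairwise = cmp$pairwise)
  })
  jsonlite::write_json(comp, paths["comparisons"], auto_unbox = TRUE,
                       digits = NA)
  run$manifest$files <- purrr::imap(
    setNames(as.list(paths), names(paths)),
    function(p, nm) list(path = basename(p), md5 = unname(tools::md5sum(p)))
  )
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  run
}
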