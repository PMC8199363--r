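test_that("region metric draws match the configured marginals", {
  config <- cohort_config()
  met <- sample_region_metrics(config, "contrast_enhancing", 1e4, seed = 21)
  se <- 0.24 / sqrt(1e4)
  expect_lt(abs(mean(met$PCr_ATP) - 1.24), 2 * se)
  expect_lt(abs(sd(met$PCr_ATP) - 0.24), 0.01)
  expect_true(all(met$Pi_ATP > 0))

  # degenerate SDs collapse onto the mean
  tiny <- cohort_config(truth = dplyr::mutate(region_truth(), sd = 1e-9))
  met0 <- sample_region_metrics(tiny, "contralateral", 50, seed = 3)
  expect_equal(met0$PDE_ATP, rep(0.57, 50), tolerance = 1e-6)

  expect_identical(
    sample_region_metrics(config, "adjacent", 100, seed = 9),
    sample_region_metrics(config, "adjacent", 100, seed = 9)
  )
  expect_error(sample_region_metrics(config, "nowhere", 10), "Unknown region")
})

test_that("derived ratios are consistent with the primary draws", {
  config <- cohort_config()
  met <- sample_region_metrics(config, "t2_hyperintense", 500, seed = 4)
  expect_equal(met$PCr_Pi, met$PCr_ATP / met$Pi_ATP)
  expect_equal(met$PME_PDE, met$PME_ATP / met$PDE_ATP)
  expect_equal(met$PDE_PCr, met$PDE_ATP / met$PCr_ATP)
})

test_that("the Gaussian copula reproduces every configured rank correlation", {
  config <- cohort_config()
  spec <- correlation_spec()
  for (reg in unique(spec$region)) {
    met <- sample_region_metrics(config, reg, 2000, seed = 11)
    sub <- spec[spec$region == reg, ]
    for (j in seq_len(nrow(sub))) {
      rho_hat <- spearman_cor(met[[sub$dwi_metric[j]]],
                              met[[sub$mrs_metric[j]]])$rho
      expect_lt(abs(rho_hat - sub$rho[j]), 0.05)
    }
  }
})

test_that("metric vectors roundtrip through encoding, fitting and quantification", {
  config <- cohort_config()
  met <- sample_region_metrics(config, "contrast_enhancing", 1, seed = 13)
  comps <- metrics_to_components(met[1, ], config, scale = 1.7)
  expect_identical(nrow(comps), 15L)

  fid <- synthesize_fid(comps, config$acq)
  fit <- fit_spectrum(fid, config$basis)
  q <- quantify_fit(fit, config$ph_constants, config$mg_constants)
  rel <- abs(unlist(q) / unlist(met[1, phosfit:::.metric_names]) - 1)
  expect_true(all(rel < 0.005))

  # pH and Mg2+ encode exactly through the inverse calibrations
  expect_equal(ph_from_pi_shift(comps$shift_ppm[comps$metabolite == "Pi"][1]),
               met$pH[1], tolerance = 1e-10)
  beta_center <- sort(comps$shift_ppm[comps$metabolite == "ATP_beta"])[2]
  expect_equal(mg_from_beta_shift(beta_center), met$Mg[1], tolerance = 1e-10)
})

test_that("inconsistent ratio sets are rejected", {
  config <- cohort_config()
  met <- sample_region_metrics(config, "adjacent", 1, seed = 2)
  met$PCr_Pi <- met$PCr_Pi * 1.5
  expect_error(metrics_to_components(met[1, ], config), "Inconsistent ratio")
  expect_error(metrics_to_components(met[1, -1], config), "Missing metrics")
})

test_that("generated cohorts are reproducible and carry structure and truth", {
  config <- small_config(regions = region_levels(), n_subjects = 2)
  cohort <- generate_cohort(config, seed = 17)
  expect_identical(nrow(cohort), 2L * 2L * 6L)
  expect_setequal(unique(cohort$region), region_levels())
  expect_true(all(paste0("truth_", phosfit:::.metric_names) %in% names(cohort)))
  expect_s3_class(cohort$fid[[1]], "p31_fid")

  again <- generate_cohort(config, seed = 17)
  expect_identical(cohort$truth_PCr_ATP, again$truth_PCr_ATP)
  expect_identical(cohort$fid[[5]]$samples, again$fid[[5]]$samples)
  other <- generate_cohort(config, seed = 18)
  expect_false(identical(cohort$truth_PCr_ATP, other$truth_PCr_ATP))
})

test_that("the QC-violation rate is honoured on average", {
  config <- cohort_config(n_subjects = 10, voxels_per_region = 3,
                          regions = c("contrast_enhancing", "adjacent"),
                          snr = Inf, qc_violation_rate = 0.2)
  cohort <- generate_cohort(config, seed = 23)
  flagged <- apply_inclusion_rules(cohort)
  frac <- exclusion_summary(flagged)$fraction_excluded
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.35)

  clean <- generate_cohort(
    cohort_config(n_subjects = 5, regions = "contralateral",
                  qc_violation_rate = 0), seed = 2
  )
  expect_equal(exclusion_summary(apply_inclusion_rules(clean))$fraction_excluded, 0)
})

test_that("quantification error shrinks as SNR grows", {
  err_at <- function(snr) {
    config <- cohort_config(n_subjects = 4, voxels_per_region = 2,
                            regions = "contralateral", snr = snr)
    cohort <- generate_cohort(config, seed = 37)
    fitted <- fit_cohort(cohort)
    median(abs(fitted$PCr_ATP - fitted$truth_PCr_ATP), na.rm = TRUE)
  }
  ladder <- vapply(c(10, 40, Inf), err_at, numeric(1))
  expect_true(all(diff(ladder) < 0))
  expect_lt(ladder[3], 1e-4)
})

test_that("cohort FIDs can be written out as text containers", {
  config <- small_config(regions = "contralateral", n_subjects = 1, snr = 25)
  cohort <- generate_cohort(config, seed = 41)
  dir <- withr::local_tempdir()
  write_cohort_fids(cohort, dir)
  files <- list.files(dir, pattern = "\\.csv$")
  expect_length(files, nrow(cohort))
  back <- read_fid(file.path(dir, paste0(cohort$voxel_id[1], ".csv")))
  expect_equal(back$samples, cohort$fid[[1]]$samples, tolerance = 1e-12)
})
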