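test_that("starting values are read off the magnitude spectrum", {
  acq <- acq_params()
  basis <- build_basis(acq)
  fid <- synthesize_fid(make_components(basis, c(PCr = 2.5)), acq)
  est <- initial_estimates(fid, basis)
  pcr0 <- est$amplitude0[est$metabolite == "PCr"]
  expect_lt(abs(pcr0 / 2.5 - 1), 0.2)

  zero <- synthesize_fid(make_components(basis, c(PCr = 1)), acq)
  zero$samples[] <- 0 + 0i
  est0 <- initial_estimates(zero, basis)
  expect_true(all(est0$amplitude0 == 0))
  expect_identical(est0$phase0[1], 0)

  expect_identical(initial_estimates(fid, basis), initial_estimates(fid, basis))
})

test_that("noiseless 15-component spectra are recovered essentially exactly", {
  acq <- acq_params()
  basis <- build_basis(acq)
  comps <- make_components(basis, example_amplitudes,
                           damping = 22, phase = 0.2,
                           shift_overrides = c(Pi = 4.93, ATP_beta = -16.7))
  fid <- synthesize_fid(comps, acq)
  fit <- fit_spectrum(fid, basis)
  expect_true(fit$converged)
  expect_true(all(abs(fit$recovery$rel_error) < 1e-3))
  expect_lt(abs(fit$estimates$shift_ppm[fit$estimates$metabolite == "Pi"] - 4.93),
            1e-4)
  # shift estimates stay inside their windows
  prior <- fit_prior(basis)
  ent <- fit$estimates
  ctr <- basis[!duplicated(basis$metabolite), ]
  for (m in ent$metabolite) {
    dev <- abs(ent$shift_ppm[ent$metabolite == m] -
                 ctr$center_ppm[ctr$metabolite == m])
    expect_lte(dev, prior$shift_window[[m]] + 1e-9)
  }
})

test_that("multiplet lines share damping and phase by construction", {
  acq <- acq_params()
  basis <- build_basis(acq)
  fid <- synthesize_fid(make_components(basis, example_amplitudes), acq,
                        noise_sd = 0.2, seed = 5)
  fit <- fit_spectrum(fid, basis)
  lines <- fitted_fid(fit)$truth
  beta <- lines[grepl("^ATP_beta", lines$component), ]
  expect_identical(length(unique(beta$damping)), 1L)
  expect_identical(length(unique(beta$phase)), 1L)
  expect_equal(diff(sort(beta$shift_ppm)),
               rep(16.3 / acq$spectrometer_freq, 2))
})

test_that("fitter agrees with a dense grid-search oracle on sparse signals", {
  acq <- acq_params(n_points = 128)
  shifts <- default_shift_table()
  cases <- list(
    list(amp = c(PCr = 1.5), centers = 0),
    list(amp = c(PCr = 1.2, Pi = 0.6), centers = c(0, 4.82)),
    list(amp = c(PCr = 1.2, Pi = 0.6, GPE = 0.4), centers = c(0, 4.82, 3.50))
  )
  basis <- build_basis(acq, shifts)
  for (cs in cases) {
    comps <- make_components(basis, cs$amp, damping = 20)
    fid <- synthesize_fid(comps, acq)
    oracle <- grid_fit_oracle(
      fid, cs$centers,
      shift_step = if (length(cs$amp) < 3) 0.05 else 0.075,
      damp_grid = seq(12.5, 27.5, by = if (length(cs$amp) < 3) 2.5 else 7.5)
    )
    fit <- fit_spectrum(fid, basis)
    est <- fit$estimates[match(names(cs$amp), fit$estimates$metabolite), ]
    # the optimizer must do at least as well as the best grid node
    expect_equal(unname(est$amplitude), unname(oracle$amplitude),
                 tolerance = 0.05)
    expect_true(all(abs(est$shift_ppm - oracle$shift) <= 0.075 + 1e-9))
    expect_true(all(abs(est$damping - oracle$damp) <= 7.5 + 1e-9))
    expect_lte(fit$residual_norm^2, oracle$rss + 1e-9)
  }
})

test_that("fitted amplitudes are scale-equivariant and ratios scale-invariant", {
  acq <- acq_params()
  basis <- build_basis(acq)
  comps <- make_components(basis, example_amplitudes)
  fid <- synthesize_fid(comps, acq, noise_sd = 0.3, seed = 8)
  fit1 <- fit_spectrum(fid, basis)
  fid_c <- fid
  fid_c$samples <- 7.5 * fid$samples
  fit2 <- fit_spectrum(fid_c, basis)
  expect_equal(fit2$estimates$amplitude, 7.5 * fit1$estimates$amplitude,
               tolerance = 1e-6)
  expect_equal(compute_ratios(fit2), compute_ratios(fit1), tolerance = 1e-6)
})

test_that("amplitude error grows with the noise level", {
  acq <- acq_params(n_points = 512)
  basis <- build_basis(acq)
  comps <- make_components(basis, example_amplitudes)
  err_at <- function(noise_sd) {
    errs <- vapply(1:12, function(i) {
      fid <- synthesize_fid(comps, acq, noise_sd = noise_sd, seed = 400 + i)
      fit <- fit_spectrum(fid, basis)
      median(abs(fit$recovery$error))
    }, numeric(1))
    median(errs)
  }
  ladder <- vapply(c(0.05, 0.1, 0.2), err_at, numeric(1))
  expect_true(all(diff(ladder) >= 0))
})

test_that("amplitude recovery is nearly unbiased at SNR 20", {
  acq <- acq_params()
  basis <- build_basis(acq)
  comps <- make_components(basis, example_amplitudes)
  sigma <- snr_to_noise_sd(comps, acq, 20)
  pcr <- vapply(1:100, function(i) {
    fid <- synthesize_fid(comps, acq, noise_sd = sigma, seed = 2000 + i)
    fit <- fit_spectrum(fid, basis)
    fit$estimates$amplitude[fit$estimates$metabolite == "PCr"]
  }, numeric(1))
  expect_lt(abs(mean(pcr) / 1.24 - 1), 0.02)
})

test_that("quality screen accepts clean fits and names failure reasons", {
  acq <- acq_params()
  basis <- build_basis(acq)
  comps <- make_components(basis, example_amplitudes)
  fid <- synthesize_fid(comps, acq)
  good <- fit_spectrum(fid, basis)
  expect_true(quality_flag(good)$accept)

  # starved optimizer: not converged
  stunted <- fit_spectrum(
    synthesize_fid(comps, acq, noise_sd = 0.5, seed = 1), basis,
    control = minpack.lm::nls.lm.control(ftol = 1e-24, ptol = 1e-24,
                                         gtol = 0, maxiter = 2)
  )
  qf <- quality_flag(stunted)
  expect_false(qf$accept)
  expect_true("no_convergence" %in% qf$reasons)

  # signal with a strong resonance missing from the basis: residual flagged
  rogue <- dplyr::bind_rows(
    comps,
    tibble::tibble(component = "rogue", metabolite = "rogue",
                   shift_ppm = 1.1, damping = 20, amplitude = 2,
                   phase = 0, relative_weight = 1)
  )
  fid_bad <- synthesize_fid(rogue, acq, noise_sd = 0.02, seed = 2)
  bad <- fit_spectrum(fid_bad, basis)
  expect_true("residual" %in% quality_flag(bad)$reasons)
})

test_that("degenerate bases are rejected before optimization", {
  acq <- acq_params()
  shifts <- default_shift_table()
  shifts$shift_ppm[shifts$metabolite == "PC"] <-
    shifts$shift_ppm[shifts$metabolite == "PE"]
  basis <- build_basis(acq, shifts)
  fid <- synthesize_fid(make_components(basis, c(PCr = 1)), acq)
  expect_error(fit_spectrum(fid, basis), "Degenerate")
})

test_that("fit tidiers expose estimates and diagnostics", {
  acq <- acq_params(n_points = 256)
  basis <- build_basis(acq)
  fid <- synthesize_fid(make_components(basis, c(PCr = 1, Pi = 0.4)), acq)
  fit <- fit_spectrum(fid, basis)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 11L)
  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
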