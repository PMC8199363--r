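test_that("ppm/Hz conversion follows the field-frequency definition", {
  acq <- acq_params()
  expect_identical(ppm_to_hz(0, acq), 0)
  expect_equal(ppm_to_hz(1, acq), 49.9)
  expect_equal(ppm_to_hz(-8.3, acq), -414.17)
  expect_equal(hz_to_ppm(ppm_to_hz(3.21, acq), acq), 3.21)
  expect_error(ppm_to_hz(NaN, acq), "finite")
})

test_that("acquisition parameters are validated", {
  expect_error(acq_params(spectrometer_freq = 0), "positive")
  expect_error(acq_params(n_points = 32), ">= 64")
  expect_error(acq_params(dwell_time = -1), "positive")
  # a sweep too narrow for the phosphorus shift range is refused
  expect_error(acq_params(dwell_time = 1e-3), "does not cover")
})

test_that("default basis has the 15-component structure with priors", {
  basis <- build_basis()
  expect_s3_class(basis, "p31_basis")
  expect_identical(nrow(basis), 15L)

  ent <- basis[!duplicated(basis$metabolite), ]
  pcr <- ent[ent$metabolite == "PCr", ]
  expect_identical(pcr$center_ppm, 0)
  expect_true(pcr$fixed)
  mm <- ent[ent$metabolite == "MM", ]
  expect_identical(mm$center_ppm, 2.2)
  expect_true(mm$fixed)
  nadh <- ent[ent$metabolite == "NADH", ]
  expect_identical(nadh$center_ppm, -8.3)
  expect_true(nadh$fixed)

  groups <- attr(basis, "groups")
  expect_length(groups$PME, 2)
  expect_length(groups$PDE, 2)
  expect_identical(
    sum(basis$metabolite %in% groups$ATP), 7L
  )
})

test_that("ATP multiplets are symmetric with J-spacing and 1:1 / 1:2:1 weights", {
  acq <- acq_params()
  j <- 16.3
  basis <- build_basis(acq, j_coupling = j)
  for (m in c("ATP_gamma", "ATP_alpha")) {
    d <- basis[basis$metabolite == m, ]
    expect_equal(sort(d$offset_hz), c(-j / 2, j / 2))
    expect_equal(d$relative_weight, c(0.5, 0.5))
    expect_equal(diff(sort(d$shift_ppm)), j / acq$spectrometer_freq)
  }
  tr <- basis[basis$metabolite == "ATP_beta", ]
  expect_equal(sort(tr$offset_hz), c(-j, 0, j))
  expect_equal(sum(tr$relative_weight), 1)
  expect_equal(tr$relative_weight[order(tr$offset_hz)], c(1, 2, 1) / 4)
})

test_that("basis construction rejects bad shift tables", {
  shifts <- default_shift_table()
  expect_error(build_basis(shifts = shifts[-1, ]), "missing")
  expect_error(build_basis(shifts = rbind(shifts, shifts[1, ])), "Duplicate")
  expect_error(build_basis(j_coupling = -1), "positive")
})

test_that("synthesized FID matches the model at t = 0 and is linear", {
  acq <- acq_params(n_points = 256)
  basis <- build_basis(acq)
  one <- make_components(basis, c(PCr = 1))
  fid1 <- synthesize_fid(one, acq)
  expect_equal(fid1$samples[1], 1 + 0i)

  comps <- make_components(basis, example_amplitudes, phase = 0.3)
  fid <- synthesize_fid(comps, acq)
  expect_equal(
    fid$samples[1],
    sum(comps$amplitude * comps$relative_weight *
          exp(complex(imaginary = comps$phase)))
  )

  # linearity and amplitude scaling at zero noise
  a <- make_components(basis, c(PCr = 1.1, Pi = 0.4))
  b <- make_components(basis, c(ATP_beta = 0.8, PE = 0.3))
  ab <- dplyr::bind_rows(a[a$amplitude > 0, ], b[b$amplitude > 0, ])
  expect_equal(
    synthesize_fid(ab, acq)$samples,
    synthesize_fid(a, acq)$samples + synthesize_fid(b, acq)$samples
  )
  a3 <- dplyr::mutate(a, amplitude = 3 * amplitude)
  expect_equal(synthesize_fid(a3, acq)$samples, 3 * synthesize_fid(a, acq)$samples)
})

test_that("spectral peaks appear at the component shifts", {
  acq <- acq_params()
  basis <- build_basis(acq)
  comps <- make_components(basis, c(PCr = 1, PE = 0.8, NADH = 0.6),
                           damping = 8)
  sp <- fid_spectrum(synthesize_fid(comps, acq))
  bin <- 1 / (acq$n_points * acq$dwell_time) / acq$spectrometer_freq
  for (shift in c(0, 6.78, -8.3)) {
    local_peak <- sp$ppm[abs(sp$ppm - shift) < 0.5][
      which.max(sp$mag[abs(sp$ppm - shift) < 0.5])
    ]
    expect_lt(abs(local_peak - shift), bin)
  }
})

test_that("synthesis noise is seeded and reproducible", {
  acq <- acq_params(n_points = 128)
  basis <- build_basis(acq)
  comps <- make_components(basis, c(PCr = 1))
  f1 <- synthesize_fid(comps, acq, noise_sd = 0.1, seed = 99)
  f2 <- synthesize_fid(comps, acq, noise_sd = 0.1, seed = 99)
  f3 <- synthesize_fid(comps, acq, noise_sd = 0.1, seed = 100)
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(f1$samples, f3$samples))
  expect_error(synthesize_fid(comps, acq, noise_sd = -1), ">= 0")
  expect_error(synthesize_fid(comps[0, ], acq), "non-empty")
})

test_that("each ATP multiplet integrates to the same local spectral area", {
  acq <- acq_params()
  basis <- build_basis(acq)
  local_area <- function(entity, center) {
    amp <- setNames(1, entity)
    sp <- fid_spectrum(synthesize_fid(make_components(basis, amp), acq))
    sum(sp$real[abs(sp$ppm - center) < 1.5])
  }
  a_gamma <- local_area("ATP_gamma", -2.48)
  a_beta <- local_area("ATP_beta", -16.75)
  expect_equal(a_beta / a_gamma, 1, tolerance = 0.02)
})

test_that("FID containers roundtrip through CSV + JSON sidecar", {
  acq <- acq_params(n_points = 128)
  basis <- build_basis(acq)
  comps <- make_components(basis, c(PCr = 1.24, Pi = 0.41))
  fid <- synthesize_fid(comps, acq, noise_sd = 0.05, seed = 3)
  path <- file.path(withr::local_tempdir(), "voxel.csv")
  write_fid(fid, path)
  back <- read_fid(path)
  expect_equal(back$samples, fid$samples, tolerance = 1e-12)
  expect_equal(back$acq$spectrometer_freq, acq$spectrometer_freq)
  expect_equal(back$truth$amplitude, fid$truth$amplitude)
  expect_error(read_fid(file.path(tempdir(), "nope.csv")), "sidecar")
})
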