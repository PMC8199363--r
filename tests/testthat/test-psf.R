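test_that("geometry derives nominal voxel and interpolated grid spacing", {
  g <- csi_geometry()
  expect_equal(g$nominal_voxel, c(30, 30, 25))
  expect_equal(g$grid_spacing, c(15, 15, 25))
  expect_error(csi_geometry(recon_matrix = c(4, 4, 4)), ">=")
  expect_error(csi_geometry(fov = c(-1, 240, 200)), "positive")
})

test_that("apodization weights are normalised, symmetric and configurable", {
  w <- hamming_weights(8)
  expect_equal(w$weight[w$k == 0], 1)
  for (k in 1:3) {
    expect_equal(w$weight[w$k == k], w$weight[w$k == -k])
  }
  expect_true(all(hamming_weights(8, "none")$weight == 1))
  expect_error(hamming_weights(1), ">= 2")
  expect_error(hamming_weights(8, "boxcar"), "must be one of")
})

test_that("the unapodized 1D response is the closed-form Dirichlet kernel", {
  geom <- csi_geometry(apodization = "none")
  psf <- compute_psf(geom, oversample = 16)
  pr <- psf$profiles[[1]]
  u <- pr$x_mm / geom$nominal_voxel[1]
  expect_equal(Mod(pr$response), dirichlet_mag(u, 8), tolerance = 1e-10)
})

test_that("rect FWHM matches the Dirichlet closed form in both conventions", {
  geom <- csi_geometry(apodization = "none")
  pr <- compute_psf(geom, oversample = 64)$profiles[[1]]
  u <- pr$x_mm / geom$nominal_voxel[1]
  mag <- Mod(pr$response)
  grid_tol <- 2 * (u[2] - u[1])

  fwhm_mag <- oracle_fwhm(function(v) dirichlet_mag(v, 8))
  expect_equal(phosfit:::profile_fwhm(u, mag), fwhm_mag, tolerance = grid_tol)
  expect_equal(fwhm_mag, 1.21, tolerance = 0.01)

  # the squared-magnitude (power) profile has the familiar 0.886 width
  fwhm_pow <- oracle_fwhm(function(v) dirichlet_mag(v, 8)^2)
  expect_equal(phosfit:::profile_fwhm(u, mag^2), fwhm_pow, tolerance = grid_tol)
  expect_equal(fwhm_pow, 0.886, tolerance = 0.01)
})

test_that("the 3D response is separable: matches a direct 3D DFT", {
  geom <- csi_geometry(acq_matrix = c(4, 4, 4), fov = c(80, 80, 80),
                       recon_matrix = c(4, 4, 4))
  psf <- compute_psf(geom, oversample = 4)
  w <- hamming_weights(4)
  npad <- 16
  arr <- array(0 + 0i, dim = c(npad, npad, npad))
  idx <- (w$k %% npad) + 1
  for (i in seq_along(idx)) for (j in seq_along(idx)) for (k in seq_along(idx)) {
    arr[idx[i], idx[j], idx[k]] <- w$weight[i] * w$weight[j] * w$weight[k]
  }
  direct <- fft(arr)
  direct <- direct / max(Mod(direct))
  # sort the direct 3D result onto the same centred spatial ordering
  xi <- seq_len(npad) - 1
  x <- ifelse(xi > npad / 2, xi - npad, xi)
  ord <- order(x)
  direct_sorted <- Mod(direct)[ord, ord, ord]
  m1 <- Mod(psf$profiles[[1]]$response)
  sep <- outer(outer(m1, m1), m1)
  expect_equal(sep, direct_sorted, tolerance = 1e-12)
})

test_that("Parseval holds for the windowed k-space energy", {
  for (win in c("none", "hamming")) {
    geom <- csi_geometry(apodization = win)
    psf <- compute_psf(geom, oversample = 8)
    w <- hamming_weights(8, win)$weight
    npad <- 16 * 8
    expect_equal(
      sum(Mod(psf$profiles[[1]]$response)^2),
      npad * sum(w^2) / sum(w)^2,
      tolerance = 1e-10
    )
  }
})

test_that("Hamming trades a wider main lobe for suppressed side lobes", {
  rect <- compute_psf(csi_geometry(apodization = "none"), oversample = 32)
  hamm <- compute_psf(csi_geometry(apodization = "hamming"), oversample = 32)
  fr <- psf_metrics(rect)
  fh <- psf_metrics(hamm)
  expect_gt(fh$fwhm_mm[[1]][1], fr$fwhm_mm[[1]][1])

  sidelobe_max <- function(psf) {
    pr <- psf$profiles[[1]]
    u <- abs(pr$x_mm) / psf$geometry$nominal_voxel[1]
    max(Mod(pr$response)[u > 1.5])
  }
  expect_lt(sidelobe_max(hamm), sidelobe_max(rect))
  # far-field leakage beyond the first Dirichlet zero is smaller with Hamming
  expect_lt(bleed_fraction(hamm, radius_vox = 1),
            bleed_fraction(rect, radius_vox = 1))
})

test_that("bleed fraction is a proper fraction that vanishes with distance", {
  psf <- compute_psf(csi_geometry(), oversample = 16)
  for (g in list(csi_geometry(), csi_geometry(apodization = "none"),
                 csi_geometry(acq_matrix = c(12, 12, 8),
                              recon_matrix = c(24, 24, 8)))) {
    b <- bleed_fraction(compute_psf(g, oversample = 16))
    expect_gte(b, 0)
    expect_lt(b, 1)
  }
  radii <- c(0.5, 1, 2, 4)
  bl <- vapply(radii, function(r) bleed_fraction(psf, radius_vox = r),
               numeric(1))
  expect_true(all(diff(bl) < 0))
  expect_lt(bl[length(bl)], 0.02)
})

test_that("effective-voxel increase orders by apodization strength", {
  inc <- vapply(c("none", "hamming", "hann"), function(win) {
    effective_voxel_increase(
      compute_psf(csi_geometry(apodization = win), oversample = 16)
    )
  }, numeric(1))
  # hann has the widest main lobe, rect the narrowest
  expect_true(inc[["none"]] < inc[["hamming"]])
  expect_true(inc[["hamming"]] < inc[["hann"]])
  expect_lt(inc[["none"]], 20)
})

test_that("relative PSF metrics are invariant to FOV rescaling", {
  a <- psf_metrics(compute_psf(csi_geometry(), oversample = 16))
  b <- psf_metrics(compute_psf(csi_geometry(fov = 2 * c(240, 240, 200)),
                               oversample = 16))
  expect_equal(a$effective_increase_pct, b$effective_increase_pct,
               tolerance = 1e-9)
  expect_equal(a$equivalent_increase_pct, b$equivalent_increase_pct,
               tolerance = 1e-9)
  expect_error(compute_psf(csi_geometry(), oversample = 2), ">= 4")
})
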