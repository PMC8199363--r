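# Independent oracles used across the test files.

# Dense grid-search fit for a few well-separated singlet components:
# at every node of a (shift x damping) grid per component, the complex
# amplitudes are solved by linear least squares and the best node wins.
# Deliberately brute force and independent of the package's optimizer.
grid_fit_oracle <- function(fid, centers_ppm, shift_halfwidth = 0.15,
                            shift_step = 0.05, damp_grid = seq(10, 35, by = 2.5)) {
  acq <- fid$acq
  t <- (seq_len(acq$n_points) - 1) * acq$dwell_time
  y <- fid$samples
  K <- length(centers_ppm)
  shift_grids <- lapply(centers_ppm, function(c0) {
    seq(c0 - shift_halfwidth, c0 + shift_halfwidth, by = shift_step)
  })
  node_grids <- lapply(seq_len(K), function(k) {
    expand.grid(shift = shift_grids[[k]], damp = damp_grid)
  })
  combos <- expand.grid(lapply(node_grids, function(g) seq_len(nrow(g))))
  best <- list(rss = Inf)
  for (r in seq_len(nrow(combos))) {
    pars <- lapply(seq_len(K), function(k) node_grids[[k]][combos[r, k], ])
    A <- sapply(pars, function(p) {
      exp((-p$damp + 2i * pi * p$shift * acq$spectrometer_freq) * t)
    })
    A <- matrix(A, ncol = K)
    cc <- qr.solve(A, y)
    rss <- sum(Mod(y - A %*% cc)^2)
    if (rss < best$rss) {
      best <- list(
        rss = rss,
        shift = vapply(pars, function(p) p$shift, numeric(1)),
        damp = vapply(pars, function(p) p$damp, numeric(1)),
        amplitude = Mod(cc),
        phase = Arg(cc)
      )
    }
  }
  best
}

# Closed-form Dirichlet kernel magnitude of an n-point rectangular k-space
# sampling, in units of the nominal voxel.
dirichlet_mag <- function(u, n) {
  out <- abs(sin(pi * u) / (n * sin(pi * u / n)))
  out[abs(u %% n) < 1e-12] <- 1
  out
}

# FWHM of a closed-form 1D profile by root finding.
oracle_fwhm <- function(f, upper = 2) {
  r <- stats::uniroot(function(u) f(u) - 0.5, c(1e-9, upper), tol = 1e-12)$root
  2 * r
}

# A small, fast cohort configuration for pipeline-level tests.
small_config <- function(regions = c("contrast_enhancing", "contralateral"),
                         n_subjects = 3, snr = 30) {
  cohort_config(
    n_subjects = n_subjects,
    voxels_per_region = 2,
    regions = regions,
    snr = snr
  )
}

# Truth metrics -> one-voxel components for hand-built signals.
example_amplitudes <- c(
  PCr = 1.24, Pi = 0.41, ATP_gamma = 1, ATP_alpha = 1, ATP_beta = 1,
  PC = 0.24, PE = 0.30, GPC = 0.22, GPE = 0.23, MM = 0.25, NADH = 0.15
)
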