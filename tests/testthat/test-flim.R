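bw_raw <- 12.5 / 256   # ns per raw TCSPC bin over a 12.5 ns record

test_that("Gaussian IRF is unit-sum with the stated width", {
  irf <- make_gaussian_irf(311, bw_raw, 256)
  expect_equal(sum(irf), 1, tolerance = 1e-12)
  # numerically measured FWHM on a fine grid matches 311 ps within a bin
  fine_bw <- 0.002
  irf_f <- make_gaussian_irf(311, fine_bw, 2000)
  above <- which(irf_f >= max(irf_f) / 2)
  fwhm_ps <- (max(above) - min(above) + 1) * fine_bw * 1000
  expect_lt(abs(fwhm_ps - 311), fine_bw * 1000 + 1e-9)
  # zero-width limit collapses to a single-bin spike
  spike <- make_gaussian_irf(0, bw_raw, 64)
  expect_equal(sum(spike > 0), 1L)
  expect_warning(make_gaussian_irf(10, bw_raw, 64), "delta")
})

test_that("decay model reduces to a single exponential in the alpha1 = 1 limit", {
  n <- 128
  delta <- c(1, rep(0, n - 1))
  mu <- decay_model(1, 0.5, 3, 1e4, 0, delta, bw_raw, n)
  t <- (seq_len(n) - 0.5) * bw_raw
  expected <- exp(-t / 0.5)
  expect_equal(mu / mu[1], expected / expected[1], tolerance = 1e-10)
  # normalization: decaying part integrates to the requested amplitude
  irf <- make_gaussian_irf(311, bw_raw, n)
  mu2 <- decay_model(0.6, 0.4, 2.5, 5000, 0, irf, bw_raw, n)
  expect_equal(sum(mu2), 5000, tolerance = 1e-9)
})

test_that("z-projection sums masked slices and matches brute-force summation", {
  set.seed(3)
  h <- array(rpois(3 * 4 * 5 * 8, 20), dim = c(3, 4, 5, 8))
  mask <- array(TRUE, dim = c(3, 4, 5))
  pz <- project_z(h, mask)
  # brute-force oracle: explicit loop over every voxel
  brute <- array(0, dim = c(4, 5, 8))
  for (z in 1:3) for (i in 1:4) for (j in 1:5) for (b in 1:8)
    brute[i, j, b] <- brute[i, j, b] + h[z, i, j, b]
  expect_equal(pz$counts, brute)
  # two identical slices double the counts
  h2 <- array(0, dim = c(2, 2, 2, 4))
  h2[1, , , ] <- array(5, dim = c(2, 2, 4))
  h2[2, , , ] <- array(5, dim = c(2, 2, 4))
  expect_equal(project_z(h2, array(TRUE, c(2, 2, 2)))$counts,
               array(10, c(2, 2, 4)))
  # masking out one slice leaves the other
  m <- array(TRUE, c(2, 2, 2)); m[2, , ] <- FALSE
  expect_equal(project_z(h2, m)$counts, array(5, c(2, 2, 4)))
  expect_warning(project_z(h2, array(FALSE, c(2, 2, 2))), "excludes")
})

test_that("temporal binning 256 -> 64 conserves photon counts per pixel exactly", {
  set.seed(5)
  counts <- array(rpois(4 * 6 * 256, 3), dim = c(4, 6, 256))
  binned <- bin_decays(counts, spatial_radius = 0L, temporal_factor = 4L)
  expect_equal(dim(binned), c(4L, 6L, 64L))
  expect_equal(apply(binned, c(1, 2), sum), apply(counts, c(1, 2), sum))
  # non-divisor factors are rejected
  expect_error(bin_decays(counts, temporal_factor = 5L), "divide")
  # spatial radius 0 is the identity in space
  expect_equal(bin_decays(counts, 0L, 1L), counts)
  # a spatially uniform field keeps its per-bin shape under binning
  u <- array(rep(rpois(16, 50), each = 25), dim = c(5, 5, 16))
  bu <- bin_decays(u, spatial_radius = 1L, temporal_factor = 1L)
  expect_equal(bu[3, 3, ] / sum(bu[3, 3, ]), u[3, 3, ] / sum(u[3, 3, ]),
               tolerance = 1e-12)
})

test_that("noise-free biexponential fits recover parameters to 1e-3 relative", {
  irf <- make_gaussian_irf(311, bw_raw, 256)
  y <- decay_model(0.7, 0.4, 2.5, 1e4, 0, irf, bw_raw, 256)
  f <- fit_decay(y, irf, bw_raw, restarts = 5L, seed = 2)
  expect_identical(f$qc, "ok")
  expect_equal(f$alpha1, 0.7, tolerance = 1e-3)
  expect_equal(f$tau1, 0.4, tolerance = 1e-3)
  expect_equal(f$tau2, 2.5, tolerance = 1e-3)
  expect_gt(f$r_squared, 0.999)
  expect_lte(f$tau1, f$tau2)
  expect_equal(f$tau_m, f$alpha1 * f$tau1 + f$alpha2 * f$tau2)
  # alpha1 = 1 collapses to a single exponential with tau_m = tau1
  y1 <- decay_model(1, 0.8, 5, 1e4, 0, irf, bw_raw, 256)
  f1 <- fit_decay(y1, irf, bw_raw, seed = 3)
  expect_equal(f1$tau_m, 0.8, tolerance = 5e-3)
  # photon floor: sparse decays are skipped with a code, not fitted
  f_low <- fit_decay(y / 1000, irf, bw_raw, min_photons = 500)
  expect_identical(f_low$qc, "low_photons")
  expect_true(is.na(f_low$tau_m))
})

test_that("least-squares optimum agrees with a coarse grid-search oracle", {
  irf <- make_gaussian_irf(311, bw_raw, 64 * 4)[1:256]
  irf <- irf / sum(irf)
  y <- decay_model(0.65, 0.5, 2.2, 8000, 2, irf, bw_raw, 256)
  yb <- colSums(matrix(y, nrow = 4))
  f <- fit_decay(yb, irf, bw_raw * 4, restarts = 5L, seed = 7)
  # oracle: exhaustive grid over (alpha1, tau1, tau2) with amplitude
  # and background solved linearly per point
  grid_a <- seq(0.45, 0.85, by = 0.05)
  grid_t1 <- seq(0.3, 0.7, by = 0.05)
  grid_t2 <- seq(1.8, 2.6, by = 0.1)
  best <- list(rss = Inf)
  for (a in grid_a) for (t1 in grid_t1) for (t2 in grid_t2) {
    mu_s <- decay_model(a, t1, t2, 1, 0, irf, bw_raw * 4, 64, oversample = 4)
    X <- cbind(mu_s, 1)
    cf <- stats::lm.fit(X, yb)$coefficients
    rss <- sum((yb - X %*% cf)^2)
    if (rss < best$rss) best <- list(rss = rss, a = a, t1 = t1, t2 = t2)
  }
  expect_lt(abs(f$alpha1 - best$a), 0.05 + 1e-9)
  expect_lt(abs(f$tau1 - best$t1), 0.05 + 1e-9)
  expect_lt(abs(f$tau2 - best$t2), 0.1 + 1e-9)
  expect_lte(f$rss, best$rss + 1e-8 * sum(yb^2))
})

test_that("component labelling is canonical: tau1 <= tau2 regardless of start", {
  irf <- make_gaussian_irf(311, bw_raw, 256)
  y <- decay_model(0.3, 0.4, 2.5, 1e4, 0, irf, bw_raw, 256)
  for (s in 1:4) {
    f <- fit_decay(y, irf, bw_raw, restarts = 2L, seed = s)
    expect_lte(f$tau1, f$tau2)
    expect_equal(f$tau_m, f$alpha1 * f$tau1 + (1 - f$alpha1) * f$tau2)
  }
})

test_that("mean lifetime and free/bound ratio arithmetic", {
  f <- list(alpha1 = 0.5, tau1 = 0.4, tau2 = 2.0)
  expect_equal(mean_lifetime(f), 1.2)
  expect_equal(free_bound_ratio(list(alpha1 = 0.8)), 4)
  expect_true(is.na(free_bound_ratio(list(alpha1 = 1))))
  # tau_m increases with the slow (bound) fraction
  tm <- sapply(seq(0, 1, 0.1), function(a2)
    mean_lifetime(list(alpha1 = 1 - a2, tau1 = 0.4, tau2 = 2.5)))
  expect_true(all(diff(tm) > 0))
  # tau_m always lies between the two lifetimes
  set.seed(9)
  for (k in 1:20) {
    a <- runif(1); t1 <- runif(1, 0.1, 1); t2 <- t1 + runif(1, 0.1, 3)
    tm1 <- mean_lifetime(list(alpha1 = a, tau1 = t1, tau2 = t2))
    expect_gte(tm1, t1); expect_lte(tm1, t2)
  }
})

test_that("Poisson-noise recovery: binned fits reach ~1% median tau_m error at 5000 photons", {
  # canonical workflow: spatial moving-window pooling (radius 2) plus
  # 256 -> 64 temporal binning before fitting; the photon pooling is
  # what buys the precision
  truth <- simulate_monolayer(monolayer_params(Lx = 220, Ly = 200,
                                               front0 = 200), seed = 3)
  stack <- synthesize_flim_stack(truth, imaging_config(),
                                 photons_per_pixel = 5000,
                                 pixel_size = 25, seed = 8)
  binned <- bin_decays(stack$counts, spatial_radius = 2L,
                       temporal_factor = 4L)
  maps <- fit_flim_field(binned, stack$irf, stack$bin_width * 4,
                         restarts = 3L, seed = 9)
  relerr <- abs(maps$tau_m - stack$tau_m_map) / stack$tau_m_map
  expect_lt(stats::median(relerr, na.rm = TRUE), 0.02)
  expect_true(all(maps$qc == "ok"))
})
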