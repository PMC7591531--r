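test_that("simulation is deterministic and rejects bad configurations", {
  a <- small_world(seed = 9)
  b <- small_world(seed = 9)
  expect_identical(a$cells, b$cells)
  expect_identical(a$positions, b$positions)
  expect_error(monolayer_params(Lx = -5), "positive")
  expect_error(monolayer_params(front0 = 1e6), "inside the domain")
  expect_error(monolayer_params(tau1 = 3, tau2 = 2), "tau1 < tau2")
  expect_error(monolayer_params(redox_edge = 0), "positive")
})

test_that("zero velocity freezes the monolayer; front advances at the set speed", {
  frozen <- simulate_monolayer(
    monolayer_params(Lx = 300, Ly = 100, front0 = 200,
                     v_front = 0, v_edge = 0, v_bulk = 0), seed = 2)
  for (f in seq_along(frozen$positions))
    expect_equal(frozen$positions[[f]], frozen$positions[[1]])
  expect_true(all(frozen$cells$speed == 0))
  # front kinematics: advance = v * T within the integration step
  p <- monolayer_params(Lx = 500, Ly = 100, front0 = 200, v_front = 24,
                        n_frames = 8, frame_interval = 15)
  tr <- simulate_monolayer(p, seed = 2)
  T_h <- (p$n_frames - 1) * p$frame_interval / 60
  expect_equal(tr$front_position[p$n_frames] - tr$front_position[1],
               24 * T_h, tolerance = 1e-9)
  expect_true(all(diff(tr$front_position) >= 0))
})

test_that("rendered Peredox channels encode redox exactly (noise-free round trip)", {
  truth <- small_world(seed = 4)
  calib <- peredox_calibration()
  rend <- render_peredox_frames(truth, calib, pixel_size = 1.0, seed = 5)
  ratios <- per_cell_ratio(rend$red[[1]], rend$green[[1]], rend$labels[[1]])
  F_true <- redox_to_fluorescence(truth$cells$redox, calib)
  got <- ratios$F_raw[match(truth$cells$cell_id, ratios$label)]
  relerr <- abs(got - F_true) / F_true
  # within rendering quantization / blob-overlap tolerance
  expect_lt(stats::median(relerr, na.rm = TRUE), 0.005)
  expect_gt(mean(relerr < 0.02, na.rm = TRUE), 0.95)
  # recovered redox matches ground truth within 2%
  redox_got <- fluorescence_to_redox(got, calib)
  rr <- abs(redox_got - truth$cells$redox) / truth$cells$redox
  expect_lt(stats::median(rr, na.rm = TRUE), 0.02)
})

test_that("channel ratio is independent of per-cell expression level", {
  # two cells with identical redox but different red amplitudes must
  # produce identical red/green ratios (that is the sensor's point)
  calib <- peredox_calibration()
  F_norm <- redox_to_fluorescence(100, calib)
  amps <- c(150, 600)
  red <- mechanometab:::render_gaussian_spots(80, 40, c(20, 60), c(20, 20),
                                              amps, 3)
  green <- mechanometab:::render_gaussian_spots(80, 40, c(20, 60), c(20, 20),
                                                amps / F_norm, 3)
  labels <- mechanometab:::label_nearest_nucleus(80, 40, c(20, 60),
                                                 c(20, 20), 6)
  out <- per_cell_ratio(red, green, labels)
  expect_equal(out$F_raw[1], out$F_raw[2], tolerance = 1e-10)
  expect_equal(out$F_raw[1], as.numeric(F_norm), tolerance = 1e-6)
})

test_that("synthetic TCSPC stacks match their stated expectation", {
  truth <- small_world(seed = 3)
  cfg <- imaging_config()
  # expectation mode: total counts equal the photon budget exactly
  st0 <- synthesize_flim_stack(truth, cfg, photons_per_pixel = 4000,
                               pixel_size = 30, poisson = FALSE)
  totals <- apply(st0$counts, c(1, 2), sum)
  expect_equal(as.vector(totals), rep(4000, length(totals)),
               tolerance = 1e-9)
  # Poisson mode: across many pixels sharing one expectation, the mean
  # per-bin count sits within 3 SE of the expectation
  stp <- synthesize_flim_stack(truth, cfg, photons_per_pixel = 4000,
                               pixel_size = 30, poisson = TRUE, seed = 6)
  j <- 3
  mu <- st0$counts[1, j, ]
  draws <- stp$counts[, j, ]           # ny draws of the same curve
  n_draws <- nrow(draws)
  se <- sqrt(mu / n_draws)
  frac_in <- mean(abs(colMeans(draws) - mu) <= 3 * se + 1e-9)
  expect_gt(frac_in, 0.95)
  # ordering violation rejected
  bad <- truth; bad$params$tau1 <- 5
  expect_error(synthesize_flim_stack(bad, cfg), "ordering")
})

test_that("forward elastic response is linear and physically shaped", {
  gel <- list(shear_modulus = 9600, poisson = 0.5)
  n <- 64; h <- 4
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  # localized patch, mean removed to satisfy zero net force
  tx[30:34, 30:34] <- 100
  tx <- tx - mean(tx)
  fld <- list(xs = (1:n - 0.5) * h, ys = (1:n - 0.5) * h,
              tx = tx, ty = ty, spacing = h)
  fwd <- forward_displacement_field(fld, gel)
  # zero traction -> zero displacement
  z <- forward_displacement_field(list(xs = fld$xs, ys = fld$ys,
                                       tx = matrix(0, n, n),
                                       ty = matrix(0, n, n), spacing = h), gel)
  expect_equal(max(abs(z$ux)), 0)
  # linearity
  fld2 <- fld; fld2$tx <- 2 * fld$tx
  fwd2 <- forward_displacement_field(fld2, gel)
  expect_equal(fwd2$ux, 2 * fwd$ux, tolerance = 1e-12)
  # displacement peaks at the patch, decays with distance, and aligns
  # with the traction direction at the patch centre
  pk <- which(abs(fwd$ux) == max(abs(fwd$ux)), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(pk - c(32, 32))), 3)
  centre <- fwd$ux[32, 32]
  expect_gt(centre, 0)                       # same sign as the traction
  expect_lt(abs(fwd$ux[32, 60]), abs(centre) / 3)
  # monotone radial decay away from the patch, and the near field is
  # within a factor ~2 of the real-space point-force prediction (the
  # periodic box and the compensating background distort the far field)
  profile_right <- abs(fwd$ux[32, 36:50])
  expect_true(all(diff(profile_right) < 0))
  patch_force <- sum(fld$tx[fld$tx > 0]) * h^2   # total positive force
  o_near <- abs(boussinesq_point(patch_force, (40 - 32) * h, 0, 9600)[1])
  expect_gt(abs(fwd$ux[32, 40]) / o_near, 0.5)
  expect_lt(abs(fwd$ux[32, 40]) / o_near, 2)
  expect_error(forward_displacement_field(
    list(tx = 1:5, ty = 1:5, spacing = 4), gel), "regular")
})

test_that("bead pairs are reproducible and degrade gracefully", {
  truth <- small_world(seed = 5)
  fwd <- forward_displacement_field(truth$traction, imaging_config())
  a <- render_bead_images(fwd, pixel_size = 1, seed = 11)
  b <- render_bead_images(fwd, pixel_size = 1, seed = 11)
  expect_identical(a$stressed, b$stressed)
  # zero displacement -> identical image pair
  zero <- fwd; zero$ux[] <- 0; zero$uy[] <- 0
  pz <- render_bead_images(zero, pixel_size = 1, seed = 3)
  expect_equal(pz$stressed, pz$relaxed)
  # huge displacements trigger the ambiguity warning
  big <- fwd; big$ux[] <- 40
  expect_warning(render_bead_images(big, pixel_size = 1, seed = 3),
                 "ambiguous")
})

test_that("uptake renders follow the prescribed profile and mask the layer", {
  truth <- small_world(seed = 6)
  # flat profile -> flat x-binned trace inside the layer
  flat <- render_uptake_images(truth, profile = function(d) 200,
                               pixel_size = 2, background = 0)
  tr <- bin_image_profile(flat$image, pixel_size = 2, bin_width = 50,
                          mask = flat$mask)
  inside <- tr$n_pixels > 0
  expect_true(any(inside))
  expect_true(all(abs(tr$mean[inside] - 200) < 1e-9))
  # mask area equals the layer footprint
  front_px <- sum((seq_len(ncol(flat$mask)) - 0.5) * 2 <=
                    truth$front_position[1])
  expect_equal(sum(flat$mask), front_px * nrow(flat$mask))
  # step profile: recovered edge position within a bin of the front
  step <- render_uptake_images(truth,
                               profile = function(d) ifelse(d < 60, 400, 100),
                               pixel_size = 2, background = 0)
  trs <- bin_image_profile(step$image, pixel_size = 2, bin_width = 10,
                           mask = step$mask)
  jump <- trs$x_center[which(diff(trs$mean) > 100) + 1]
  expect_lt(abs((truth$front_position[1] - 60) - (jump - 5)), 10 + 1e-9)
})

test_that("rendering preserves the prescribed edge-to-bulk orderings", {
  truth <- small_world(seed = 7)
  cells <- truth$cells
  edge <- cells$x0 > stats::quantile(cells$x0, 0.8)
  bulk <- cells$x0 < stats::quantile(cells$x0, 0.2)
  expect_lt(mean(cells$redox[edge]), mean(cells$redox[bulk]))   # edge-low
  expect_gt(mean(cells$speed[edge]), mean(cells$speed[bulk]))   # edge-fast
  expect_gt(mean(cells$alpha1[edge]), mean(cells$alpha1[bulk])) # more free NADH
  expect_lt(mean(cells$tau_m[edge]), mean(cells$tau_m[bulk]))   # edge-short
  expect_gt(mean(cells$traction[edge]), mean(cells$traction[bulk]))
  expect_gt(mean(cells$aspect[edge]), mean(cells$aspect[bulk]))
})
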