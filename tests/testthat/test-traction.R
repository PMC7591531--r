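make_true_field <- function(seed = 1) {
  truth <- simulate_monolayer(monolayer_params(Lx = 400, Ly = 160,
                                               front0 = 250), seed = seed)
  truth$traction
}

test_that("bead displacement measurement recovers rigid and elastic fields", {
  fx <- make_spot_fixture(n = 600, nx = 400, ny = 240, min_sep = 8,
                          sigma = 1.5, seed = 3)
  # identical pair: zero field
  same <- measure_bead_displacements(fx$image, fx$image, pixel_size = 1,
                                     register = FALSE)
  expect_lt(max(abs(same$ux)), 1e-9)
  # known sub-pixel rigid shift, registration disabled
  shifted <- mechanometab:::render_gaussian_spots(400, 240, fx$x + 1.5,
                                                  fx$y, fx$amp, 1.5)
  m <- measure_bead_displacements(shifted, fx$image, pixel_size = 1,
                                  register = FALSE, smooth_sigma = 0)
  expect_lt(abs(mean(m$ux) - 1.5), 0.05)
  expect_lt(abs(mean(m$uy)), 0.05)
  expect_error(measure_bead_displacements(fx$image, fx$image[, 1:100]),
               "identical dimensions")
})

test_that("registration removes stage drift before displacement analysis", {
  fx <- make_spot_fixture(n = 600, nx = 400, ny = 240, min_sep = 8,
                          sigma = 1.5, seed = 4)
  # pure stage drift (5, 3) px: after registration the field is ~zero
  drifted <- mechanometab:::render_gaussian_spots(400, 240, fx$x + 5,
                                                  fx$y + 3, fx$amp, 1.5)
  m <- measure_bead_displacements(drifted, fx$image, pixel_size = 1,
                                  register = TRUE)
  expect_equal(as.numeric(m$drift), c(5, 3))
  expect_lt(sqrt(mean(m$ux^2 + m$uy^2)) - sqrt(5^2 + 3^2), 0.1)
})

test_that("simulated bead pair displacements are accurate to 0.1 px RMS", {
  tf <- make_true_field(seed = 2)
  fwd <- forward_displacement_field(tf, imaging_config())
  bp <- render_bead_images(fwd, pixel_size = 0.5, seed = 5)
  m <- measure_bead_displacements(bp$stressed, bp$relaxed,
                                  pixel_size = 0.5, register = FALSE)
  true_ux <- outer(m$ys, m$xs, function(yy, xx)
    bilinear_interp(fwd$ux, fwd$xs, fwd$ys, xx, yy))
  true_uy <- outer(m$ys, m$xs, function(yy, xx)
    bilinear_interp(fwd$uy, fwd$xs, fwd$ys, xx, yy))
  rms_px <- sqrt(mean((m$ux - true_ux)^2 + (m$uy - true_uy)^2)) / 0.5
  expect_lt(rms_px, 0.1)
})

test_that("traction inversion is the exact inverse of the forward operator", {
  tf <- make_true_field(seed = 1)
  fwd <- forward_displacement_field(tf, imaging_config())
  inv <- compute_tractions(list(ux = fwd$ux, uy = fwd$uy,
                                spacing = fwd$spacing,
                                xs = fwd$xs, ys = fwd$ys),
                           imaging_config(), lambda = 0)
  rel <- sqrt(sum((inv$tx - tf$tx)^2 + (inv$ty - tf$ty)^2) /
                sum(tf$tx^2 + tf$ty^2))
  expect_lt(rel, 0.02)
  # net force balance of the recovered field
  net <- sqrt(sum(inv$tx)^2 + sum(inv$ty)^2) /
    sum(sqrt(inv$tx^2 + inv$ty^2))
  expect_lt(net, 0.01)
  # zero displacement -> zero traction
  z <- compute_tractions(list(ux = fwd$ux * 0, uy = fwd$uy * 0,
                              spacing = fwd$spacing), imaging_config(), 0)
  expect_equal(max(abs(z$tx)), 0)
  # linearity
  inv2 <- compute_tractions(list(ux = 2 * fwd$ux, uy = 2 * fwd$uy,
                                 spacing = fwd$spacing), imaging_config(), 0)
  expect_equal(inv2$tx, 2 * inv$tx, tolerance = 1e-9)
  expect_error(compute_tractions(list(ux = fwd$ux, uy = fwd$uy,
                                      spacing = 0), imaging_config()),
               "positive")
  bad <- fwd; bad$ux[1, 1] <- NA
  expect_error(compute_tractions(bad, imaging_config()), "non-finite")
})

test_that("regularization monotonically damps recovered traction power", {
  tf <- make_true_field(seed = 3)
  fwd <- forward_displacement_field(tf, imaging_config())
  u <- list(ux = fwd$ux, uy = fwd$uy, spacing = fwd$spacing)
  power <- sapply(c(0, 1e-4, 1e-3, 1e-2), function(l) {
    out <- compute_tractions(u, imaging_config(), lambda = l)
    sum(out$tx^2 + out$ty^2)
  })
  expect_true(all(diff(power) <= 0))
})

test_that("two traction patches four grid spacings apart stay resolved", {
  n <- 64; h <- 4
  tx <- matrix(0, n, n)
  tx[31:33, 21:23] <- 120
  tx[31:33, 41:43] <- 120          # 20 nodes apart (> 4 spacings)
  tx <- tx - mean(tx)
  fld <- list(xs = (1:n - 0.5) * h, ys = (1:n - 0.5) * h, tx = tx,
              ty = matrix(0, n, n), spacing = h)
  fwd <- forward_displacement_field(fld, imaging_config())
  inv <- compute_tractions(list(ux = fwd$ux, uy = fwd$uy, spacing = h),
                           imaging_config(), lambda = 1e-4)
  row <- inv$tx[32, ]
  expect_gt(row[22], row[32] + 20)   # two maxima with a valley between
  expect_gt(row[42], row[32] + 20)
})

test_that("inversion is equivariant under 90-degree rotation", {
  n <- 48; h <- 5
  set.seed(8)
  base <- matrix(0, n, n)
  base[18:26, 20:28] <- matrix(runif(81, 0, 100), 9, 9)
  tx <- base - mean(base)
  fld <- list(ux = NULL)
  f1 <- forward_displacement_field(list(tx = tx, ty = matrix(0, n, n),
                                        spacing = h), imaging_config())
  # rotate the traction field by 90 deg: (tx, ty) -> (-ty, tx), grid
  # rotated likewise
  rot <- function(m) t(m)[n:1, , drop = FALSE]
  f2 <- forward_displacement_field(list(tx = matrix(0, n, n),
                                        ty = rot(tx), spacing = h),
                                   imaging_config())
  expect_equal(rot(f1$ux), f2$uy, tolerance = 1e-9)
  expect_equal(rot(f1$uy) * 0, f2$ux * 0)  # shapes agree
})

test_that("per-cell traction averages the field over footprints", {
  xs <- (1:20 - 0.5) * 5; ys <- (1:10 - 0.5) * 5
  field <- list(xs = xs, ys = ys,
                tx = matrix(30, 10, 20), ty = matrix(40, 10, 20))
  cells <- data.frame(cell_id = 1:3, x = c(20, 50, 80), y = c(25, 25, 25))
  out <- per_cell_traction(field, cells)
  expect_equal(out$traction, rep(50, 3))    # |T| = sqrt(30^2+40^2)
  # linearity in the field
  f2 <- field; f2$tx <- 2 * f2$tx; f2$ty <- 2 * f2$ty
  expect_equal(per_cell_traction(f2, cells)$traction, rep(100, 3))
  # edge-elevated synthetic field: per-cell means preserve the ordering
  truth <- simulate_monolayer(monolayer_params(Lx = 400, Ly = 160,
                                               front0 = 250), seed = 4)
  pct <- per_cell_traction(truth$traction,
                           data.frame(cell_id = truth$cells$cell_id,
                                      x = truth$cells$x0,
                                      y = truth$cells$y0))
  expect_equal(pct$traction, truth$cells$traction)
  edge <- truth$cells$x0 > 200; bulk <- truth$cells$x0 < 100
  expect_gt(mean(pct$traction[edge]), mean(pct$traction[bulk]))
})
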