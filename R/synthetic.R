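#' Parameters of the synthetic expanding-monolayer world
#'
#' Collects every knob of the ground-truth generator: domain geometry,
#' cell lattice spacing, the front-relative exponential gradients of
#' speed, redox, lifetime composition and traction, and acquisition
#' timing. The generator prescribes a front-relative velocity field that
#' decays exponentially into the bulk, which is sufficient to create the
#' retrograde gradients (fast/elongated/low-redox/short-lifetime/
#' high-traction cells at the advancing edge, slow jammed cells in the
#' bulk) that the analysis pipeline must resolve. Gradient magnitudes
#' are configurable statements about the synthetic world, not claims
#' about the biology.
#'
#' @param Lx,Ly Domain size in µm.
#' @param front0 Initial x-position of the advancing free edge (µm);
#'   cells occupy `[0, front0]`.
#' @param spacing Mean cell spacing in the jammed bulk (µm).
#' @param spacing_edge Mean spacing at the free edge (µm); larger than
#'   `spacing` gives the edge-high cell-area gradient.
#' @param ar_edge,ar_bulk Target Voronoi aspect ratio at the edge and in
#'   the bulk (cells elongate along the migration axis at the edge).
#' @param jitter Positional jitter as a fraction of local spacing.
#' @param v_front Front advance speed (µm/h).
#' @param v_edge,v_bulk Cell speed at the edge and deep in the bulk
#'   (µm/h).
#' @param decay_len Exponential decay length of all edge-to-bulk
#'   gradients (µm).
#' @param redox_edge,redox_bulk True NAD+/NADH at edge and bulk
#'   (dimensionless; the physiologic range spans roughly 10 to 1000,
#'   with the migrating edge more reduced, i.e. lower).
#' @param alpha1_edge,alpha1_bulk Fast (free-NADH) fraction of the
#'   biexponential decay at edge and bulk; a larger free fraction at the
#'   edge gives the edge-short mean lifetime.
#' @param tau1,tau2 Fast and slow lifetimes (ns); `tau1 < tau2`.
#' @param traction_edge,traction_bulk Traction magnitude scale (Pa) at
#'   edge and bulk.
#' @param traction_spacing Traction/displacement grid spacing (µm).
#' @param n_frames Number of time-lapse frames.
#' @param frame_interval Frame interval in minutes.
#' @return A list of class `monolayer_params`.
#' @export
monolayer_params <- function(Lx = 800, Ly = 160, front0 = 500,
                             spacing = 16, spacing_edge = 22,
                             ar_edge = 1.9, ar_bulk = 1.05,
                             jitter = 0.06,
                             v_front = 20, v_edge = 20, v_bulk = 0.5,
                             decay_len = 150,
                             redox_edge = 30, redox_bulk = 300,
                             alpha1_edge = 0.85, alpha1_bulk = 0.70,
                             tau1 = 0.4, tau2 = 2.5,
                             traction_edge = 300, traction_bulk = 30,
                             traction_spacing = 8,
                             n_frames = 8, frame_interval = 15) {
  p <- as.list(environment())
  if (Lx <= 0 || Ly <= 0) stop("domain dimensions must be positive")
  if (front0 <= 0 || front0 > Lx) stop("'front0' must lie inside the domain")
  if (spacing <= 0 || spacing_edge <= 0) stop("cell spacing must be positive")
  if (tau1 >= tau2) stop("lifetime ordering violated: need tau1 < tau2")
  if (n_frames < 1) stop("'n_frames' must be at least 1")
  if (any(c(alpha1_edge, alpha1_bulk) < 0 | c(alpha1_edge, alpha1_bulk) > 1))
    stop("free fractions must lie in [0, 1]")
  if (redox_edge <= 0 || redox_bulk <= 0) stop("redox must be positive")
  class(p) <- "monolayer_params"
  p
}

#' Imaging configuration
#'
#' Acquisition constants of the two imaging arms: widefield Peredox /
#' bead imaging (0.325 µm/pixel) and multiphoton FLIM (0.792 µm/pixel,
#' 256 raw time bins, 311-ps-FWHM IRF), plus the elastic substrate
#' (9.6 kPa shear modulus, 100 µm thick polyacrylamide gel).
#'
#' @param pixel_size_redox µm per pixel of the widefield channels.
#' @param pixel_size_flim µm per pixel of the FLIM stack.
#' @param frame_interval Minutes between time-lapse frames.
#' @param n_time_bins_raw Raw TCSPC time bins.
#' @param time_bin_width TCSPC bin width in ns (default spans a 12.5 ns
#'   record with 256 bins).
#' @param irf_fwhm IRF full width at half maximum, ps.
#' @param bead_diameter Fiducial bead diameter, µm.
#' @param gel_shear_modulus Substrate shear modulus, Pa.
#' @param gel_poisson Substrate Poisson ratio (0.5 = incompressible).
#' @param gel_thickness Gel thickness, µm.
#' @return A list of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_redox = 0.325,
                           pixel_size_flim = 0.792,
                           frame_interval = 15,
                           n_time_bins_raw = 256,
                           time_bin_width = 12.5 / 256,
                           irf_fwhm = 311,
                           bead_diameter = 0.2,
                           gel_shear_modulus = 9600,
                           gel_poisson = 0.5,
                           gel_thickness = 100) {
  p <- as.list(environment())
  num <- unlist(p[names(p) != "gel_poisson"])
  if (any(num <= 0)) stop("imaging configuration values must be positive")
  if (gel_poisson < 0 || gel_poisson > 0.5)
    stop("'gel_poisson' must lie in [0, 0.5]")
  class(p) <- "imaging_config"
  p
}

# Edge-to-bulk exponential gradient evaluated at distance d >= 0 behind
# the front.
edge_profile <- function(d, edge, bulk, decay_len) {
  bulk + (edge - bulk) * exp(-pmax(d, 0) / decay_len)
}

#' Simulate ground-truth monolayer dynamics
#'
#' Seeds cells on a jittered lattice whose local spacing and anisotropy
#' follow the prescribed edge-to-bulk gradients, then advects them with
#' a front-relative velocity field `v(x) = v_bulk + (v_edge - v_bulk)
#' exp(-(front - x)/decay_len)` while the front advances at `v_front`.
#' Jammed bulk cells barely move; edge cells migrate with the front.
#' Every per-cell truth value (speed, redox, aspect target, traction
#' magnitude, free-NADH fraction) is recorded so downstream measurements
#' can be validated.
#'
#' @param params A [monolayer_params()] object.
#' @param seed Integer seed; output is fully deterministic given the
#'   seed.
#' @return A list of class `monolayer_truth` with elements `cells`
#'   (data.frame of per-cell truth), `positions` (list of per-frame
#'   data.frames `cell_id`, `x`, `y` in µm), `front_position` (µm per
#'   frame), `traction` (gridded true traction field), `params`, `seed`.
#' @export
simulate_monolayer <- function(params = monolayer_params(), seed = 1L) {
  stopifnot(inherits(params, "monolayer_params"))
  set.seed(seed)
  p <- params

  # --- lattice seeding: columns marching back from the front ---------
  xs <- c(); ys <- c(); ar_t <- c(); area_t <- c()
  x <- p$front0
  repeat {
    d <- p$front0 - x
    s <- edge_profile(d, p$spacing_edge, p$spacing, p$decay_len)
    ar <- edge_profile(d, p$ar_edge, p$ar_bulk, p$decay_len)
    dx <- s * sqrt(ar)           # column-to-column step (elongated in x)
    dy <- s / sqrt(ar)
    x <- x - dx / 2
    if (x < dx / 4) break
    ycol <- seq(dy / 2, p$Ly - dy / 4, by = dy)
    xs <- c(xs, rep(x, length(ycol)))
    ys <- c(ys, ycol)
    ar_t <- c(ar_t, rep(ar, length(ycol)))
    area_t <- c(area_t, rep(dx * dy, length(ycol)))
    x <- x - dx / 2
  }
  n <- length(xs)
  if (n < 3L) stop("degenerate configuration: fewer than 3 cells seeded")
  jit <- p$jitter * sqrt(area_t)
  xs <- xs + stats::rnorm(n, 0, jit)
  ys <- pmin(pmax(ys + stats::rnorm(n, 0, jit), 0.5), p$Ly - 0.5)
  xs <- pmin(pmax(xs, 0.5), p$front0 - 0.5)

  # --- advection ------------------------------------------------------
  dt <- p$frame_interval / 60    # h
  front <- p$front0 + (seq_len(p$n_frames) - 1L) * p$v_front * dt
  positions <- vector("list", p$n_frames)
  px <- xs; py <- ys
  positions[[1]] <- data.frame(cell_id = seq_len(n), x = px, y = py)
  disp_sum <- numeric(n)
  for (f in seq_len(p$n_frames)[-1]) {
    v <- edge_profile(front[f - 1] - px, p$v_edge, p$v_bulk, p$decay_len)
    step <- v * dt
    px <- pmin(px + step, front[f] - 0.5)
    disp_sum <- disp_sum + step
    positions[[f]] <- data.frame(cell_id = seq_len(n), x = px, y = py)
  }
  speed_true <- if (p$n_frames > 1) disp_sum / ((p$n_frames - 1) * dt)
                else rep(0, n)

  d0 <- p$front0 - xs            # distance behind front at t = 0
  cells <- data.frame(
    cell_id = seq_len(n), x0 = xs, y0 = ys,
    speed = speed_true,
    redox = edge_profile(d0, p$redox_edge, p$redox_bulk, p$decay_len),
    alpha1 = edge_profile(d0, p$alpha1_edge, p$alpha1_bulk, p$decay_len),
    aspect = ar_t,
    area = area_t
  )
  cells$tau_m <- cells$alpha1 * p$tau1 + (1 - cells$alpha1) * p$tau2

  traction <- true_traction_field(p)
  # per-cell truth is the same estimand the pipeline reports: the mean
  # traction magnitude over the cell footprint (nearest-centroid
  # partition of the grid), not a point sample at the centroid
  tt <- per_cell_traction(traction,
                          data.frame(cell_id = cells$cell_id,
                                     x = cells$x0, y = cells$y0))
  cells$traction <- tt$traction[match(cells$cell_id, tt$cell_id)]

  structure(list(cells = cells, positions = positions,
                 front_position = front, traction = traction,
                 params = p, seed = seed),
            class = "monolayer_truth")
}

#' @export
print.monolayer_truth <- function(x, ...) {
  cat(sprintf("Synthetic monolayer: %d cells, %d frames, domain %g x %g um\n",
              nrow(x$cells), length(x$positions), x$params$Lx, x$params$Ly))
  cat(sprintf("  front: %.1f -> %.1f um (seed %d)\n",
              x$front_position[1], x$front_position[length(x$front_position)],
              x$seed))
  invisible(x)
}

# Prescribed, self-equilibrated true traction field: magnitude follows
# the edge-to-bulk gradient, direction -x (cells pull rearward at the
# edge), smoothly tapered in y, rolled off toward x = 0 (the layer
# midline, where tractions vanish by symmetry) and ahead of the front,
# with the mean removed so the net force over the domain vanishes. The
# roll-offs also keep the field compact, which the periodic Fourier
# elasticity operators require.
true_traction_field <- function(p) {
  h <- p$traction_spacing
  xs <- seq(h / 2, p$Lx - h / 2, by = h)
  ys <- seq(h / 2, p$Ly - h / 2, by = h)
  d <- p$front0 - xs
  mag <- edge_profile(d, p$traction_edge, p$traction_bulk, p$decay_len)
  # ahead of the front: decay over a couple of grid cells, not a cliff
  mag[d < 0] <- p$traction_edge * exp(d[d < 0] / (2 * h))
  # midline roll-off over ~100 um
  mid_taper <- pmin(xs / min(100, p$front0 / 4), 1)
  mag <- mag * sin(pi / 2 * mid_taper)^2
  taper_y <- sin(pi * ys / p$Ly)^2
  tx <- -outer(taper_y, mag)          # rows = y, cols = x
  tx <- tx - mean(tx)
  ty <- matrix(0, length(ys), length(xs))
  list(xs = xs, ys = ys, tx = tx, ty = ty, spacing = h)
}

#' Render two-channel Peredox frames from ground truth
#'
#' Paints every nucleus as a compact Gaussian blob in the red (mCherry)
#' channel with a per-cell log-normal amplitude emulating expression
#' variation, and sets the green (T-Sapphire) amplitude so the
#' red/green ratio equals the normalized fluorescence ratio implied by
#' the cell's true redox state under the calibration model. Optional
#' Gaussian read noise can be added. A ground-truth label image marks
#' each nucleus footprint.
#'
#' @param truth A `monolayer_truth` object.
#' @param calib A [peredox_calibration()] model (must be invertible over
#'   the redox range used).
#' @param pixel_size µm per pixel of the rendered frames.
#' @param nucleus_sigma Nucleus blob standard deviation in pixels.
#' @param expression_sdlog Log-SD of the per-cell red amplitude.
#' @param noise_sd Additive Gaussian noise SD (0 = noise-free).
#' @param frames Which frames to render (default all).
#' @param seed Integer seed.
#' @return A list of class `peredox_frames`: `red`, `green`, `labels`
#'   (lists of matrices), `pixel_size`, `F_norm` (per-cell true
#'   normalized ratio), `n_clipped` (cells whose redox fell outside the
#'   invertible fluorescence range).
#' @export
render_peredox_frames <- function(truth, calib = peredox_calibration(),
                                  pixel_size = 0.325, nucleus_sigma = 3,
                                  expression_sdlog = 0.2, noise_sd = 0,
                                  frames = NULL, seed = 1L) {
  stopifnot(inherits(truth, "monolayer_truth"))
  set.seed(seed)
  p <- truth$params
  if (is.null(frames)) frames <- seq_along(truth$positions)
  nx <- ceiling(p$Lx / pixel_size); ny <- ceiling(p$Ly / pixel_size)
  n <- nrow(truth$cells)
  red_amp <- stats::rlnorm(n, log(200), expression_sdlog)
  F_norm <- redox_to_fluorescence(truth$cells$redox, calib)
  margin <- 1e-3 * calib$A
  clipped <- F_norm <= 1 + margin | F_norm >= 1 + calib$A - margin
  if (any(clipped))
    warning(sum(clipped), " cells have redox outside the invertible range")
  green_amp <- red_amp / F_norm
  red <- green <- labels <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    pos <- truth$positions[[frames[k]]]
    xp <- pos$x / pixel_size + 0.5; yp <- pos$y / pixel_size + 0.5
    red[[k]] <- render_gaussian_spots(nx, ny, xp, yp, red_amp, nucleus_sigma)
    green[[k]] <- render_gaussian_spots(nx, ny, xp, yp, green_amp, nucleus_sigma)
    if (noise_sd > 0) {
      red[[k]] <- red[[k]] + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
      green[[k]] <- green[[k]] + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
    }
    labels[[k]] <- label_nearest_nucleus(nx, ny, xp, yp,
                                         radius = 2 * nucleus_sigma)
  }
  structure(list(red = red, green = green, labels = labels,
                 pixel_size = pixel_size, F_norm = F_norm,
                 n_clipped = sum(clipped), frames = frames),
            class = "peredox_frames")
}

# Ground-truth label image: pixels within `radius` of a nucleus centre,
# assigned to the nearest centre.
label_nearest_nucleus <- function(nx, ny, x, y, radius) {
  lab <- matrix(0L, ny, nx)
  best <- matrix(Inf, ny, nx)
  r <- ceiling(radius)
  for (i in seq_along(x)) {
    j1 <- max(1L, floor(x[i] - r)); j2 <- min(nx, ceiling(x[i] + r))
    i1 <- max(1L, floor(y[i] - r)); i2 <- min(ny, ceiling(y[i] + r))
    if (j1 > j2 || i1 > i2) next
    d2 <- outer(((i1:i2) - y[i])^2, ((j1:j2) - x[i])^2, "+")
    sel <- d2 <= radius^2 & d2 < best[i1:i2, j1:j2]
    blk <- lab[i1:i2, j1:j2]
    blk[sel] <- i
    lab[i1:i2, j1:j2] <- blk
    bb <- best[i1:i2, j1:j2]
    bb[sel] <- d2[sel]
    best[i1:i2, j1:j2] <- bb
  }
  lab
}

#' Synthesize a TCSPC decay stack from ground truth
#'
#' Builds, for each FLIM pixel, the expected photon histogram of the
#' biexponential decay at the local free-NADH fraction, convolved with
#' the Gaussian IRF, with a constant background, normalized so the total
#' expected count equals the photon budget, then draws Poisson counts.
#'
#' @param truth A `monolayer_truth` object (frame 1 geometry is used).
#' @param config An [imaging_config()].
#' @param photons_per_pixel Expected total photons per pixel.
#' @param background_frac Background level as a fraction of the
#'   noise-free curve peak. Default 0.01.
#' @param pixel_size µm per FLIM pixel (defaults to the config value).
#' @param poisson Draw Poisson counts (`TRUE`) or return expectations.
#' @param seed Integer seed.
#' @return A list of class `flim_stack`: `counts` (`[y, x, bin]`),
#'   `irf`, `bin_width` (ns), `pixel_size`, truth maps `alpha1_map`,
#'   `tau_m_map`, and the generating `tau1`, `tau2`.
#' @export
synthesize_flim_stack <- function(truth, config = imaging_config(),
                                  photons_per_pixel = 5000,
                                  background_frac = 0.01,
                                  pixel_size = config$pixel_size_flim,
                                  poisson = TRUE, seed = 1L) {
  stopifnot(inherits(truth, "monolayer_truth"))
  if (photons_per_pixel <= 0) stop("'photons_per_pixel' must be positive")
  p <- truth$params
  if (p$tau1 >= p$tau2) stop("lifetime ordering violated: need tau1 < tau2")
  set.seed(seed)
  nb <- config$n_time_bins_raw
  bw <- config$time_bin_width
  irf <- make_gaussian_irf(config$irf_fwhm, bw, nb)
  nx <- ceiling(p$front0 / pixel_size)
  ny <- max(4L, ceiling(p$Ly / pixel_size))
  xs <- (seq_len(nx) - 0.5) * pixel_size
  a1 <- edge_profile(truth$front_position[1] - xs,
                     p$alpha1_edge, p$alpha1_bulk, p$decay_len)
  counts <- array(0, dim = c(ny, nx, nb))
  alpha1_map <- matrix(rep(a1, each = ny), ny, nx)
  for (j in seq_len(nx)) {
    mu <- decay_model(a1[j], p$tau1, p$tau2, 1, 0, irf, bw, nb)
    C <- background_frac * max(mu)
    mu <- mu + C
    mu <- mu * (photons_per_pixel / sum(mu))
    for (i in seq_len(ny))
      counts[i, j, ] <- if (poisson) stats::rpois(nb, mu) else mu
  }
  structure(list(counts = counts, irf = irf, bin_width = bw,
                 pixel_size = pixel_size, alpha1_map = alpha1_map,
                 tau_m_map = alpha1_map * p$tau1 + (1 - alpha1_map) * p$tau2,
                 tau1 = p$tau1, tau2 = p$tau2, seed = seed),
            class = "flim_stack")
}

#' Surface displacements of an elastic half-space under traction
#'
#' Forward Boussinesq problem: given a traction field on a regular grid,
#' computes the in-plane surface displacements of a semi-infinite
#' incompressible elastic substrate in Fourier space. Linear in the
#' traction; serves as the oracle for the traction inversion.
#'
#' @param traction A list with `tx`, `ty` (matrices, rows = y),
#'   `spacing` (µm) and optionally `xs`, `ys`.
#' @param gel A list with `shear_modulus` (Pa) and `poisson` ratio, or
#'   an [imaging_config()].
#' @return The input list with `ux`, `uy` displacement matrices (µm)
#'   added.
#' @export
forward_displacement_field <- function(traction, gel = imaging_config()) {
  G <- if (inherits(gel, "imaging_config")) gel$gel_shear_modulus
       else gel$shear_modulus
  nu <- if (inherits(gel, "imaging_config")) gel$gel_poisson else gel$poisson
  op <- traction_fourier_op(traction, G, nu)
  tx_h <- stats::fft(traction$tx); ty_h <- stats::fft(traction$ty)
  ux_h <- op$gxx * tx_h + op$gxy * ty_h
  uy_h <- op$gxy * tx_h + op$gyy * ty_h
  traction$ux <- Re(stats::fft(ux_h, inverse = TRUE)) / length(ux_h)
  traction$uy <- Re(stats::fft(uy_h, inverse = TRUE)) / length(uy_h)
  traction
}

# Fourier-space Boussinesq Green's tensor on the grid of `field`.
# G(k) = 2(1+nu) / (E k^3) * [[(1-nu)k^2 + nu ky^2, -nu kx ky],
#                             [-nu kx ky, (1-nu)k^2 + nu kx^2]]
# with E = 2 G (1+nu); the k = 0 mode is null (zero-mean traction).
traction_fourier_op <- function(field, G, nu) {
  tx <- field$tx
  if (is.null(dim(tx)) || nrow(tx) < 2 || ncol(tx) < 2)
    stop("traction grid must be a regular 2D lattice")
  if (!all(dim(field$ty) == dim(tx)))
    stop("traction components must share one regular grid")
  h <- field$spacing
  if (is.null(h) || h <= 0) stop("grid spacing must be positive")
  ny <- nrow(tx); nx <- ncol(tx)
  kx <- 2 * pi * fft_freq(nx, h)
  ky <- 2 * pi * fft_freq(ny, h)
  KX <- matrix(rep(kx, each = ny), ny, nx)
  KY <- matrix(rep(ky, nx), ny, nx)
  K <- sqrt(KX^2 + KY^2)
  E <- 2 * G * (1 + nu)
  pref <- ifelse(K > 0, 2 * (1 + nu) / (E * K^3), 0)
  list(gxx = pref * ((1 - nu) * K^2 + nu * KY^2),
       gyy = pref * ((1 - nu) * K^2 + nu * KX^2),
       gxy = pref * (-nu * KX * KY))
}

#' Render a bead image pair from a displacement field
#'
#' Scatters fiducial beads uniformly at random (seeded), renders the
#' relaxed (traction-free) reference image, then shifts every bead by
#' the locally interpolated displacement and renders the stressed image.
#'
#' @param field A displacement field as returned by
#'   [forward_displacement_field()] (needs `xs`, `ys`, `ux`, `uy` in
#'   µm).
#' @param pixel_size µm per pixel of the bead channel.
#' @param bead_density Beads per µm².
#' @param psf_sigma Bead point-spread sigma in pixels.
#' @param seed Integer seed.
#' @return A list of class `bead_pair`: `stressed`, `relaxed`
#'   (matrices), `beads` (data.frame of true positions and shifts, µm),
#'   `pixel_size`.
#' @export
render_bead_images <- function(field, pixel_size = 0.65,
                               bead_density = 0.05, psf_sigma = 1.5,
                               seed = 1L) {
  stopifnot(!is.null(field$ux), !is.null(field$uy))
  set.seed(seed)
  Lx <- max(field$xs) + field$spacing / 2
  Ly <- max(field$ys) + field$spacing / 2
  n_beads <- max(10L, round(bead_density * Lx * Ly))
  bx <- stats::runif(n_beads, 0, Lx)
  by <- stats::runif(n_beads, 0, Ly)
  ux <- bilinear_interp(field$ux, field$xs, field$ys, bx, by)
  uy <- bilinear_interp(field$uy, field$xs, field$ys, bx, by)
  mean_spacing <- sqrt(Lx * Ly / n_beads)
  if (max(sqrt(ux^2 + uy^2)) > mean_spacing / 2)
    warning("displacements exceed half the mean bead spacing; ",
            "tracking may be ambiguous")
  nx <- ceiling(Lx / pixel_size); ny <- ceiling(Ly / pixel_size)
  to_px <- function(v) v / pixel_size + 0.5
  relaxed <- render_gaussian_spots(nx, ny, to_px(bx), to_px(by),
                                   1000, psf_sigma)
  stressed <- render_gaussian_spots(nx, ny, to_px(bx + ux), to_px(by + uy),
                                    1000, psf_sigma)
  structure(list(stressed = stressed, relaxed = relaxed,
                 beads = data.frame(x = bx, y = by, ux = ux, uy = uy),
                 pixel_size = pixel_size),
            class = "bead_pair")
}

#' Render a dye-uptake image with a layer mask
#'
#' Single-channel intensity image whose value inside the cell layer
#' follows a prescribed x-dependent profile (e.g. a glucose-uptake
#' gradient), with constant background outside the layer, plus the
#' ground-truth layer mask.
#'
#' @param truth A `monolayer_truth` object.
#' @param profile A function of distance behind the front (µm) giving
#'   intensity, or `NULL` for the default edge-high exponential.
#' @param pixel_size µm per pixel.
#' @param background Intensity outside the layer.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list with `image`, `mask` (matrices), `pixel_size`.
#' @export
render_uptake_images <- function(truth, profile = NULL, pixel_size = 1.3,
                                 background = 10, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "monolayer_truth"))
  set.seed(seed)
  p <- truth$params
  if (is.null(profile))
    profile <- function(d) edge_profile(d, 400, 100, p$decay_len)
  front <- truth$front_position[1]
  nx <- ceiling(p$Lx / pixel_size); ny <- ceiling(p$Ly / pixel_size)
  xs <- (seq_len(nx) - 0.5) * pixel_size
  inside <- xs <= front
  vals <- ifelse(inside, profile(front - xs), background)
  img <- matrix(rep(vals, each = ny), ny, nx)
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
  mask <- matrix(rep(inside, each = ny), ny, nx)
  list(image = img, mask = mask, pixel_size = pixel_size)
}
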