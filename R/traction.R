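#' Measure bead displacements from a stressed/relaxed image pair
#'
#' Windowed cross-correlation (PIV-style) between the relaxed reference
#' image and the stressed image: the field reports how far the gel
#' surface moved from the relaxed to the stressed state, on a regular
#' grid of window centres. An optional rigid registration step removes
#' stage-positioning offset estimated over the whole field before the
#' windowed pass. Windows whose correlation peak is not decisive
#' (peak-to-second-peak ratio below threshold) are masked and filled by
#' local interpolation.
#'
#' @param stressed,relaxed Same-shape bead-channel matrices.
#' @param pixel_size µm per pixel.
#' @param window Correlation window size in pixels.
#' @param overlap Fractional window overlap.
#' @param register Estimate and remove a global rigid shift first.
#' @param peak_ratio_min Decisiveness threshold for window peaks.
#' @param smooth_sigma Gaussian smoothing of the displacement field, in
#'   grid nodes (0 disables). A light filter (default 1) suppresses
#'   window-level correlation noise before the ill-conditioned
#'   inversion; a uniform field passes through unchanged.
#' @return A list of class `displacement_field`: `xs`, `ys` (grid
#'   centres, µm), `ux`, `uy` (µm), `spacing` (µm), `drift` (the removed
#'   rigid shift, px), `n_masked`.
#' @export
measure_bead_displacements <- function(stressed, relaxed, pixel_size = 0.65,
                                       window = 32L, overlap = 0.5,
                                       register = TRUE,
                                       peak_ratio_min = 1.2,
                                       smooth_sigma = 1) {
  if (!all(dim(stressed) == dim(relaxed)))
    stop("image pair must have identical dimensions")
  ny <- nrow(relaxed); nx <- ncol(relaxed)
  drift <- c(0, 0)
  if (register) {
    d <- window_displacement(relaxed, stressed)
    drift <- round(d[1:2])
    if (any(drift != 0)) stressed <- shift_image(stressed, -drift)
  }
  step <- max(4L, round(window * (1 - overlap)))
  cx <- seq(window / 2, nx - window / 2, by = step)
  cy <- seq(window / 2, ny - window / 2, by = step)
  if (length(cx) < 2L || length(cy) < 2L)
    stop("image too small for the requested correlation window")
  ux <- uy <- matrix(NA_real_, length(cy), length(cx))
  ok <- matrix(TRUE, length(cy), length(cx))
  for (a in seq_along(cy)) for (b in seq_along(cx)) {
    ii <- (round(cy[a] - window / 2) + 1):(round(cy[a] + window / 2))
    jj <- (round(cx[b] - window / 2) + 1):(round(cx[b] + window / 2))
    ii <- ii[ii >= 1 & ii <= ny]; jj <- jj[jj >= 1 & jj <= nx]
    d <- window_displacement(relaxed[ii, jj], stressed[ii, jj],
                             max_shift = window / 3)
    if (d[3] < peak_ratio_min) { ok[a, b] <- FALSE; next }
    ux[a, b] <- d[1]; uy[a, b] <- d[2]
  }
  n_masked <- sum(!ok)
  if (n_masked > 0) {
    ux <- fill_masked(ux); uy <- fill_masked(uy)
  }
  if (smooth_sigma > 0) {
    ux <- gauss_smooth(ux, smooth_sigma)
    uy <- gauss_smooth(uy, smooth_sigma)
  }
  structure(list(xs = cx * pixel_size, ys = cy * pixel_size,
                 ux = (ux + drift[1]) * pixel_size,
                 uy = (uy + drift[2]) * pixel_size,
                 spacing = step * pixel_size,
                 drift = drift, n_masked = n_masked),
            class = "displacement_field")
}

# integer-shift an image, zero padding the vacated margin
shift_image <- function(m, shift) {
  dx <- shift[1]; dy <- shift[2]
  out <- matrix(0, nrow(m), ncol(m))
  src_i <- max(1, 1 - dy):min(nrow(m), nrow(m) - dy)
  src_j <- max(1, 1 - dx):min(ncol(m), ncol(m) - dx)
  out[src_i + dy, src_j + dx] <- m[src_i, src_j]
  out
}

# replace NA entries by the mean of their finite 8-neighbourhood
# (iterated until filled)
fill_masked <- function(m) {
  while (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    filled_any <- FALSE
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      ii <- max(1, i - 1):min(nrow(m), i + 1)
      jj <- max(1, j - 1):min(ncol(m), j + 1)
      nb <- m[ii, jj]
      if (any(is.finite(nb))) {
        m[i, j] <- mean(nb, na.rm = TRUE)
        filled_any <- TRUE
      }
    }
    if (!filled_any) { m[is.na(m)] <- 0; break }
  }
  m
}

#' Recover tractions from a displacement field
#'
#' Tikhonov-regularized inversion of the Fourier-space Boussinesq
#' operator for a semi-infinite elastic substrate: per wavevector, the
#' 2x2 Green's tensor `G(k)` relating traction to surface displacement
#' is inverted as `t = (G'G + lambda^2 I)^-1 G' u`. With regularization
#' tending to zero this is the exact inverse of
#' [forward_displacement_field()]. The zero mode is set to zero (an
#' isolated layer exerts no net force).
#'
#' @param field A `displacement_field` (or any list with `ux`, `uy` in
#'   µm on a regular grid plus `spacing`).
#' @param gel A list with `shear_modulus` (Pa) and `poisson`, or an
#'   [imaging_config()].
#' @param lambda Tikhonov parameter, in units of the Green's operator
#'   norm (µm/Pa); 0 = unregularized.
#' @return The input list with `tx`, `ty` traction matrices (Pa) added,
#'   of class `traction_field`.
#' @export
compute_tractions <- function(field, gel = imaging_config(), lambda = 0) {
  if (is.null(field$ux) || is.null(field$uy))
    stop("'field' must carry 'ux' and 'uy' displacement matrices")
  if (!all(is.finite(field$ux)) || !all(is.finite(field$uy)))
    stop("displacement field contains non-finite values")
  if (is.null(field$spacing) || field$spacing <= 0)
    stop("grid spacing must be positive")
  G <- if (inherits(gel, "imaging_config")) gel$gel_shear_modulus
       else gel$shear_modulus
  nu <- if (inherits(gel, "imaging_config")) gel$gel_poisson
        else gel$poisson
  op <- traction_fourier_op(list(tx = field$ux, ty = field$uy,
                                 spacing = field$spacing), G, nu)
  ux_h <- stats::fft(field$ux); uy_h <- stats::fft(field$uy)
  # per-k symmetric 2x2 solve: t = (G^2 + l^2)^-1 G u
  a <- op$gxx; b <- op$gxy; c2 <- op$gyy
  # M = G'G + l^2 I  (G symmetric real)
  m11 <- a * a + b * b + lambda^2
  m12 <- b * (a + c2)
  m22 <- c2 * c2 + b * b + lambda^2
  det <- m11 * m22 - m12^2
  det[det == 0] <- Inf
  # rhs = G u
  r1 <- a * ux_h + b * uy_h
  r2 <- b * ux_h + c2 * uy_h
  tx_h <- (m22 * r1 - m12 * r2) / det
  ty_h <- (m11 * r2 - m12 * r1) / det
  tx_h[1, 1] <- 0; ty_h[1, 1] <- 0
  field$tx <- Re(stats::fft(tx_h, inverse = TRUE)) / length(tx_h)
  field$ty <- Re(stats::fft(ty_h, inverse = TRUE)) / length(ty_h)
  field$gel <- list(shear_modulus = G, poisson = nu)
  field$lambda <- lambda
  class(field) <- unique(c("traction_field", class(field)))
  field
}

#' Mean traction magnitude per cell footprint
#'
#' Averages the traction magnitude `|T|` over each cell's footprint.
#' Footprints may come from Voronoi polygons (preferred in a confluent
#' layer) or any label image co-registered to the traction grid. Cells
#' whose footprint covers less than one traction grid cell are flagged.
#'
#' @param field A `traction_field` (with `xs`, `ys`, `tx`, `ty`).
#' @param cells Data.frame with `cell_id` (or `cell`), `x`, `y` centroid
#'   positions in the same units as the field grid.
#' @param polygons Optional list of polygon vertex matrices (from
#'   [tessellate()]); if omitted, grid nodes are assigned to the nearest
#'   centroid (Voronoi assignment by construction).
#' @return Data.frame `cell_id`, `traction` (Pa, mean `|T|`),
#'   `n_nodes`, `qc_flag`.
#' @export
per_cell_traction <- function(field, cells, polygons = NULL) {
  mag <- sqrt(field$tx^2 + field$ty^2)
  gx <- rep(field$xs, each = length(field$ys))
  gy <- rep(field$ys, length(field$xs))
  id_col <- if ("cell_id" %in% names(cells)) "cell_id" else "cell"
  n <- nrow(cells)
  assign_idx <- if (is.null(polygons)) {
    # nearest-centroid assignment = Voronoi partition of the grid
    nearest <- apply(cbind(gx, gy), 1, function(pt)
      which.min((cells$x - pt[1])^2 + (cells$y - pt[2])^2))
    nearest
  } else {
    idx <- rep(NA_integer_, length(gx))
    for (i in seq_len(n)) {
      inside <- point_in_polygon(gx, gy, polygons[[i]])
      idx[inside & is.na(idx)] <- i
    }
    idx
  }
  out <- data.frame(cell_id = cells[[id_col]], traction = NA_real_,
                    n_nodes = 0L, qc_flag = "ok")
  for (i in seq_len(n)) {
    sel <- which(assign_idx == i)
    out$n_nodes[i] <- length(sel)
    if (length(sel) == 0L) {
      out$qc_flag[i] <- "footprint_below_grid"
    } else {
      out$traction[i] <- mean(mag[cbind(match(gy[sel], field$ys),
                                        match(gx[sel], field$xs))])
    }
  }
  out
}

# even-odd ray-casting point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
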