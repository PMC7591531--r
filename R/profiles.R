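#' Grid scattered per-cell values onto a regular lattice
#'
#' Linear (barycentric, Delaunay-based) interpolation of per-cell
#' scalar values onto a regular grid whose spacing matches typical cell
#' spacing in the dense layer (35 px at 0.325 µm/px, about 11 µm).
#' Grid nodes outside the convex hull of the cells are `NA`.
#'
#' @param cells Data.frame with `x`, `y` and the value column.
#' @param value Name of the column to grid.
#' @param grid_spacing Grid spacing, same units as `x`, `y`. Default
#'   `35 * 0.325` µm.
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   cell bounding box.
#' @return A list of class `gridded_field`: `xs`, `ys`, `values`
#'   (matrix, rows = y), `spacing`, `quantity`.
#' @export
grid_cell_values <- function(cells, value, grid_spacing = 35 * 0.325,
                             bounds = NULL) {
  stopifnot(grid_spacing > 0)
  if (!value %in% names(cells)) stop("no column '", value, "' in 'cells'")
  keep <- is.finite(cells$x) & is.finite(cells$y) &
    is.finite(cells[[value]])
  if (sum(keep) < 3L) stop("need at least 3 cells with finite values")
  cells <- cells[keep, ]
  if (is.null(bounds))
    bounds <- c(min(cells$x), max(cells$x), min(cells$y), max(cells$y))
  xs <- seq(bounds[1], bounds[2], by = grid_spacing)
  ys <- seq(bounds[3], bounds[4], by = grid_spacing)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, length(xs))
  z <- interp::interpp(cells$x, cells$y, cells[[value]],
                       xo = gx, yo = gy, duplicate = "mean")$z
  vals <- matrix(z, nrow = length(ys), ncol = length(xs))
  if (all(is.na(vals))) stop("interpolated field is entirely missing")
  structure(list(xs = xs, ys = ys, values = vals, spacing = grid_spacing,
                 quantity = value),
            class = "gridded_field")
}

#' Centre of mass of a layer
#'
#' The layer centre used for alignment: the mean x-position of the
#' cells (cell mode) or of the masked pixels (mask mode).
#'
#' @param x Either a numeric vector of cell x-positions, a data.frame
#'   with an `x` column, or a logical/0-1 mask matrix.
#' @param pixel_size For mask input, µm per pixel (mask columns are x).
#' @return Centre x-coordinate (µm, or input units for cell mode).
#' @export
layer_center <- function(x, pixel_size = 1) {
  if (is.matrix(x)) {
    sel <- which(x != 0, arr.ind = TRUE)
    if (nrow(sel) == 0L) stop("mask is empty")
    return(mean(sel[, 2] - 0.5) * pixel_size)
  }
  if (is.data.frame(x)) x <- x$x
  if (length(x) == 0L) stop("no positions supplied")
  mean(x)
}

#' Split a strip into two layers, fronts oriented toward +x
#'
#' An imaged strip spans the layer edge-to-edge and therefore contains
#' two advancing fronts; each half is treated as a separate layer. Both
#' halves are re-expressed in distance from the layer centre, with the
#' advancing front toward +x (the left half is mirrored).
#'
#' @param field A `gridded_field` (or list with `xs`, `ys`, `values`).
#' @param center Layer centre x (same units as `xs`); defaults to the
#'   value-weighted midpoint of the grid.
#' @return A list of two `gridded_field`s (`right`, `left`), each with
#'   `xs` measured from the centre, increasing toward its front.
#' @export
split_and_orient_fronts <- function(field, center = NULL) {
  xs <- field$xs
  if (is.null(center)) center <- mean(range(xs))
  if (center <= min(xs) || center >= max(xs))
    stop("layer centre lies outside the strip")
  right_sel <- xs >= center
  left_sel <- xs <= center
  right <- list(xs = xs[right_sel] - center, ys = field$ys,
                values = field$values[, right_sel, drop = FALSE],
                spacing = field$spacing, quantity = field$quantity)
  lx <- center - xs[left_sel]
  ord <- order(lx)
  left <- list(xs = lx[ord], ys = field$ys,
               values = field$values[, which(left_sel)[ord], drop = FALSE],
               spacing = field$spacing, quantity = field$quantity)
  class(right) <- class(left) <- "gridded_field"
  list(right = right, left = left)
}

#' Composite aligned layers into a mean map and x-profile trace
#'
#' Aligns every layer by its centre (already done if the fields come
#' from [split_and_orient_fronts()]), resamples onto a common grid by
#' nearest-node shift, averages pixel-by-pixel ignoring missing values,
#' and collapses the composite into an x-binned trace whose error bars
#' are the layer-to-layer standard deviation of per-layer bin means.
#'
#' @param fields List of `gridded_field`s on commensurate grids, each
#'   with `xs` already measured from its own layer centre.
#' @param bin_width Trace bin width along x (µm). Default 260.
#' @param min_layers_sd Bins with fewer contributing layers than this
#'   report `sd = NA`. Default 3 (but `sd = 0` is reported when all
#'   contributing layers agree exactly at fewer layers).
#' @return A list of class `layer_profile`: `map` (composited matrix),
#'   `map_xs`, `trace` (data.frame `x_center`, `mean`, `sd`,
#'   `n_layers`), `bin_width`, `quantity`.
#' @export
composite_layers <- function(fields, bin_width = 260, min_layers_sd = 2) {
  stopifnot(length(fields) >= 1L)
  spacing <- fields[[1]]$spacing
  # common x-axis: union of node positions snapped to the grid pitch
  snap <- function(f) round(f$xs / spacing)
  all_idx <- sort(unique(unlist(lapply(fields, snap))))
  map_xs <- all_idx * spacing
  nyl <- vapply(fields, function(f) length(f$ys), 1L)
  ny <- max(nyl)
  acc <- array(NA_real_, dim = c(ny, length(map_xs), length(fields)))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    cols <- match(snap(f), all_idx)
    acc[seq_len(nrow(f$values)), cols, k] <- f$values
  }
  map <- apply(acc, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  # per-layer y-collapsed x-binned means
  bins <- floor(map_xs / bin_width)
  ub <- sort(unique(bins))
  layer_bin <- matrix(NA_real_, length(fields), length(ub))
  for (k in seq_along(fields)) {
    prof <- colMeans(acc[, , k, drop = FALSE][, , 1, drop = FALSE],
                     na.rm = TRUE)
    for (b in seq_along(ub)) {
      v <- prof[bins == ub[b]]
      v <- v[is.finite(v)]
      if (length(v)) layer_bin[k, b] <- mean(v)
    }
  }
  n_layers <- colSums(is.finite(layer_bin))
  tr_mean <- ifelse(n_layers > 0, colMeans(layer_bin, na.rm = TRUE), NA)
  tr_sd <- apply(layer_bin, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(if (length(v) >= min_layers_sd) 0 else NA_real_)
    stats::sd(v)
  })
  trace <- data.frame(x_center = (ub + 0.5) * bin_width,
                      mean = tr_mean, sd = tr_sd, n_layers = n_layers)
  trace <- trace[trace$n_layers > 0, ]
  structure(list(map = map, map_xs = map_xs, trace = trace,
                 bin_width = bin_width,
                 quantity = fields[[1]]$quantity),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("Layer profile of '%s': %d bins of %g um\n",
              x$quantity %||% "?", nrow(x$trace), x$bin_width))
  print(utils::head(x$trace, 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area-normalize an uptake intensity profile
#'
#' Converts a per-pixel dye intensity profile (e.g. glucose-analogue
#' uptake) into a per-cell uptake index: intensity is referenced to the
#' layer-centre value of the confined (pre-lift) condition and
#' multiplied by the local mean cell area relative to the same
#' reference, so the trace reports uptake per cell rather than per
#' pixel.
#'
#' @param intensity Numeric vector of binned intensity means.
#' @param cell_area Numeric vector of binned mean cell areas on the
#'   same bins.
#' @param reference_intensity Pre-lift layer-centre intensity (> 0).
#' @param reference_area Cell area at the same reference (> 0).
#' @return Numeric vector: dimensionless per-cell uptake index; `NA`
#'   where the area bin is missing or non-positive.
#' @export
normalize_uptake_by_area <- function(intensity, cell_area,
                                     reference_intensity,
                                     reference_area) {
  if (length(intensity) != length(cell_area))
    stop("profiles must share bins")
  if (!is.finite(reference_intensity) || reference_intensity <= 0)
    stop("'reference_intensity' must be positive")
  if (!is.finite(reference_area) || reference_area <= 0)
    stop("'reference_area' must be positive")
  out <- (intensity / reference_intensity) * (cell_area / reference_area)
  out[!is.finite(cell_area) | cell_area <= 0] <- NA_real_
  out
}

#' Convert a fluorescence-ratio profile to a redox profile
#'
#' Applies the calibration transform bin-wise to a composited
#' fluorescence-ratio trace: the composite is built first in
#' fluorescence-ratio units and converted to NAD+/NADH afterwards, with
#' the symmetric fluorescence dispersion mapped through the nonlinear
#' transform into asymmetric redox error bars.
#'
#' @param profile A `layer_profile` whose trace is in normalized
#'   fluorescence-ratio units.
#' @param model A [peredox_calibration()].
#' @return The profile with trace columns `redox`, `redox_lo`,
#'   `redox_hi`, `clipped` appended (note the decreasing transform:
#'   `mean + sd` maps to `redox_lo`).
#' @export
transform_profile_to_redox <- function(profile, model = peredox_calibration()) {
  tr <- profile$trace
  pe <- propagate_error(tr$mean, ifelse(is.finite(tr$sd), tr$sd, 0), model)
  tr$redox <- pe$redox
  tr$redox_lo <- pe$lower
  tr$redox_hi <- pe$upper
  tr$clipped <- pe$clipped
  profile$trace <- tr
  profile$quantity <- paste0(profile$quantity, "_redox")
  profile
}

#' X-binned trace of an intensity image
#'
#' Collapses an image over y and bins along x, optionally restricted to
#' a mask; a light-weight path for dye-uptake images that never pass
#' through per-cell gridding.
#'
#' @param image Matrix (rows = y).
#' @param pixel_size µm per pixel.
#' @param bin_width Bin width (µm).
#' @param mask Optional logical matrix; only masked pixels contribute.
#' @return Data.frame `x_center`, `mean`, `n_pixels`.
#' @export
bin_image_profile <- function(image, pixel_size, bin_width = 260,
                              mask = NULL) {
  nx <- ncol(image)
  xs <- (seq_len(nx) - 0.5) * pixel_size
  bins <- floor(xs / bin_width)
  if (!is.null(mask)) image[!mask] <- NA
  colm <- colMeans(image, na.rm = TRUE)
  ub <- sort(unique(bins))
  out <- data.frame(x_center = (ub + 0.5) * bin_width,
                    mean = NA_real_, n_pixels = 0L)
  for (b in seq_along(ub)) {
    sel <- bins == ub[b]
    v <- colm[sel]
    out$mean[b] <- mean(v[is.finite(v)])
    out$n_pixels[b] <- sum(is.finite(image[, sel]))
  }
  out
}
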