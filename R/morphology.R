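#' Voronoi tessellation of nuclear centroids
#'
#' Partitions the domain so each point belongs to its nearest nuclear
#' centroid; in a confluent layer the Voronoi polygon is a proxy for the
#' cell footprint. Polygons are clipped to the rectangular domain, and
#' cells whose polygon touches the domain boundary (including the free
#' edge ahead of the advancing front) are flagged so they can be
#' excluded from shape statistics.
#'
#' @param centroids Data.frame or matrix with columns `x`, `y` (µm or
#'   px; metrics come out in the same units).
#' @param domain_bounds Numeric `c(xmin, xmax, ymin, ymax)` clipping
#'   rectangle; defaults to the bounding box of the centroids.
#' @param boundary_tol Distance (same units) within which a polygon
#'   vertex counts as touching the boundary.
#' @return A list of class `voronoi_cells`: `polygons` (list of
#'   two-column vertex matrices, one per centroid, counter-clockwise),
#'   `metrics` (data.frame `cell`, `x`, `y`, `area`, `perimeter`,
#'   `aspect_ratio`, `is_boundary`), `bounds`.
#' @export
tessellate <- function(centroids, domain_bounds = NULL,
                       boundary_tol = 1e-6) {
  centroids <- as.data.frame(centroids)
  if (!all(c("x", "y") %in% names(centroids)))
    stop("'centroids' needs columns 'x' and 'y'")
  n <- nrow(centroids)
  if (n < 3L) stop("need at least 3 centroids to tessellate")
  dup <- duplicated(round(cbind(centroids$x, centroids$y), 9))
  if (any(dup))
    stop("duplicate centroids at rows: ",
         paste(which(dup), collapse = ", "))
  if (is.null(domain_bounds))
    domain_bounds <- c(min(centroids$x), max(centroids$x),
                       min(centroids$y), max(centroids$y))
  dd <- deldir::deldir(centroids$x, centroids$y, rw = domain_bounds,
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  polys <- vector("list", n)
  met <- data.frame(cell = seq_len(n), x = centroids$x, y = centroids$y,
                    area = NA_real_, perimeter = NA_real_,
                    aspect_ratio = NA_real_, is_boundary = FALSE)
  for (i in seq_len(n)) {
    tl <- tiles[[i]]
    v <- cbind(x = tl$x, y = tl$y)
    polys[[i]] <- v
    m <- shape_metrics(v)
    met$area[i] <- m["area"]
    met$perimeter[i] <- m["perimeter"]
    met$aspect_ratio[i] <- m["aspect_ratio"]
    met$is_boundary[i] <-
      any(v[, 1] <= domain_bounds[1] + boundary_tol |
          v[, 1] >= domain_bounds[2] - boundary_tol |
          v[, 2] <= domain_bounds[3] + boundary_tol |
          v[, 2] >= domain_bounds[4] - boundary_tol)
  }
  structure(list(polygons = polys, metrics = met, bounds = domain_bounds),
            class = "voronoi_cells")
}

#' @export
print.voronoi_cells <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Voronoi tessellation: %d cells (%d interior)\n",
              nrow(m), sum(!m$is_boundary)))
  cat(sprintf("  interior area  %.3g +/- %.2g\n",
              mean(m$area[!m$is_boundary]), stats::sd(m$area[!m$is_boundary])))
  cat(sprintf("  interior AR    %.3g +/- %.2g\n",
              mean(m$aspect_ratio[!m$is_boundary]),
              stats::sd(m$aspect_ratio[!m$is_boundary])))
  invisible(x)
}

#' Area, perimeter and aspect ratio of a polygon
#'
#' Exact shoelace formulas for the area, perimeter and second central
#' moments of a simple polygon. The aspect ratio is the major/minor axis
#' ratio of the ellipse with the same second central moments as the
#' polygon (the usual region-property convention), so a 2x1 rectangle
#' has aspect ratio exactly 2 and any square exactly 1.
#'
#' @param vertices Two-column matrix of polygon vertices in order
#'   (either orientation; the polygon is not closed explicitly).
#' @return Named numeric vector `area`, `perimeter`, `aspect_ratio`,
#'   `orientation` (radians of the major axis). Degenerate (zero-area)
#'   polygons return `NA` metrics.
#' @export
shape_metrics <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L)
    return(c(area = NA, perimeter = NA, aspect_ratio = NA, orientation = NA))
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  A <- sum(cross) / 2
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  if (abs(A) < .Machine$double.eps * 100)
    return(c(area = 0, perimeter = per, aspect_ratio = NA, orientation = NA))
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  # second moments about the origin (standard polygon moment formulas)
  Ixx <- sum((y^2 + y * yn + yn^2) * cross) / 12
  Iyy <- sum((x^2 + x * xn + xn^2) * cross) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  # central, normalized by area -> covariance of the uniform lamina
  sxx <- Iyy / A - cx^2
  syy <- Ixx / A - cy^2
  sxy <- Ixy / A - cx * cy
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ar <- if (lam[2] > 0) sqrt(lam[1] / lam[2]) else Inf
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  c(area = abs(A), perimeter = per, aspect_ratio = ar, orientation = ang)
}

#' Append Voronoi morphometrics to a per-cell table
#'
#' Runs [tessellate()] on the centroid columns of a per-cell record
#' table and joins `area`, `perimeter`, `aspect_ratio`, `is_boundary`
#' back onto it.
#'
#' @param cells Data.frame with columns `x`, `y` (one row per cell).
#' @inheritParams tessellate
#' @return The input data.frame with morphology columns appended.
#' @export
add_morphology <- function(cells, domain_bounds = NULL) {
  vor <- tessellate(cells[, c("x", "y")], domain_bounds)
  cbind(cells, vor$metrics[, c("area", "perimeter", "aspect_ratio",
                               "is_boundary")])
}
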