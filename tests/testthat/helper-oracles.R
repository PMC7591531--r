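# Independent oracles and fixture builders shared across the suite.
# Every oracle here is a deliberately naive implementation, kept
# separate from the package's own algorithms.

# O(n^2) Voronoi areas by half-plane intersection: start from the
# bounding rectangle and clip with the perpendicular bisector against
# every other site (Sutherland-Hodgman).
voronoi_oracle <- function(x, y, bounds) {
  clip_halfplane <- function(poly, a, b, c) {
    # keep points with a*px + b*py <= c
    n <- nrow(poly)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
      fp <- a * p[1] + b * p[2] - c
      fq <- a * q[1] + b * q[2] - c
      if (fp <= 0) out <- rbind(out, p)
      if ((fp < 0) != (fq < 0)) {
        t <- fp / (fp - fq)
        out <- rbind(out, p + t * (q - p))
      }
    }
    out
  }
  rect <- rbind(c(bounds[1], bounds[3]), c(bounds[2], bounds[3]),
                c(bounds[2], bounds[4]), c(bounds[1], bounds[4]))
  n <- length(x)
  areas <- numeric(n)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    for (j in seq_len(n)) {
      if (i == j || nrow(poly) == 0) next
      # bisector: points closer to i than j
      a <- 2 * (x[j] - x[i]); b <- 2 * (y[j] - y[i])
      c <- x[j]^2 - x[i]^2 + y[j]^2 - y[i]^2
      poly <- clip_halfplane(poly, a, b, c)
    }
    polys[[i]] <- poly
    areas[i] <- if (nrow(poly) >= 3) shoelace_area(poly) else 0
  }
  list(areas = areas, polygons = polys)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Dense-rasterization moment oracle for polygon shape metrics.
raster_shape_oracle <- function(vertices, resolution = 400) {
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  pad <- 0.05 * max(diff(xr), diff(yr))
  xs <- seq(xr[1] - pad, xr[2] + pad, length.out = resolution)
  ys <- seq(yr[1] - pad, yr[2] + pad, length.out = resolution)
  px <- rep(xs, each = length(ys)); py <- rep(ys, length(xs))
  inside <- mechanometab:::point_in_polygon(px, py, vertices)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  A <- sum(inside) * dx * dy
  cx <- mean(px[inside]); cy <- mean(py[inside])
  sxx <- mean((px[inside] - cx)^2)
  syy <- mean((py[inside] - cy)^2)
  sxy <- mean((px[inside] - cx) * (py[inside] - cy))
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE)$values
  list(area = A, aspect_ratio = sqrt(max(ev) / min(ev)))
}

# Real-space Boussinesq surface displacement of a tangential point
# force (incompressible half-space), used to sanity-check the Fourier
# forward operator's shape.
boussinesq_point <- function(fx, x, y, G) {
  r <- sqrt(x^2 + y^2)
  ux <- fx / (4 * pi * G * r) * (1 + x^2 / r^2)
  uy <- fx * x * y / (4 * pi * G * r^3)
  cbind(ux, uy)
}

# Non-overlapping random spot fixture for detection tests: jittered
# grid placement guarantees the minimum separation without rejection
# sampling.
make_spot_fixture <- function(n = 50, nx = 300, ny = 200, min_sep = 15,
                              sigma = 3, seed = 1) {
  set.seed(seed)
  g <- min_sep * 1.35
  jit <- (g - min_sep) / 2
  gx <- seq(min_sep, nx - min_sep, by = g)
  gy <- seq(min_sep, ny - min_sep, by = g)
  grid <- expand.grid(x = gx, y = gy)
  stopifnot(nrow(grid) >= n)
  pick <- grid[sample(nrow(grid), n), ]
  x <- pick$x + stats::runif(n, -jit, jit)
  y <- pick$y + stats::runif(n, -jit, jit)
  amp <- stats::runif(n, 100, 300)
  list(x = x, y = y, amp = amp,
       image = mechanometab:::render_gaussian_spots(nx, ny, x, y, amp,
                                                    sigma))
}

# Small, fast monolayer world reused by several module tests.
small_world <- function(seed = 1) {
  simulate_monolayer(monolayer_params(Lx = 400, Ly = 120, front0 = 250,
                                      n_frames = 4), seed = seed)
}
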