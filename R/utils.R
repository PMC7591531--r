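# Shared numerical helpers: blob rendering, Gaussian smoothing, FFT
# frequency grids, bilinear interpolation, sub-pixel peak refinement.

# Render 2D Gaussian spots into an ny x nx image (row = y, col = x).
# Positions are in pixel units (1-based, pixel centres at integers).
# Each spot is drawn only inside a +/- 4 sigma window for speed.
render_gaussian_spots <- function(nx, ny, x, y, amplitude, sigma) {
  stopifnot(length(x) == length(y))
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, length(x))
  img <- matrix(0, nrow = ny, ncol = nx)
  w <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    j1 <- max(1L, floor(cx - w)); j2 <- min(nx, ceiling(cx + w))
    i1 <- max(1L, floor(cy - w)); i2 <- min(ny, ceiling(cy + w))
    if (j1 > j2 || i1 > i2) next
    gx <- exp(-((j1:j2) - cx)^2 / (2 * sigma^2))
    gy <- exp(-((i1:i2) - cy)^2 / (2 * sigma^2))
    img[i1:i2, j1:j2] <- img[i1:i2, j1:j2] + amplitude[i] * outer(gy, gx)
  }
  img
}

# Separable Gaussian smoothing with replicate padding (kernel +/-3 sigma).
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_rows <- function(m) rbind(m[rep(1L, r), , drop = FALSE], m,
                                m[rep(nrow(m), r), , drop = FALSE])
  smooth_cols <- function(m) {
    f <- stats::filter(pad_rows(m), k, sides = 2)
    f[(r + 1L):(r + nrow(m)), , drop = FALSE]
  }
  t(smooth_cols(t(smooth_cols(img))))
}

# FFT sample frequencies (cycles per unit), matching the usual fftfreq.
fft_freq <- function(n, d = 1) {
  c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / (n * d)
}

# Bilinear interpolation of matrix `m` (rows = y grid `ys`, cols = x grid
# `xs`, both ascending regular) at scattered points; clamped at edges.
bilinear_interp <- function(m, xs, ys, xq, yq) {
  nx <- length(xs); ny <- length(ys)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  fx <- (xq - xs[1]) / dx; fy <- (yq - ys[1]) / dy
  j <- pmin(pmax(floor(fx), 0), nx - 2); i <- pmin(pmax(floor(fy), 0), ny - 2)
  tx <- pmin(pmax(fx - j, 0), 1); ty <- pmin(pmax(fy - i, 0), 1)
  i <- i + 1L; j <- j + 1L   # to 1-based corner indices
  m[cbind(i, j)] * (1 - tx) * (1 - ty) +
    m[cbind(i, j + 1L)] * tx * (1 - ty) +
    m[cbind(i + 1L, j)] * (1 - tx) * ty +
    m[cbind(i + 1L, j + 1L)] * tx * ty
}

# FFT-based *linear* cross-correlation of two equally sized windows
# (mean subtracted, zero padded to twice the size so nothing wraps),
# normalized by the per-lag overlap area so broad peaks are not biased
# toward zero lag. Zero lag sits at the centre element
# (floor(n/2)+1) of the returned n x n surface.
xcorr2 <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  pa <- matrix(0, 2 * nr, 2 * nc); pb <- pa
  pa[1:nr, 1:nc] <- a - mean(a)
  pb[1:nr, 1:nc] <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb),
                      inverse = TRUE)) / length(pa)
  lag_r <- seq_len(nr) - (floor(nr / 2) + 1L)
  lag_c <- seq_len(nc) - (floor(nc / 2) + 1L)
  idx_r <- (lag_r %% (2 * nr)) + 1L
  idx_c <- (lag_c %% (2 * nc)) + 1L
  overlap <- outer(nr - abs(lag_r), nc - abs(lag_c))
  cc[idx_r, idx_c] / pmax(overlap, 1)
}

# Parabolic three-point sub-pixel refinement around an integer peak.
parabolic_subpixel <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den == 0) return(0)
  d <- 0.5 * (ym1 - yp1) / den
  max(min(d, 1), -1)
}

# Displacement of window `b` relative to `a` (how far a's content moved
# to become b), via the cross-correlation peak with sub-pixel fit.
# Returns c(dx, dy, peak_ratio).
window_displacement <- function(a, b, max_shift = Inf) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(c(0, 0, 0))
  cc <- xcorr2(a, b)
  c0r <- floor(nrow(cc) / 2) + 1L; c0c <- floor(ncol(cc) / 2) + 1L
  if (is.finite(max_shift)) {
    keep_r <- abs(seq_len(nrow(cc)) - c0r) <= max_shift
    keep_c <- abs(seq_len(ncol(cc)) - c0c) <= max_shift
    cc[!keep_r, ] <- -Inf; cc[, !keep_c] <- -Inf
  }
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  pr <- pk[1]; pc <- pk[2]
  dy <- pr - c0r; dx <- pc - c0c
  if (pr > 1 && pr < nrow(cc))
    dy <- dy + parabolic_subpixel(cc[pr - 1, pc], cc[pr, pc], cc[pr + 1, pc])
  if (pc > 1 && pc < ncol(cc))
    dx <- dx + parabolic_subpixel(cc[pr, pc - 1], cc[pr, pc], cc[pr, pc + 1])
  # decisiveness: main peak vs the highest secondary peak outside a
  # 3-px exclusion zone (adjacent samples of a broad peak are not
  # competitors)
  excl <- 3L
  rr <- max(1, pr - excl):min(nrow(cc), pr + excl)
  rc <- max(1, pc - excl):min(ncol(cc), pc + excl)
  rest <- cc
  rest[rr, rc] <- -Inf
  second <- max(rest[is.finite(rest)], -Inf)
  ratio <- if (is.finite(second) && second > 0) cc[pr, pc] / second else Inf
  c(dx = dx, dy = dy, peak_ratio = ratio)
}
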