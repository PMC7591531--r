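#' Detect nuclei in a single fluorescence channel
#'
#' Band-pass (difference-of-Gaussians) blob detection followed by
#' nearest-peak pixel assignment. The detection threshold is applied to
#' the band-pass response relative to its own maximum, never to raw
#' intensity, so dim but well-formed nuclei are found and uneven
#' illumination does not bias detection. Centroids are refined to
#' sub-pixel precision by intensity-weighted averaging of the smoothed
#' image around each peak.
#'
#' @param image Single-channel 2D numeric matrix (rows = y).
#' @param sigma Expected nucleus scale in pixels (blob sigma).
#' @param threshold Peak acceptance threshold as a fraction of the
#'   maximum band-pass response.
#' @param min_separation Minimum peak separation in pixels (default
#'   `2 * sigma`).
#' @return A list with `detections` (data.frame `id`, `x`, `y`,
#'   `response`) and `labels` (integer matrix assigning pixels near a
#'   peak to that detection).
#' @export
detect_nuclei <- function(image, sigma = 3, threshold = 0.1,
                          min_separation = 2 * sigma) {
  if (length(dim(image)) != 2L) stop("'image' must be a 2D matrix")
  empty <- list(detections = data.frame(id = integer(), x = numeric(),
                                        y = numeric(), response = numeric()),
                labels = matrix(0L, nrow(image), ncol(image)))
  if (all(image == image[1])) return(empty)
  # band-pass at a scale finer than the nucleus, so touching blobs keep
  # separate response maxima down to about two blob sigmas apart
  s1 <- max(1, 0.6 * sigma)
  band <- gauss_smooth(image, s1) - gauss_smooth(image, 1.6 * s1)
  peaks <- local_maxima(band, radius = max(1L, floor(min_separation / 2)),
                        min_value = threshold * max(band))
  if (nrow(peaks) == 0L) return(empty)
  # sub-pixel refinement: 3x3 parabolic fit on the band-pass peak
  ny <- nrow(image); nx <- ncol(image)
  xs <- ys <- numeric(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    i0 <- peaks$row[k]; j0 <- peaks$col[k]
    dx <- dy <- 0
    if (j0 > 1 && j0 < nx)
      dx <- parabolic_subpixel(band[i0, j0 - 1], band[i0, j0],
                               band[i0, j0 + 1])
    if (i0 > 1 && i0 < ny)
      dy <- parabolic_subpixel(band[i0 - 1, j0], band[i0, j0],
                               band[i0 + 1, j0])
    xs[k] <- j0 + dx
    ys[k] <- i0 + dy
  }
  det <- data.frame(id = seq_len(nrow(peaks)), x = xs, y = ys,
                    response = peaks$value)
  labels <- label_nearest_nucleus(nx, ny, det$x, det$y,
                                  radius = 2 * sigma)
  list(detections = det, labels = labels)
}

# Local maxima of a matrix: strictly the largest value in a
# (2r+1)^2 neighbourhood and above `min_value`.
local_maxima <- function(m, radius = 1L, min_value = -Inf) {
  ny <- nrow(m); nx <- ncol(m)
  # dilation by shifting over the neighbourhood
  dil <- matrix(-Inf, ny, nx)
  for (di in -radius:radius) for (dj in -radius:radius) {
    if (di == 0 && dj == 0) next
    src_i <- max(1, 1 - di):min(ny, ny - di)
    src_j <- max(1, 1 - dj):min(nx, nx - dj)
    dil[src_i, src_j] <- pmax(dil[src_i, src_j],
                              m[src_i + di, src_j + dj])
  }
  idx <- which(m > dil & m >= min_value, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], value = m[idx])
}

#' Dense optical flow between two frames
#'
#' Multi-scale block cross-correlation with parabolic sub-pixel peak
#' refinement: the displacement of each window of `frame_a` that best
#' explains `frame_b` is estimated on a coarse grid and bilinearly
#' interpolated to every pixel. Identical frames yield an exactly zero
#' field.
#'
#' @param frame_a,frame_b Same-shape 2D matrices (earlier, later frame).
#' @param window Window size in pixels.
#' @param overlap Fractional window overlap (0.5 = half-overlapping).
#' @param max_shift Largest trusted displacement in pixels.
#' @return A list with `vx`, `vy` (per-pixel displacement matrices,
#'   frame_a -> frame_b) and the window-grid versions `grid_x`,
#'   `grid_y`, `gvx`, `gvy`.
#' @export
estimate_flow <- function(frame_a, frame_b, window = 32L, overlap = 0.5,
                          max_shift = window / 3) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have identical dimensions")
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  if (identical(frame_a, frame_b)) {
    z <- matrix(0, ny, nx)
    return(list(vx = z, vy = z))
  }
  window <- min(window, 2^floor(log2(min(nx, ny))))
  step <- max(4L, round(window * (1 - overlap)))
  cx <- seq(window / 2, nx - window / 2, by = step)
  cy <- seq(window / 2, ny - window / 2, by = step)
  if (length(cx) < 2L || length(cy) < 2L) {
    # frame too small for a grid: single global estimate
    d <- window_displacement(frame_a, frame_b, max_shift = max_shift)
    return(list(vx = matrix(d[1], ny, nx), vy = matrix(d[2], ny, nx)))
  }
  gvx <- gvy <- matrix(0, length(cy), length(cx))
  for (a in seq_along(cy)) for (b in seq_along(cx)) {
    ii <- (round(cy[a] - window / 2) + 1):(round(cy[a] + window / 2))
    jj <- (round(cx[b] - window / 2) + 1):(round(cx[b] + window / 2))
    ii <- ii[ii >= 1 & ii <= ny]; jj <- jj[jj >= 1 & jj <= nx]
    d <- window_displacement(frame_a[ii, jj], frame_b[ii, jj],
                             max_shift = max_shift)
    gvx[a, b] <- d[1]; gvy[a, b] <- d[2]
  }
  px <- seq_len(nx); py <- seq_len(ny)
  vx <- outer(py, px, function(yy, xx)
    bilinear_interp(gvx, cx, cy, xx, yy))
  vy <- outer(py, px, function(yy, xx)
    bilinear_interp(gvy, cx, cy, xx, yy))
  list(vx = vx, vy = vy, grid_x = cx, grid_y = cy, gvx = gvx, gvy = gvy)
}

#' Link per-frame detections into trajectories
#'
#' Flow-assisted frame-to-frame linking: each open track's next position
#' is predicted by advecting its last detection with the optical flow,
#' and predictions are matched to candidate detections by optimal
#' (Hungarian) assignment of the prediction-to-candidate distances under
#' a gating radius. Unmatched detections open new tracks; unmatched
#' tracks terminate (no gap closing). This mirrors tracking with dynamic
#' segmentation: overlapping or ambiguous nuclei are disambiguated by
#' their position history plus the flow-interpolated prediction.
#'
#' @param detections_by_frame List (one element per frame) of detection
#'   data.frames with columns `x`, `y`.
#' @param flows Optional list of flow fields (length `n_frames - 1`), as
#'   returned by [estimate_flow()]; `NULL` disables flow prediction.
#' @param gate Gating radius in pixels: candidate matches farther than
#'   this from the prediction are forbidden.
#' @return A data.frame with columns `track_id`, `frame`, `x`, `y`,
#'   `detection_id`.
#' @export
link_tracks <- function(detections_by_frame, flows = NULL, gate = 15) {
  n_frames <- length(detections_by_frame)
  if (n_frames < 2L) stop("need at least 2 frames to link")
  d1 <- detections_by_frame[[1]]
  tracks <- data.frame(track_id = seq_len(nrow(d1)), frame = 1L,
                       x = d1$x, y = d1$y,
                       detection_id = seq_len(nrow(d1)))
  open <- data.frame(track_id = seq_len(nrow(d1)), x = d1$x, y = d1$y)
  next_id <- nrow(d1) + 1L
  for (f in seq_len(n_frames - 1L)) {
    det <- detections_by_frame[[f + 1L]]
    nd <- nrow(det); nt <- nrow(open)
    # flow-advected predictions of every open track
    pred <- open
    if (!is.null(flows) && nt > 0) {
      fl <- flows[[f]]
      xi <- pmin(pmax(round(open$x), 1), ncol(fl$vx))
      yi <- pmin(pmax(round(open$y), 1), nrow(fl$vx))
      pred$x <- open$x + fl$vx[cbind(yi, xi)]
      pred$y <- open$y + fl$vy[cbind(yi, xi)]
    }
    assigned_det <- integer(0)
    new_open <- list()
    if (nt > 0 && nd > 0) {
      cost <- outer(seq_len(nt), seq_len(nd), function(a, b)
        sqrt((pred$x[a] - det$x[b])^2 + (pred$y[a] - det$y[b])^2))
      match <- gated_assignment(cost, gate)
      for (a in seq_len(nt)) {
        b <- match[a]
        if (is.na(b)) next
        assigned_det <- c(assigned_det, b)
        tracks <- rbind(tracks, data.frame(
          track_id = open$track_id[a], frame = f + 1L,
          x = det$x[b], y = det$y[b], detection_id = b))
        new_open[[length(new_open) + 1L]] <-
          data.frame(track_id = open$track_id[a], x = det$x[b], y = det$y[b])
      }
    }
    if (nd > 0) {
      for (b in setdiff(seq_len(nd), assigned_det)) {
        tracks <- rbind(tracks, data.frame(
          track_id = next_id, frame = f + 1L,
          x = det$x[b], y = det$y[b], detection_id = b))
        new_open[[length(new_open) + 1L]] <-
          data.frame(track_id = next_id, x = det$x[b], y = det$y[b])
        next_id <- next_id + 1L
      }
    }
    open <- if (length(new_open)) do.call(rbind, new_open)
            else open[0, ]
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  tracks
}

# Optimal assignment of rows (tracks) to columns (detections) under a
# gating radius. Returns, per row, the matched column or NA. Pairs
# beyond the gate are given a prohibitive cost and post-filtered.
gated_assignment <- function(cost, gate) {
  nt <- nrow(cost); nd <- ncol(cost)
  big <- max(gate * 1e3, 1e6)
  padded <- matrix(big, max(nt, nd), max(nt, nd))
  padded[seq_len(nt), seq_len(nd)] <- pmin(cost, big)
  padded[seq_len(nt), seq_len(nd)][cost > gate] <- big
  sol <- clue::solve_LSAP(padded)
  match <- rep(NA_integer_, nt)
  for (a in seq_len(nt)) {
    b <- sol[a]
    if (b <= nd && cost[a, b] <= gate) match[a] <- b
  }
  match
}

#' Per-track migration speed
#'
#' Speed is the mean over consecutive frame pairs of the displacement
#' magnitude, converted to µm/h: the magnitude of the velocity vector
#' only, with no directional averaging (so a cell wiggling in place
#' still has positive speed). Tracks with fewer than two detections have
#' undefined speed and are flagged.
#'
#' @param tracks Data.frame from [link_tracks()] (`track_id`, `frame`,
#'   `x`, `y` in pixels).
#' @param frame_interval Minutes between frames.
#' @param pixel_size µm per pixel.
#' @return A data.frame `track_id`, `n_frames`, `speed` (µm/h; `NA` for
#'   single-detection tracks), `net_displacement` (µm).
#' @export
compute_speeds <- function(tracks, frame_interval = 15, pixel_size = 0.325) {
  stopifnot(frame_interval > 0, pixel_size > 0)
  dt_h <- frame_interval / 60
  ids <- unique(tracks$track_id)
  out <- data.frame(track_id = ids, n_frames = NA_integer_,
                    speed = NA_real_, net_displacement = NA_real_)
  for (k in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[k], ]
    tr <- tr[order(tr$frame), ]
    out$n_frames[k] <- nrow(tr)
    if (nrow(tr) < 2L) next
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) * pixel_size
    dframes <- diff(tr$frame)
    out$speed[k] <- mean(steps / (dframes * dt_h))
    out$net_displacement[k] <-
      sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2) *
      pixel_size
  }
  out
}

#' Track nuclei across a rendered frame sequence
#'
#' Convenience wrapper: detects nuclei in every frame of the red
#' channel, estimates frame-to-frame optical flow, links detections
#' into tracks, and computes speeds.
#'
#' @param frames List of single-channel matrices (the mCherry channel).
#' @param frame_interval Minutes between frames.
#' @param pixel_size µm per pixel.
#' @param sigma Nucleus blob scale in pixels.
#' @param gate Linking gate radius in pixels.
#' @return A list with `tracks`, `speeds`, `detections` (per frame).
#' @export
track_nuclei <- function(frames, frame_interval = 15, pixel_size = 0.325,
                         sigma = 3, gate = 15) {
  dets <- lapply(frames, function(f) detect_nuclei(f, sigma = sigma))
  det_list <- lapply(dets, `[[`, "detections")
  flows <- NULL
  if (length(frames) > 1L)
    flows <- lapply(seq_len(length(frames) - 1L), function(i)
      estimate_flow(frames[[i]], frames[[i + 1L]]))
  tracks <- link_tracks(det_list, flows, gate = gate)
  speeds <- compute_speeds(tracks, frame_interval, pixel_size)
  list(tracks = tracks, speeds = speeds, detections = dets)
}
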