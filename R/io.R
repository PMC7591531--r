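#' Write an image stack as plain-text frames with a JSON sidecar
#'
#' Portable text interchange for image sequences: each frame/channel is
#' a tab-separated matrix (`<base>_f<frame>.tsv`) and a JSON sidecar
#' (`<base>.json`) records the acquisition metadata (µm/pixel, frame
#' interval, frame count). Integer data round-trips exactly.
#'
#' @param frames A matrix or list of matrices.
#' @param base Path base (no extension).
#' @param pixel_size µm per pixel (required metadata).
#' @param frame_interval Minutes between frames (`NA` for snapshots).
#' @return Invisibly, the sidecar path.
#' @export
write_image_stack <- function(frames, base, pixel_size,
                              frame_interval = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  if (missing(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
    stop("metadata 'pixel_size' (um/pixel) is required and must be positive")
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    paths[k] <- sprintf("%s_f%03d.tsv", base, k)
    utils::write.table(frames[[k]], paths[k], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  sidecar <- paste0(base, ".json")
  jsonlite::write_json(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         n_frames = length(frames),
         dim = dim(frames[[1]]), files = basename(paths)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param base Path base used at write time (or the sidecar path).
#' @return A list with `frames` (list of matrices), `pixel_size`,
#'   `frame_interval`.
#' @export
read_image_stack <- function(base) {
  sidecar <- if (grepl("\\.json$", base)) base else paste0(base, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar '", sidecar,
         "': pixel_size cannot be defaulted silently")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size))
    stop("sidecar lacks required key 'pixel_size'")
  dir <- dirname(sidecar)
  frames <- lapply(file.path(dir, meta$files), function(p)
    as.matrix(utils::read.table(p, sep = "\t")))
  frames <- lapply(frames, function(m) {
    dimnames(m) <- NULL
    m
  })
  list(frames = frames, pixel_size = meta$pixel_size,
       frame_interval = meta$frame_interval)
}

#' Run the full synthetic mechano-metabolic pipeline
#'
#' Executes every stage in dependency order on a freshly simulated
#' monolayer: simulate ground truth, render the two Peredox channels,
#' track nuclei and compute speeds, tessellate for morphology, convert
#' per-cell ratios to redox, reconstruct tractions from a rendered bead
#' pair, fit the synthetic FLIM field, and build layer profiles. All
#' seeds derive from the single `seed` argument, so two runs with the
#' same configuration are identical.
#'
#' @param params A [monolayer_params()] object.
#' @param config An [imaging_config()].
#' @param calib A [peredox_calibration()].
#' @param seed Integer master seed.
#' @param pixel_size Rendering pixel size (µm/px) for the widefield
#'   channels; coarser than the instrument default keeps synthetic runs
#'   desk-sized.
#' @param bead_pixel_size Rendering pixel size of the bead channel,
#'   which benefits from finer sampling than the nuclei channels.
#' @param flim Logical: run the (slower) per-pixel FLIM fitting stage.
#' @param flim_photons Photon budget per FLIM pixel.
#' @param flim_pixel_size µm per FLIM pixel.
#' @param traction_lambda Tikhonov parameter of the traction inversion.
#' @param out_dir Optional directory; when given, per-cell tables and a
#'   JSON run manifest are written there.
#' @return A list of class `pipeline_run`: `truth`, `cells` (measured
#'   per-cell table: position, speed, morphology, F_raw, redox,
#'   traction), `tracks`, `flim` (fitted maps or `NULL`),
#'   `traction_field`, `manifest`.
#' @export
run_pipeline <- function(params = monolayer_params(),
                         config = imaging_config(),
                         calib = peredox_calibration(),
                         seed = 1L, pixel_size = 1.0,
                         bead_pixel_size = 0.5,
                         flim = FALSE, flim_photons = 5000,
                         flim_pixel_size = 25,
                         traction_lambda = 1e-3, out_dir = NULL) {
  t0 <- Sys.time()
  truth <- simulate_monolayer(params, seed = seed)
  rendered <- render_peredox_frames(truth, calib, pixel_size = pixel_size,
                                    seed = seed + 1L)

  # --- tracking & speeds -------------------------------------------
  trk <- track_nuclei(rendered$red, frame_interval = params$frame_interval,
                      pixel_size = pixel_size,
                      gate = max(10, 2 * params$v_edge *
                                   params$frame_interval / 60 / pixel_size))
  speeds <- trk$speeds

  # --- per-cell ratio & redox on frame 1 ---------------------------
  det1 <- trk$detections[[1]]
  ratios <- per_cell_ratio(rendered$red[[1]], rendered$green[[1]],
                           det1$labels)
  cells <- data.frame(cell_id = det1$detections$id,
                      x = det1$detections$x * pixel_size,
                      y = det1$detections$y * pixel_size)
  cells$F_raw <- ratios$F_raw[match(cells$cell_id, ratios$label)]
  redox <- fluorescence_to_redox(cells$F_raw, calib)
  cells$redox <- as.numeric(redox)
  cells$redox_clipped <- attr(redox, "clipped")

  # --- morphology ---------------------------------------------------
  cells <- add_morphology(cells, domain_bounds = c(0, params$Lx,
                                                   0, params$Ly))

  # link measured frame-1 detections to track speeds (track ids start
  # from frame-1 detection ids by construction)
  sp <- speeds$speed[match(cells$cell_id, speeds$track_id)]
  cells$speed <- sp

  # --- traction -----------------------------------------------------
  fwd <- forward_displacement_field(truth$traction, config)
  beads <- render_bead_images(fwd, pixel_size = bead_pixel_size,
                              seed = seed + 2L)
  meas <- measure_bead_displacements(beads$stressed, beads$relaxed,
                                     pixel_size = bead_pixel_size,
                                     register = FALSE)
  tfield <- compute_tractions(meas, config, lambda = traction_lambda)
  pct <- per_cell_traction(tfield, cells)
  cells$traction <- pct$traction[match(cells$cell_id, pct$cell_id)]

  # --- FLIM ---------------------------------------------------------
  flim_maps <- NULL
  if (flim) {
    stack <- synthesize_flim_stack(truth, config,
                                   photons_per_pixel = flim_photons,
                                   pixel_size = flim_pixel_size,
                                   seed = seed + 3L)
    binned <- bin_decays(stack$counts, spatial_radius = 2L,
                         temporal_factor = 4L)
    flim_maps <- fit_flim_field(binned, stack$irf, stack$bin_width * 4,
                                restarts = 3L, seed = seed + 4L)
    flim_maps$truth_tau_m <- stack$tau_m_map
  }

  manifest <- list(
    package = "mechanometab",
    seed = seed,
    stage_seeds = list(simulate = seed, render = seed + 1L,
                       beads = seed + 2L, flim = seed + 3L,
                       flim_fit = seed + 4L),
    params = unclass(params), config = unclass(config),
    calibration = unclass(calib)[c("A", "B", "hill", "K", "pH")],
    pixel_size = pixel_size,
    n_cells_truth = nrow(truth$cells),
    n_cells_detected = nrow(cells),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(trk$tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    manifest$outputs <- c("cells.csv", "tracks.csv")
    manifest$output_md5 <- as.list(tools::md5sum(
      file.path(out_dir, manifest$outputs)))
    names(manifest$output_md5) <- manifest$outputs
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(truth = truth, cells = cells, tracks = trk$tracks,
                 flim = flim_maps, traction_field = tfield,
                 rendered = rendered, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d/%d cells detected\n",
              x$manifest$seed, x$manifest$n_cells_detected,
              x$manifest$n_cells_truth))
  cat(sprintf("  elapsed %.1f s\n", x$manifest$elapsed_s))
  invisible(x)
}
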