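# Pipeline verbs gluing the modules together: simulate an acquisition from a
# phantom config, retrieve contrast maps from a frame stack, reconstruct
# retrieved sinograms.  Each verb is callable programmatically and exposed
# through the thin command-line wrapper in inst/cli/eidark.

default_ic_positions <- function(p, n = 9L, half_span_um = 13.5) {
  # n points symmetric about the curve peak; the default half-span is 1.5
  # reference standard deviations for the laboratory preset (sigma_r = 9 um)
  p$x0 + seq(-half_span_um, half_span_um, length.out = n)
}

signals_from_config <- function(cfg, g) {
  ph <- cfg$phantom
  if (is.null(ph$type)) stop("config$phantom$type is required")
  acq <- cfg$acquisition
  n_dither <- if (is.null(acq$n_dither)) 1L else as.integer(acq$n_dither)
  if (identical(ph$type, "wedge")) {
    m <- material_preset(ph$material)
    n_columns <- as.integer(ph$n_columns %||% 128L)
    x_extent_mm <- ph$x_extent_mm %||% 16
    s <- make_wedge(m,
                    x_extent_mm = x_extent_mm,
                    max_thickness_mm = ph$max_thickness_mm %||% 16,
                    n_columns = n_columns,
                    n_rows = as.integer(ph$n_rows %||% 1L),
                    g = g)
    list(signals = list(s), angles = 0, n_dither = n_dither,
         truth = s, material = m,
         fine_pitch_um = x_extent_mm * 1000 / n_columns)
  } else if (identical(ph$type, "cylinder")) {
    m <- material_preset(ph$material)
    grid <- as.integer(ph$grid %||% 128L)
    vox <- make_cylinder(m, radius_mm = ph$radius_mm %||% 20,
                         grid = grid,
                         fov_mm = ph$fov_mm %||% (2.5 * (ph$radius_mm %||% 20)))
    n_angles <- as.integer(acq$n_angles %||% 64L)
    arc <- acq$angular_range_deg %||% 180
    angles <- seq(0, arc, length.out = n_angles + 1L)[seq_len(n_angles)]
    sig <- lapply(angles, function(a) line_integrals(vox, a, g))
    list(signals = sig, angles = angles, n_dither = n_dither,
         truth = sig[[1]], material = m, phantom = vox,
         fine_pitch_um = vox$voxel_pitch_um)
  } else {
    stop("unknown phantom type '", ph$type,
         "'; available presets: wedge, cylinder")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an acquisition from a run configuration
#'
#' Builds the phantom named in `config$phantom`, forward-projects it at the
#' configured angles, simulates the frame stack and, when `out_dir` is
#' given, writes the stack, the ground-truth signal maps of the first angle
#' and a manifest JSON carrying the config hash and seed.
#'
#' @param config a [read_run_config()] object or plain list.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return A list with `stack` (a `frame_stack`), `truth` (ground-truth
#'   [sample_signals()] of the first angle), `angles_deg`, `material` and
#'   `manifest`.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  g <- geometry_from_config(cfg$geometry)
  p <- do.call(ic_params, cfg$ic %||% list())
  acq <- cfg$acquisition %||% list()
  world <- signals_from_config(cfg, g)
  ic_positions <- acq$ic_positions %||% default_ic_positions(p)
  stack <- simulate_frames(world$signals, p,
                           ic_positions = ic_positions,
                           n_dither = world$n_dither,
                           noise = acq$noise %||% "none",
                           seed = acq$seed,
                           exposure_scale = acq$exposure_scale %||% 1,
                           angles_deg = world$angles)
  stack$fine_pitch_um <- world$fine_pitch_um
  manifest <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                   seed = acq$seed, n_frames = length(stack$data))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_frame_stack(stack, file.path(out_dir, "frames"),
                      extra = list(config_hash = manifest$config_hash))
    write_map(world$truth$t, file.path(out_dir, "truth_t"),
              name = "t", units = "",
              extra = list(config_hash = manifest$config_hash))
    write_map(world$truth$dx_ref, file.path(out_dir, "truth_dx_ref"),
              name = "dx_ref", units = "um",
              extra = list(config_hash = manifest$config_hash))
    write_map(world$truth$sigma_o2, file.path(out_dir, "truth_sigma_o2"),
              name = "sigma_o2", units = "um^2",
              extra = list(config_hash = manifest$config_hash))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(stack = stack, truth = world$truth, angles_deg = world$angles,
       material = world$material, manifest = manifest)
}

#' Retrieve contrast maps from a frame stack
#'
#' Dispatches on `config$retrieval$mode`:
#' * `"conventional"` — per-pixel Gaussian fits over the IC positions
#'   (requires more than one IC position), channels from
#'   [conventional_retrieve()] against the stack's reference curve;
#' * `"single-shot"` — pure-phase dark field from the frame nearest the
#'   curve peak via [single_shot_purephase()] (warns if the stack holds a
#'   full IC scan, of which only the peak frame is used);
#' * `"hybrid"` — [hybrid_retrieve()] with `config$retrieval$gamma` either a
#'   number (mrad⁻²) or `"estimate"`, the latter running a conventional
#'   retrieval of the first angle first (requires a fully sampled stack).
#'
#' @param config a [read_run_config()] object or plain list.
#' @param stack a `frame_stack` or a path prefix for [read_frame_stack()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return A `retrieved_maps` object: arrays `t`, `dx_ref`, `sigma_o2`
#'   (µm²), `a` (hybrid only), `flags`, indexed `(row, col, dither, angle)`,
#'   plus `mode`, `gamma`, `angles_deg`, `n_dither`, `geometry`.
#' @export
cmd_retrieve <- function(config, stack, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (is.character(stack)) stack <- read_frame_stack(stack)
  stopifnot(inherits(stack, "frame_stack"))
  mode <- cfg$retrieval$mode %||% "conventional"
  g <- geometry_from_config(cfg$geometry)
  p <- stack$ic
  d <- dim(stack$data)
  n_ic <- d[1]
  sr2 <- cfg$retrieval$sigma_r2 %||% p$sigma_r2

  perm <- function(arr) aperm(arr, c(3, 4, 1, 2))  # (dither,angle,row,col) -> (row,col,dither,angle)

  if (mode == "conventional") {
    if (n_ic < 4L) stop("conventional retrieval needs a sampled illumination curve (>= 4 IC positions)")
    fits <- fit_frame_stack(stack, with_offset = isTRUE(cfg$retrieval$with_offset))
    ref <- list(area = array(p$A * stack$exposure_scale, dim(fits$area)),
                center = array(p$x0, dim(fits$area)),
                width2 = array(sr2, dim(fits$area)),
                flags = NULL)
    rtr <- conventional_retrieve(ref, fits)
    out <- list(t = perm(rtr$t), dx_ref = perm(rtr$dx_ref),
                sigma_o2 = perm(rtr$sigma_o2), flags = perm(rtr$flags),
                mode = mode, gamma = NA_real_)
  } else {
    # single-shot modes use the frame nearest the reference peak
    i_peak <- which.min(abs(stack$ic_positions - p$x0))
    if (n_ic > 1L) {
      warning("single-shot retrieval on a ", n_ic,
              "-point stack: using only the peak frame (position ",
              stack$ic_positions[i_peak], " um)")
    }
    Is <- stack$data[i_peak, , , , , drop = FALSE]
    dim(Is) <- d[-1]
    Ir <- ic_reference(stack$ic_positions[i_peak], p) * stack$exposure_scale
    if (mode == "single-shot") {
      ss <- single_shot_purephase(Ir, Is, sr2)
      out <- list(t = perm(array(1, dim(Is))),
                  dx_ref = perm(array(0, dim(Is))),
                  sigma_o2 = perm(ss$sigma_o2), flags = perm(ss$flags),
                  mode = mode, gamma = 0)
    } else if (mode == "hybrid") {
      gam <- cfg$retrieval$gamma
      if (is.null(gam)) stop("hybrid retrieval requires config$retrieval$gamma (a number in mrad^-2, or \"estimate\")")
      if (identical(gam, "estimate")) {
        if (n_ic < 4L) {
          stop("gamma estimation requires a fully sampled illumination curve (conventional retrieval at one projection)")
        }
        first <- stack
        first$data <- stack$data[, , 1L, , , drop = FALSE]
        first$angles_deg <- stack$angles_deg[1L]
        conv_cfg <- cfg
        conv_cfg$retrieval <- list(mode = "conventional", sigma_r2 = sr2)
        conv <- cmd_retrieve(conv_cfg, first)
        gm <- estimate_gamma(conv$t,
                             variance_um2_to_mrad2(conv$sigma_o2, g),
                             mask_threshold = cfg$retrieval$mask_threshold %||% 0.01)
        gam <- gm$gamma
        message("estimated gamma = ", signif(gam, 6), " mrad^-2 from ",
                gm$n_pixels, " pixels")
      }
      hy <- hybrid_retrieve(array(Ir, dim(Is)), Is, gam, sr2, g)
      out <- list(t = perm(hy$t), dx_ref = perm(array(0, dim(Is))),
                  sigma_o2 = perm(hy$sigma_o2), a = perm(hy$a),
                  flags = perm(hy$flags), mode = mode, gamma = gam)
    } else {
      stop("unknown retrieval mode '", mode, "'")
    }
  }
  out$angles_deg <- stack$angles_deg
  out$n_dither <- stack$n_dither
  out$fine_pitch_um <- stack$fine_pitch_um %||%
    (g$pixel_pitch_um / stack$n_dither)
  out$geometry <- g
  class(out) <- "retrieved_maps"
  nbad <- sum(out$flags != FLAG_OK)
  if (nbad > 0) {
    tab <- table(factor(out$flags[out$flags != FLAG_OK],
                        levels = retrieval_flags(),
                        labels = names(retrieval_flags())))
    message("flagged pixels: ",
            paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                  collapse = ", "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hsh <- config_hash(cfg)
    for (nm in intersect(c("t", "dx_ref", "sigma_o2", "a", "flags"), names(out))) {
      dd <- dim(out[[nm]])
      write_map(matrix(out[[nm]][, , 1L, 1L], dd[1], dd[2]),
                file.path(out_dir, paste0("retrieved_", nm)),
                name = nm,
                units = if (nm == "sigma_o2") "um^2" else if (nm == "dx_ref") "um" else "",
                extra = list(config_hash = hsh, mode = mode))
    }
    dd <- dim(out$sigma_o2)
    prof <- roi_profile(matrix(out$sigma_o2[, , 1L, 1L], dd[1], dd[2]),
                        pitch_um = out$fine_pitch_um * stack$n_dither)
    write_profile_csv(prof, file.path(out_dir, "profile_sigma_o2"))
  }
  out
}

#' Reconstruct a retrieved signal by filtered back projection
#'
#' Builds the sinogram of the requested signal kind from a
#' [cmd_retrieve()] result (interleaving dither steps), reconstructs it with
#' [fbp_reconstruct()] and reports the cupping metric when a homogeneous
#' interior is expected.
#'
#' @param config a [read_run_config()] object or plain list; uses
#'   `config$recon$signal_kind` (default `"hybrid"` for hybrid retrievals,
#'   else `"sigma_o2"`), `config$recon$filter` and, optionally,
#'   `config$recon$cupping_radius_px`.
#' @param retrieved a `retrieved_maps` object.
#' @param row detector row to reconstruct.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return List with `sinogram`, `slice` and `cupping` (NA when no cupping
#'   radius was configured).
#' @export
cmd_recon <- function(config, retrieved, row = 1L, out_dir = NULL) {
  cfg <- read_run_config(config)
  stopifnot(inherits(retrieved, "retrieved_maps"))
  if (length(retrieved$angles_deg) < 2L) stop("reconstruction requires per-angle maps")
  kind <- cfg$recon$signal_kind %||%
    (if (identical(retrieved$mode, "hybrid")) "hybrid" else "sigma_o2")
  g <- retrieved$geometry
  src <- switch(kind,
                minus_log_t = -log(retrieved$t),
                sigma_o2 = variance_to_angular(retrieved$sigma_o2, g),
                hybrid = variance_to_angular(retrieved$sigma_o2, g),
                stop("unknown signal kind '", kind, "'"))
  sino <- build_sinogram(src, retrieved$angles_deg, signal_kind = kind,
                         pitch_um = retrieved$fine_pitch_um %||%
                           (g$pixel_pitch_um / retrieved$n_dither),
                         row = row)
  slice <- fbp_reconstruct(sino, filter = cfg$recon$filter %||% "ramp")
  cup <- NA_real_
  if (!is.null(cfg$recon$cupping_radius_px)) {
    mask <- interior_disk_mask(slice, cfg$recon$cupping_radius_px)
    cup <- cupping_metric(slice, mask)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hsh <- config_hash(cfg)
    write_sinogram(sino, file.path(out_dir, "sinogram"),
                   extra = list(config_hash = hsh))
    write_map(slice$data, file.path(out_dir, "slice"), name = kind,
              units = slice$units, extra = list(config_hash = hsh))
    jsonlite::write_json(list(signal_kind = kind, cupping_metric = cup,
                              config_hash = hsh),
                         file.path(out_dir, "cupping.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(sinogram = sino, slice = slice, cupping = cup)
}
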