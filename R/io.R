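# On-disk formats.  Image-like data travels as plain CSV matrices with a
# JSON sidecar carrying metadata (axis order, units, seed, config hash);
# multi-dimensional stacks use a long-format CSV indexed by
# (ic, dither, angle, row, col).  Axis order is documented in the metadata,
# not implied by position.

meta_path <- function(path) paste0(path, ".json")
data_path <- function(path) paste0(path, ".csv")

# full-precision decimal representation so write -> read is bit-identical
fmt_full <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(m, path) {
  ch <- matrix(fmt_full(m), nrow(m), ncol(m))
  utils::write.table(ch, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

write_meta <- function(meta, path) {
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_meta <- function(path) {
  jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
}

#' Hash of a configuration (or any R object)
#'
#' Stable content hash embedded in every output artifact so that runs can be
#' traced back to their configuration.
#'
#' @param x an R object.
#' @return Character hash.
#' @export
config_hash <- function(x) rlang::hash(x)

#' Write / read a frame stack
#'
#' The stack is stored as `<path>.csv` (long format with columns
#' `ic, dither, angle, row, col, intensity`) plus `<path>.json` holding the
#' dimensions, IC positions, angles, noise model, seed and reference-curve
#' parameters. `read_frame_stack()` inverts `write_frame_stack()` exactly.
#'
#' @param stack a `frame_stack` from [simulate_frames()].
#' @param path output path prefix (no extension).
#' @param extra named list merged into the JSON metadata (e.g. config hash).
#' @return `write_frame_stack()`: the path prefix, invisibly;
#'   `read_frame_stack()`: a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  idx <- expand.grid(ic = seq_len(d[1]), dither = seq_len(d[2]),
                     angle = seq_len(d[3]), row = seq_len(d[4]),
                     col = seq_len(d[5]))
  df <- cbind(idx, intensity = fmt_full(as.vector(stack$data)))
  utils::write.csv(df, data_path(path), row.names = FALSE, quote = FALSE)
  meta <- c(list(kind = "frame_stack",
                 axis_order = c("ic", "dither", "angle", "row", "col"),
                 dim = d,
                 ic_positions_um = stack$ic_positions,
                 n_dither = stack$n_dither,
                 angles_deg = stack$angles_deg,
                 exposure_scale = stack$exposure_scale,
                 noise = stack$noise,
                 seed = stack$seed,
                 fine_pitch_um = stack$fine_pitch_um,
                 ic_params = unclass(stack$ic)),
            extra)
  write_meta(meta, path)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$kind, "frame_stack")) stop("not a frame_stack artifact")
  df <- utils::read.csv(data_path(path))
  data <- array(NA_real_, dim = meta$dim)
  data[as.matrix(df[, c("ic", "dither", "angle", "row", "col")])] <- df$intensity
  p <- do.call(ic_params, lapply(meta$ic_params, as.numeric))
  structure(list(data = data, ic_positions = as.numeric(meta$ic_positions_um),
                 n_dither = as.integer(meta$n_dither),
                 angles_deg = as.numeric(meta$angles_deg),
                 exposure_scale = as.numeric(meta$exposure_scale),
                 noise = meta$noise,
                 seed = if (!is.null(meta$seed)) as.numeric(meta$seed),
                 fine_pitch_um = if (!is.null(meta$fine_pitch_um))
                   as.numeric(meta$fine_pitch_um),
                 ic = p),
            class = "frame_stack")
}

#' Write / read a 2-D map
#'
#' Plain CSV matrix (no row names) plus JSON sidecar with the map name,
#' units and any extra metadata.
#'
#' @param map numeric matrix.
#' @param path output path prefix.
#' @param name map name recorded in the metadata.
#' @param units unit string recorded in the metadata.
#' @param extra named list merged into the metadata.
#' @return `write_map()`: path prefix, invisibly; `read_map()`: the matrix
#'   with the metadata attached as attribute `"meta"`.
#' @export
write_map <- function(map, path, name = "map", units = "", extra = list()) {
  stopifnot(is.matrix(map))
  write_matrix_csv(map, data_path(path))
  write_meta(c(list(kind = "map", name = name, units = units,
                    dim = dim(map)), extra), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$kind, "map")) stop("not a map artifact")
  m <- as.matrix(utils::read.table(data_path(path), sep = ","))
  dimnames(m) <- NULL
  attr(m, "meta") <- meta
  m
}

#' Write / read a sinogram
#'
#' @param s a `sinogram`.
#' @param path output path prefix.
#' @param extra named list merged into the metadata.
#' @return `write_sinogram()`: path prefix, invisibly; `read_sinogram()`:
#'   a `sinogram`.
#' @export
write_sinogram <- function(s, path, extra = list()) {
  stopifnot(inherits(s, "sinogram"))
  write_matrix_csv(s$data, data_path(path))
  write_meta(c(list(kind = "sinogram", angles_deg = s$angles_deg,
                    signal_kind = s$signal_kind, pitch_um = s$pitch_um,
                    dim = dim(s$data)), extra), path)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- read_meta(path)
  if (!identical(meta$kind, "sinogram")) stop("not a sinogram artifact")
  m <- as.matrix(utils::read.table(data_path(path), sep = ","))
  dimnames(m) <- NULL
  structure(list(data = m, angles_deg = as.numeric(meta$angles_deg),
                 signal_kind = meta$signal_kind,
                 pitch_um = as.numeric(meta$pitch_um)),
            class = "sinogram")
}

#' ROI-averaged profile of a map
#'
#' Averages the rows of a rectangular region of interest and reports, per
#' column, the mean and the standard deviation across rows — the profile
#' methodology used for wedge validation plots.
#'
#' @param map numeric matrix.
#' @param rows row indices of the ROI (default: all rows).
#' @param pitch_um column pitch (µm) for the x coordinate.
#' @return data.frame with `x_um`, `mean`, `sd`.
#' @export
roi_profile <- function(map, rows = seq_len(nrow(map)), pitch_um = 1) {
  stopifnot(is.matrix(map))
  roi <- map[rows, , drop = FALSE]
  data.frame(x_um = (seq_len(ncol(map)) - 1) * pitch_um,
             mean = colMeans(roi),
             sd = apply(roi, 2, stats::sd))
}

#' Write a profile CSV
#'
#' @param profile data.frame from [roi_profile()].
#' @param path file path (`.csv` appended if absent).
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' JSON configuration with blocks `geometry`, `acquisition`
#' (`ic_positions`, `n_dither`, `noise`, `seed`, `exposure_scale`),
#' `phantom`, `retrieval` (`mode`, `gamma`, `sigma_r2`, `mask_threshold`)
#' and `recon` (`filter`, `signal_kind`). Unknown modes or enum values fail
#' here rather than mid-pipeline.
#'
#' @param path JSON file path, or a named list already parsed.
#' @return Validated config list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    path
  }
  if (!is.null(cfg$retrieval$mode)) {
    if (!cfg$retrieval$mode %in% c("conventional", "single-shot", "hybrid")) {
      stop("unknown retrieval mode '", cfg$retrieval$mode, "'")
    }
  }
  if (!is.null(cfg$acquisition$noise)) {
    if (!cfg$acquisition$noise %in% c("none", "poisson")) {
      stop("unknown noise model '", cfg$acquisition$noise, "'")
    }
  }
  if (!is.null(cfg$recon$filter)) {
    if (!cfg$recon$filter %in% c("ramp", "shepp-logan")) {
      stop("unknown reconstruction filter '", cfg$recon$filter, "'")
    }
  }
  structure(cfg, class = c("run_config", "list"))
}
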