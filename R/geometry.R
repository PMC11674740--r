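#' System geometry for an edge-illumination setup
#'
#' Bundles the distances, mask periods/apertures and detector pitch of an
#' edge-illumination system. The geometry object is the single authority for
#' unit conversions between length-squared dark-field units (variance of the
#' beamlet profile at the detector-mask plane, in µm²) and angular units
#' (µrad² / mrad²), and for period projection under geometric magnification.
#'
#' The propagation distance used for angle conversions is the distance from
#' the sample-mask plane to the detector-mask plane; the sample is treated as
#' sitting at the sample mask.
#'
#' Defaults reproduce the laboratory system the method was developed on: a
#' rotating-anode source with the detector at 850 mm, the sample mask at
#' 685 mm (geometric magnification ~1.24, propagation distance 165 mm),
#' sample/detector mask periods of 79/98 µm, apertures of 10/17 µm and a
#' 50 µm detector pixel pitch.
#'
#' @param source_to_detector_mm source-to-detector distance (mm).
#' @param source_to_sample_mask_mm source to sample-mask distance (mm);
#'   must be smaller than `source_to_detector_mm`.
#' @param sample_mask_period_um,detector_mask_period_um mask periods (µm).
#' @param sample_mask_aperture_um,detector_mask_aperture_um aperture widths (µm).
#' @param pixel_pitch_um detector pixel pitch (µm).
#' @return An object of class `ei_geometry`.
#' @examples
#' g <- ei_geometry()
#' magnification(g)
#' project_period(79, g)
#' @export
ei_geometry <- function(source_to_detector_mm = 850,
                        source_to_sample_mask_mm = 685,
                        sample_mask_period_um = 79,
                        detector_mask_period_um = 98,
                        sample_mask_aperture_um = 10,
                        detector_mask_aperture_um = 17,
                        pixel_pitch_um = 50) {
  g <- list(
    source_to_detector_mm = source_to_detector_mm,
    source_to_sample_mask_mm = source_to_sample_mask_mm,
    sample_mask_period_um = sample_mask_period_um,
    detector_mask_period_um = detector_mask_period_um,
    sample_mask_aperture_um = sample_mask_aperture_um,
    detector_mask_aperture_um = detector_mask_aperture_um,
    pixel_pitch_um = pixel_pitch_um
  )
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("geometry field '", nm, "' must be a single positive number")
    }
  }
  if (source_to_sample_mask_mm >= source_to_detector_mm) {
    stop("source_to_sample_mask_mm must be smaller than source_to_detector_mm")
  }
  structure(g, class = "ei_geometry")
}

#' @export
print.ei_geometry <- function(x, ...) {
  cat("Edge-illumination geometry\n")
  cat(sprintf("  source -> detector      %8.1f mm\n", x$source_to_detector_mm))
  cat(sprintf("  source -> sample mask   %8.1f mm\n", x$source_to_sample_mask_mm))
  cat(sprintf("  propagation distance    %8.1f mm\n", propagation_distance(x)))
  cat(sprintf("  magnification           %8.4f\n", magnification(x)))
  cat(sprintf("  mask periods (s/d)      %g / %g um\n",
              x$sample_mask_period_um, x$detector_mask_period_um))
  cat(sprintf("  mask apertures (s/d)    %g / %g um\n",
              x$sample_mask_aperture_um, x$detector_mask_aperture_um))
  cat(sprintf("  pixel pitch             %g um\n", x$pixel_pitch_um))
  invisible(x)
}

#' Build a geometry object from a parsed JSON config block
#'
#' Field names carry their units, e.g. `source_to_detector_mm`. Missing
#' fields fall back to the laboratory preset of [ei_geometry()].
#'
#' @param block a named list, typically `config$geometry` from
#'   [read_run_config()].
#' @return An `ei_geometry` object.
#' @export
geometry_from_config <- function(block) {
  if (is.null(block)) return(ei_geometry())
  known <- names(formals(ei_geometry))
  extra <- setdiff(names(block), known)
  if (length(extra)) stop("unknown geometry fields: ", paste(extra, collapse = ", "))
  do.call(ei_geometry, block)
}

#' Geometric magnification
#'
#' Ratio of source-to-detector over source-to-sample-mask distance; the
#' factor by which the sample-mask period projects onto the detector plane.
#'
#' @param g an [ei_geometry()] object.
#' @return Dimensionless magnification (> 1).
#' @export
magnification <- function(g) {
  stopifnot(inherits(g, "ei_geometry"))
  g$source_to_detector_mm / g$source_to_sample_mask_mm
}

#' Propagation distance (sample-mask plane to detector-mask plane)
#'
#' @param g an [ei_geometry()] object.
#' @return Distance in mm.
#' @export
propagation_distance <- function(g) {
  stopifnot(inherits(g, "ei_geometry"))
  g$source_to_detector_mm - g$source_to_sample_mask_mm
}

# propagation distance in metres; internal
z_m <- function(g) propagation_distance(g) / 1000

#' Project a period onto the detector plane
#'
#' @param period_um period at the sample-mask plane (µm), strictly positive.
#' @param g an [ei_geometry()] object.
#' @return Projected period in µm: `period_um * magnification(g)`.
#' @export
project_period <- function(period_um, g) {
  if (any(!is.finite(period_um)) || any(period_um <= 0)) {
    stop("period must be positive")
  }
  period_um * magnification(g)
}

#' Convert a lateral shift to a refraction angle
#'
#' A lateral displacement of the beamlet at the detector-mask plane divided
#' by the propagation distance gives the refraction angle; with the shift in
#' µm and the distance in metres the angle comes out in µrad.
#'
#' @param shift_um lateral shift(s) in µm.
#' @param g an [ei_geometry()] object.
#' @return Angle(s) in µrad.
#' @export
shift_to_angle <- function(shift_um, g) {
  shift_um / z_m(g)
}

#' @rdname shift_to_angle
#' @param angle_urad angle(s) in µrad.
#' @export
angle_to_shift <- function(angle_urad, g) {
  angle_urad * z_m(g)
}

#' Convert dark-field variance between length² and angular units
#'
#' The dark-field signal is measured as a variance in µm² at the
#' detector-mask plane and becomes a geometry-independent angular variance
#' (µrad²) after division by the squared propagation distance.
#' `variance_to_angular()` and `angular_to_variance()` are exact inverses.
#'
#' @param v_um2 variance(s) in µm².
#' @param g an [ei_geometry()] object.
#' @return `variance_to_angular()`: µrad²; `angular_to_variance()`: µm².
#' @export
variance_to_angular <- function(v_um2, g) {
  v_um2 / z_m(g)^2
}

#' @rdname variance_to_angular
#' @param v_urad2 angular variance(s) in µrad².
#' @export
angular_to_variance <- function(v_urad2, g) {
  v_urad2 * z_m(g)^2
}

#' Convert dark-field variance between µm² and the canonical mrad²
#'
#' The retrieval math works in angular units: variances in mrad², gamma in
#' mrad⁻². These helpers move the presentation unit (µm² at the
#' detector-mask plane) into and out of that canonical unit
#' (1 mrad² = 1e6 µrad²).
#'
#' @param v_um2 variance(s) in µm².
#' @param g an [ei_geometry()] object.
#' @return `variance_um2_to_mrad2()`: mrad²; `variance_mrad2_to_um2()`: µm².
#' @export
variance_um2_to_mrad2 <- function(v_um2, g) variance_to_angular(v_um2, g) * 1e-6

#' @rdname variance_um2_to_mrad2
#' @param v_mrad2 variance(s) in mrad².
#' @export
variance_mrad2_to_um2 <- function(v_mrad2, g) angular_to_variance(v_mrad2 * 1e6, g)

urad2_to_mrad2 <- function(v_urad2) v_urad2 * 1e-6
mrad2_to_urad2 <- function(v_mrad2) v_mrad2 * 1e6
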