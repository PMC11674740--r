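#' Reference illumination-curve parameters
#'
#' The intensity recorded by one pixel as the sample mask is scanned through
#' one period (the illumination curve, IC) is well approximated by a
#' Gaussian: `A / sqrt(2*pi*sigma_r2) * exp(-(x - x0)^2 / (2*sigma_r2))`,
#' optionally plus a small additive `offset` that absorbs the heavier-than-
#' Gaussian tails of real curves. `A` is the area under the curve (a
#' counts-scale amplitude), `x0` the mask position of peak alignment and
#' `sigma_r2` the curve variance in µm².
#'
#' Defaults (`A = 200`, `sigma_r2 = 81` µm²) are typical per-pixel values for
#' the laboratory system of [ei_geometry()].
#'
#' @param A area under the curve (counts scale), > 0.
#' @param x0 alignment offset (µm).
#' @param sigma_r2 reference variance (µm²), > 0.
#' @param offset additive constant (counts), >= 0. Default 0 (ideal masks).
#' @return An object of class `ic_params`.
#' @export
ic_params <- function(A = 200, x0 = 0, sigma_r2 = 81, offset = 0) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(x0), length(x0) == 1L, is.finite(x0),
            is.numeric(sigma_r2), length(sigma_r2) == 1L, is.finite(sigma_r2),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  if (A <= 0) stop("A must be > 0")
  if (sigma_r2 <= 0) stop("sigma_r2 must be > 0")
  if (offset < 0) stop("offset must be >= 0")
  structure(list(A = A, x0 = x0, sigma_r2 = sigma_r2, offset = offset),
            class = "ic_params")
}

#' Per-pixel sample signals
#'
#' The three per-pixel quantities a sample imprints on the illumination
#' curve: `t`, the transmission (fractional change in curve area from
#' attenuation); `dx_ref`, the lateral shift of the curve centre from
#' refraction (µm); and `sigma_o2`, the broadening of the curve variance
#' from sub-resolution scattering, i.e. the dark-field signal (µm² at the
#' detector-mask plane).
#'
#' Inputs may be scalars or matrices, and are recycled to a common shape.
#' With `physical = TRUE` (the default, intended for simulation inputs) the
#' constructor enforces `0 < t <= 1` and `sigma_o2 >= 0`; retrieved maps may
#' violate these bounds under noise and are constructed with
#' `physical = FALSE`, which preserves the values and leaves flagging to the
#' retrieval functions.
#'
#' @param t transmission map (dimensionless).
#' @param dx_ref refraction shift map (µm).
#' @param sigma_o2 scattering (dark-field) variance map (µm²).
#' @param physical validate physical-simulation bounds?
#' @return An object of class `sample_signals`: a list of three equally
#'   shaped numeric matrices.
#' @export
sample_signals <- function(t = 1, dx_ref = 0, sigma_o2 = 0, physical = TRUE) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)
  dims <- lapply(list(t, dx_ref, sigma_o2), function(x) {
    if (is.matrix(x)) dim(x) else NULL
  })
  dims <- unique(Filter(Negate(is.null), dims))
  if (length(dims) > 1L) stop("t, dx_ref and sigma_o2 must share a shape")
  target <- if (length(dims)) dims[[1]] else c(1L, 1L)
  expand <- function(x) {
    if (is.matrix(x)) x else matrix(x, target[1], target[2])
  }
  t <- expand(t); dx_ref <- expand(dx_ref); sigma_o2 <- expand(sigma_o2)
  if (isTRUE(physical)) {
    if (any(t <= 0 | t > 1)) stop("physical transmission requires 0 < t <= 1")
    if (any(sigma_o2 < 0)) stop("physical sigma_o2 must be >= 0")
  }
  structure(list(t = t, dx_ref = dx_ref, sigma_o2 = sigma_o2),
            class = "sample_signals")
}

#' Identity (empty-beam) signals
#'
#' @param nrow,ncol map dimensions.
#' @return `sample_signals` with `t = 1`, `dx_ref = 0`, `sigma_o2 = 0`.
#' @export
empty_signals <- function(nrow = 1L, ncol = 1L) {
  sample_signals(matrix(1, nrow, ncol), matrix(0, nrow, ncol),
                 matrix(0, nrow, ncol))
}

#' Evaluate the reference illumination curve
#'
#' @param xbar sample-mask displacement(s) (µm).
#' @param p an [ic_params()] object.
#' @return Intensity at each `xbar`.
#' @export
ic_reference <- function(xbar, p) {
  stopifnot(inherits(p, "ic_params"))
  p$A / sqrt(2 * pi * p$sigma_r2) *
    exp(-(xbar - p$x0)^2 / (2 * p$sigma_r2)) + p$offset
}

#' Evaluate the sample illumination curve
#'
#' The sample curve is the reference curve scaled in area by the
#' transmission `t`, shifted by the refraction displacement `dx_ref` and
#' broadened from variance `sigma_r2` to `sigma_r2 + sigma_o2` by
#' scattering.
#'
#' Either `xbar` is scalar and the signal maps give the shape of the result,
#' or the signals are scalar (1x1) and `xbar` is a vector.
#'
#' @param xbar sample-mask displacement(s) (µm).
#' @param p an [ic_params()] object.
#' @param s a [sample_signals()] object.
#' @return Intensity with the shape of the broadcast inputs.
#' @export
ic_sample <- function(xbar, p, s) {
  stopifnot(inherits(p, "ic_params"), inherits(s, "sample_signals"))
  t <- s$t; dx <- s$dx_ref; so2 <- s$sigma_o2
  if (length(xbar) > 1L) {
    if (length(t) != 1L) stop("vector xbar requires scalar (1x1) signals")
    t <- t[1]; dx <- dx[1]; so2 <- so2[1]
  }
  w <- p$sigma_r2 + so2
  t * p$A / sqrt(2 * pi * w) *
    exp(-(xbar - p$x0 - dx)^2 / (2 * w)) + p$offset
}

#' Reference and sample intensities at the illumination-curve peak
#'
#' Evaluates both curves at `xbar = x0`, the single-shot working point. The
#' squared ratio of the two values is the single-shot measurement statistic
#' Omega used by [single_shot_purephase()] and [hybrid_retrieve()].
#'
#' @inheritParams ic_sample
#' @return List with elements `reference` and `sample`.
#' @export
peak_pair <- function(p, s) {
  list(reference = ic_reference(p$x0, p), sample = ic_sample(p$x0, p, s))
}

#' Simulate an acquired frame stack
#'
#' Generates per-pixel intensities for every combination of
#' illumination-curve position, dither step and projection angle, by
#' evaluating [ic_sample()] with the per-pixel signals of each angle.
#'
#' The per-angle signal maps must be supplied at "fine" column resolution,
#' `n_dither` times the detector column count: dithering translates the
#' sample laterally in sub-pixel steps, so dither step `d` sees fine columns
#' `d, d + n_dither, d + 2*n_dither, ...`. Retrieval interleaves the steps
#' back with [build_sinogram()].
#'
#' @param signals_by_angle list (one element per projection angle) of
#'   [sample_signals()] maps, all the same shape, with a column count
#'   divisible by `n_dither`.
#' @param p an [ic_params()] object (reference curve, assumed common to all
#'   pixels).
#' @param ic_positions numeric vector of sample-mask displacements (µm) at
#'   which frames are taken; a single position at the curve peak for
#'   single-shot acquisition.
#' @param n_dither number of dithering steps.
#' @param noise `"none"` for expected intensities, `"poisson"` for Poisson
#'   counting noise on the expected counts.
#' @param seed integer seed, required when `noise = "poisson"`; two runs
#'   with equal seeds produce identical stacks.
#' @param exposure_scale dose factor multiplying expected counts before
#'   noise is applied.
#' @param angles_deg optional vector of projection angles (degrees) recorded
#'   as metadata; defaults to `0, 1, ..., n_angle - 1` indices if omitted.
#' @return A `frame_stack`: a list with the 5-D intensity array `data`
#'   indexed `(ic, dither, angle, row, col)` plus acquisition metadata.
#' @export
simulate_frames <- function(signals_by_angle, p, ic_positions,
                            n_dither = 1L, noise = c("none", "poisson"),
                            seed = NULL, exposure_scale = 1,
                            angles_deg = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(p, "ic_params"), length(ic_positions) >= 1L)
  if (inherits(signals_by_angle, "sample_signals")) {
    signals_by_angle <- list(signals_by_angle)
  }
  n_angle <- length(signals_by_angle)
  shapes <- unique(lapply(signals_by_angle, function(s) dim(s$t)))
  if (length(shapes) != 1L) stop("per-angle signal maps must share a shape")
  nr <- shapes[[1]][1]
  nc_fine <- shapes[[1]][2]
  if (nc_fine %% n_dither != 0L) {
    stop("fine column count must be divisible by n_dither")
  }
  nc <- nc_fine %/% n_dither
  if (is.null(angles_deg)) angles_deg <- seq_len(n_angle) - 1
  if (length(angles_deg) != n_angle) stop("angles_deg length mismatch")

  n_ic <- length(ic_positions)
  data <- array(NA_real_, dim = c(n_ic, n_dither, n_angle, nr, nc))
  for (a in seq_len(n_angle)) {
    s <- signals_by_angle[[a]]
    for (d in seq_len(n_dither)) {
      cols <- seq.int(d, nc_fine, by = n_dither)
      sd <- sample_signals(s$t[, cols, drop = FALSE],
                           s$dx_ref[, cols, drop = FALSE],
                           s$sigma_o2[, cols, drop = FALSE],
                           physical = FALSE)
      for (i in seq_len(n_ic)) {
        data[i, d, a, , ] <- ic_sample(ic_positions[i], p, sd) * exposure_scale
      }
    }
  }
  if (noise == "poisson") {
    if (is.null(seed)) stop("poisson noise requires a seed")
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    data[] <- stats::rpois(length(data), lambda = data)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(data = data, ic_positions = as.numeric(ic_positions),
                 n_dither = as.integer(n_dither),
                 angles_deg = as.numeric(angles_deg),
                 exposure_scale = exposure_scale,
                 noise = noise,
                 seed = if (!is.null(seed)) as.numeric(seed),
                 ic = p),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "frame_stack: %d IC positions x %d dither x %d angles x %dx%d pixels (%s)\n",
    d[1], d[2], d[3], d[4], d[5], x$noise))
  invisible(x)
}

#' Sensitivity of the pixel intensity to each contrast channel
#'
#' For a small perturbation in one contrast channel at a time (attenuation,
#' refraction, scattering), computes the magnitude of the intensity change
#' `|Ir(xbar) - Is(xbar)|` across the illumination curve. Sensitivity to
#' attenuation and scattering peaks at the curve maximum, where sensitivity
#' to refraction vanishes — the basis for single-shot dark-field acquisition
#' at the peak.
#'
#' With `normalize = "max"` (default) each channel's curve is scaled to its
#' own maximum, which reproduces the qualitative behaviour above. With
#' `normalize = "reference"` the change is divided pointwise by the
#' reference curve `Ir(xbar)`; note that this makes the attenuation channel
#' constant in `xbar`.
#'
#' @param p an [ic_params()] object.
#' @param xbar_grid mask displacements (µm) to evaluate.
#' @param small_signals named list with the perturbation per channel:
#'   elements `t`, `dx_ref` (µm), `sigma_o2` (µm²).
#' @param normalize `"max"` or `"reference"`.
#' @return A data.frame with columns `xbar`, `attenuation`, `refraction`,
#'   `scattering`.
#' @export
sensitivity_curves <- function(p, xbar_grid = seq(-30, 30, length.out = 241),
                               small_signals = list(t = 0.95, dx_ref = 1,
                                                    sigma_o2 = 4),
                               normalize = c("max", "reference")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(p, "ic_params"))
  ir <- ic_reference(xbar_grid, p)
  one <- function(s) abs(ir - ic_sample(xbar_grid, p, s))
  curves <- list(
    attenuation = one(sample_signals(t = small_signals$t)),
    refraction  = one(sample_signals(dx_ref = small_signals$dx_ref)),
    scattering  = one(sample_signals(sigma_o2 = small_signals$sigma_o2))
  )
  curves <- lapply(curves, function(v) {
    switch(normalize, max = v / max(v), reference = v / ir)
  })
  out <- data.frame(xbar = xbar_grid, attenuation = curves$attenuation,
                    refraction = curves$refraction,
                    scattering = curves$scattering)
  attr(out, "normalize") <- normalize
  out
}
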