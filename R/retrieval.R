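# Per-pixel status codes shared by the retrieval paths.
FLAG_OK <- 0L
FLAG_NONPHYSICAL <- 1L       # value outside physical bounds; preserved, not clamped
FLAG_NEG_DISCRIMINANT <- 2L  # hybrid quadratic has no real root; a set to 0
FLAG_BAD_INPUT <- 3L         # nonpositive intensity / zero reference area
FLAG_NO_CONVERGENCE <- 4L    # Gaussian fit did not converge

#' Flag code labels
#'
#' @return Named integer vector mapping flag labels to the codes used in
#'   per-pixel `flags` matrices.
#' @export
retrieval_flags <- function() {
  c(ok = FLAG_OK, nonphysical = FLAG_NONPHYSICAL,
    negative_discriminant = FLAG_NEG_DISCRIMINANT,
    bad_input = FLAG_BAD_INPUT, no_convergence = FLAG_NO_CONVERGENCE)
}

#' Fit a Gaussian (plus optional constant) to one illumination curve
#'
#' Nonlinear least squares fit of
#' `I(x) = area/sqrt(2*pi*width2) * exp(-(x - center)^2/(2*width2)) + offset`
#' to the sampled intensities of one pixel. Initial guesses come from the
#' sample moments of the curve. Non-convergence is reported through
#' `converged = FALSE` (and NA parameters), never as an error, so that a
#' degenerate pixel does not abort a full-field retrieval.
#'
#' @param intensities measured intensities.
#' @param positions sample-mask displacements (µm), same length, distinct;
#'   at least 4 points (5 with offset).
#' @param with_offset also fit an additive constant?
#' @return List with `area`, `center`, `width2`, `offset`, `converged`.
#' @export
fit_illumination_curve <- function(intensities, positions, with_offset = FALSE) {
  n <- length(intensities)
  if (length(positions) != n) stop("intensities and positions length mismatch")
  if (anyDuplicated(positions)) stop("positions must be distinct")
  need <- if (with_offset) 5L else 4L
  if (n < need) stop("need at least ", need, " points")

  fail <- list(area = NA_real_, center = NA_real_, width2 = NA_real_,
               offset = NA_real_, converged = FALSE)
  base <- if (with_offset) min(intensities) else 0
  w <- pmax(intensities - base, 0)
  if (sum(w) <= 0) return(fail)
  c0 <- sum(w * positions) / sum(w)
  v0 <- sum(w * (positions - c0)^2) / sum(w)
  if (!is.finite(v0) || v0 <= 0) return(fail)
  dx <- mean(diff(sort(positions)))
  a0 <- sum(w) * dx

  df <- data.frame(x = positions, y = intensities)
  fml <- if (with_offset) {
    y ~ area / sqrt(2 * pi * width2) * exp(-(x - center)^2 / (2 * width2)) + off
  } else {
    y ~ area / sqrt(2 * pi * width2) * exp(-(x - center)^2 / (2 * width2))
  }
  start <- list(area = a0, center = c0, width2 = v0)
  lower <- c(area = 1e-12, center = -Inf, width2 = 1e-12)
  if (with_offset) {
    start$off <- base
    lower <- c(lower, off = 0)
  }
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(fml, data = df, start = start, algorithm = "port",
                 lower = lower,
                 control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  # port flags "singular convergence" on zero-residual (noise-free) curves
  # even though the estimates are at the minimum; accept those by residual.
  rel_rms <- sqrt(stats::deviance(fit) / n) / max(abs(intensities))
  if (!isTRUE(fit$convInfo$isConv) && !(is.finite(rel_rms) && rel_rms < 1e-6)) {
    return(fail)
  }
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || cf["width2"] <= 0 || cf["area"] <= 0) return(fail)
  list(area = unname(cf["area"]), center = unname(cf["center"]),
       width2 = unname(cf["width2"]),
       offset = if (with_offset) unname(cf["off"]) else 0,
       converged = TRUE)
}

#' Fit illumination curves for every pixel of a frame stack
#'
#' Runs [fit_illumination_curve()] on the IC axis of a [simulate_frames()]
#' stack, per (dither step, angle, row, column). Pixels whose fit fails are
#' flagged `no_convergence` and their parameters set to the reference values
#' in `fallback` (so downstream retrieval sees a null signal there rather
#' than NA).
#'
#' @param stack a `frame_stack` with more than one IC position.
#' @param with_offset fit an additive constant per pixel?
#' @param fallback an [ic_params()] supplying replacement parameters for
#'   non-converged pixels; defaults to the stack's reference curve.
#' @return An `ic_fits` object: arrays `area`, `center`, `width2`, `flags`
#'   indexed `(dither, angle, row, col)`.
#' @export
fit_frame_stack <- function(stack, with_offset = FALSE, fallback = stack$ic) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  if (d[1] < 4L) stop("conventional fitting needs >= 4 IC positions")
  out_dim <- d[-1]
  area <- center <- width2 <- array(NA_real_, out_dim)
  flags <- array(FLAG_OK, out_dim)
  for (dd in seq_len(d[2])) for (aa in seq_len(d[3])) {
    for (rr in seq_len(d[4])) for (cc in seq_len(d[5])) {
      f <- fit_illumination_curve(stack$data[, dd, aa, rr, cc],
                                  stack$ic_positions, with_offset)
      if (f$converged) {
        area[dd, aa, rr, cc] <- f$area
        center[dd, aa, rr, cc] <- f$center
        width2[dd, aa, rr, cc] <- f$width2
      } else {
        flags[dd, aa, rr, cc] <- FLAG_NO_CONVERGENCE
        area[dd, aa, rr, cc] <- fallback$A * stack$exposure_scale
        center[dd, aa, rr, cc] <- fallback$x0
        width2[dd, aa, rr, cc] <- fallback$sigma_r2
      }
    }
  }
  structure(list(area = area, center = center, width2 = width2, flags = flags),
            class = "ic_fits")
}

#' Conventional multi-point retrieval from Gaussian fits
#'
#' Given per-pixel Gaussian fits of the reference and sample illumination
#' curves, the three contrast channels follow from the fit parameters:
#' transmission is the area ratio, refraction the centre shift, dark field
#' the width increase:
#' `t = area_s/area_r`, `dx_ref = center_s - center_r`,
#' `sigma_o2 = width2_s - width2_r`.
#'
#' @param ref_fits,sample_fits `ic_fits` objects on matching grids, or plain
#'   lists with `area`/`center`/`width2` arrays.
#' @return List of arrays `t`, `dx_ref`, `sigma_o2` (µm²) and `flags`
#'   (zero reference area flagged `bad_input`; fit failures propagate).
#' @export
conventional_retrieve <- function(ref_fits, sample_fits) {
  if (!all(dim(ref_fits$area) == dim(sample_fits$area))) {
    stop("reference and sample fit grids do not match")
  }
  flags <- array(FLAG_OK, dim(ref_fits$area))
  if (!is.null(ref_fits$flags)) {
    flags[ref_fits$flags != FLAG_OK] <- FLAG_NO_CONVERGENCE
  }
  if (!is.null(sample_fits$flags)) {
    flags[sample_fits$flags != FLAG_OK] <- FLAG_NO_CONVERGENCE
  }
  bad <- ref_fits$area == 0
  flags[bad] <- FLAG_BAD_INPUT
  t <- sample_fits$area / ref_fits$area
  t[bad] <- NA_real_
  so2 <- sample_fits$width2 - ref_fits$width2
  flags[flags == FLAG_OK & (t > 1 | t <= 0 | so2 < 0)] <- FLAG_NONPHYSICAL
  list(t = t,
       dx_ref = sample_fits$center - ref_fits$center,
       sigma_o2 = so2,
       flags = flags)
}

#' Single-shot pure-phase dark-field retrieval
#'
#' At the illumination-curve peak, with refraction neglected and `t = 1`
#' (pure phase object), the scattering variance follows from the squared
#' peak-intensity ratio `Omega = (Ir/Is)^2` alone:
#' `sigma_o2 = sigma_r2 * (Omega - 1)`.
#'
#' Noise can push `Is` above `Ir`; the resulting negative variance is
#' preserved (so tomographic noise stays zero-mean) and flagged
#' `nonphysical`.
#'
#' @param Ir_peak,Is_peak reference and sample peak intensities (scalars or
#'   equally shaped arrays).
#' @param sigma_r2 reference curve variance; the result inherits its units
#'   (µm² in, µm² out).
#' @return List with `sigma_o2` and `flags`.
#' @export
single_shot_purephase <- function(Ir_peak, Is_peak, sigma_r2) {
  flags <- array(FLAG_OK, dim = dim(as.array(Is_peak)))
  bad <- !is.finite(Is_peak) | Is_peak <= 0
  omega <- (Ir_peak / Is_peak)^2
  so2 <- sigma_r2 * (omega - 1)
  so2[bad] <- NA_real_
  flags[bad] <- FLAG_BAD_INPUT
  flags[!bad & so2 < 0] <- FLAG_NONPHYSICAL
  list(sigma_o2 = so2, flags = flags)
}

#' Estimate the attenuation-to-scattering ratio gamma
#'
#' Under macroscopic homogeneity, `-ln(t)` and `sigma_o2` are proportional
#' across the sample with constant ratio `gamma` (mrad⁻²). The estimate is
#' taken over the pixels where the sample is present (`-ln t` above
#' `mask_threshold`), from a conventionally retrieved, fully sampled
#' projection. The default `"ratio_of_sums"` estimator
#' `sum(-ln t) / sum(sigma_o2)` is robust to low-signal pixels; a
#' `"median_of_ratios"` alternative is provided.
#'
#' @param t_map transmission map.
#' @param sigma_o2_mrad2 dark-field map in mrad² (convert µm² maps with
#'   the geometry first; see [hybrid_retrieve()] which does this for you).
#' @param mask_threshold sample mask: pixels with `-ln t` above this enter
#'   the estimate.
#' @param method `"ratio_of_sums"` or `"median_of_ratios"`.
#' @return A `gamma_model`: list with `gamma` (mrad⁻²), `source`
#'   (`"estimated"`), `mask_threshold`, `n_pixels`.
#' @export
estimate_gamma <- function(t_map, sigma_o2_mrad2, mask_threshold = 0.01,
                           method = c("ratio_of_sums", "median_of_ratios")) {
  method <- match.arg(method)
  if (!all(dim(as.array(t_map)) == dim(as.array(sigma_o2_mrad2)))) {
    stop("t and sigma_o2 maps must share a shape")
  }
  mlt <- -log(t_map)
  keep <- is.finite(mlt) & is.finite(sigma_o2_mrad2) & mlt > mask_threshold
  if (!any(keep)) stop("no pixels pass the sample mask; no attenuation signal")
  g <- switch(method,
    ratio_of_sums = {
      denom <- sum(sigma_o2_mrad2[keep])
      if (denom <= 0) stop("total dark-field signal is not positive")
      sum(mlt[keep]) / denom
    },
    median_of_ratios = {
      ok <- keep & sigma_o2_mrad2 > 0
      if (!any(ok)) stop("no pixels with positive dark-field signal")
      stats::median(mlt[ok] / sigma_o2_mrad2[ok])
    })
  structure(list(gamma = g, source = "estimated",
                 mask_threshold = mask_threshold, method = method,
                 n_pixels = sum(keep)),
            class = "gamma_model")
}

#' Gamma model from a user-supplied constant
#'
#' @param gamma attenuation-to-scattering ratio (mrad⁻²), >= 0.
#' @return A `gamma_model` with `source = "user"`.
#' @export
gamma_model <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop("gamma must be a single number >= 0")
  }
  structure(list(gamma = gamma, source = "user", mask_threshold = NA_real_),
            class = "gamma_model")
}

#' Solve the hybrid single-shot quadratic for the attenuated fraction
#'
#' The hybrid retrieval closes the single-shot system by assuming
#' macroscopic homogeneity, `sigma_o2 = (a + a^2/2) / gamma` with
#' `a = 1 - t` the attenuated beam fraction (a second-order expansion of
#' `-ln(1-a)/gamma`). Substituting this and `t = 1 - a` into the single-shot
#' relation `Omega = (sigma_r2 + sigma_o2) / (t^2 sigma_r2)` gives, with
#' `G = gamma * sigma_r2 * Omega`, the quadratic
#'
#' `(G - 1/2) a^2 - (2G + 1) a + (G - gamma*sigma_r2) = 0`,
#'
#' whose negative-square-root branch is the physical solution: it is
#' continuous down to `gamma = 0`, where it reduces to the pure-phase result
#' `a = 0`, `sigma_o2 = sigma_r2 * (Omega - 1)`. The branch is evaluated in
#' the division-safe form `a = 2C / (B + sqrt(B^2 - 4AC))`, which remains
#' finite when the leading coefficient crosses zero.
#'
#' All quantities are in canonical angular units: `sigma_r2` in mrad²,
#' `gamma` in mrad⁻²; `Omega` is dimensionless. Negative discriminants
#' (possible under noise) are flagged and return `a = 0`; out-of-range
#' solutions (`a < 0`, `a > 1`, `sigma_o2 < 0`) are preserved unclamped and
#' flagged `nonphysical`.
#'
#' @param Omega squared peak ratio(s) `(Ir/Is)^2`, > 0.
#' @param gamma scalar gamma (mrad⁻²), >= 0.
#' @param sigma_r2 scalar reference variance (mrad²), > 0.
#' @return A `hybrid_solution`: list of arrays `a` (attenuated fraction),
#'   `sigma_o2` (mrad²) and integer `flags` (see [retrieval_flags()]).
#' @export
hybrid_solve <- function(Omega, gamma, sigma_r2) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop("gamma must be a single number >= 0 (mrad^-2)")
  }
  if (!is.numeric(sigma_r2) || length(sigma_r2) != 1L || sigma_r2 <= 0) {
    stop("sigma_r2 must be a single positive number (mrad^2)")
  }
  dims <- dim(as.array(Omega))
  flags <- array(FLAG_OK, dims)
  a <- array(0, dims)
  so2 <- array(NA_real_, dims)
  bad <- !is.finite(Omega) | Omega <= 0
  flags[bad] <- FLAG_BAD_INPUT

  if (gamma == 0) {
    # exact pure-phase limit of the negative-root branch
    so2[!bad] <- sigma_r2 * (Omega[!bad] - 1)
    flags[!bad & so2 < 0] <- FLAG_NONPHYSICAL
    return(structure(list(a = a, sigma_o2 = so2, flags = flags),
                     class = "hybrid_solution"))
  }

  G <- gamma * sigma_r2 * Omega
  B <- 2 * G + 1
  C <- G - gamma * sigma_r2
  disc <- B^2 - 4 * (G - 0.5) * C
  neg <- !bad & disc < 0
  flags[neg] <- FLAG_NEG_DISCRIMINANT
  ok <- !bad & !neg
  a[ok] <- 2 * C[ok] / (B[ok] + sqrt(disc[ok]))
  so2[ok | neg] <- (a[ok | neg] + a[ok | neg]^2 / 2) / gamma
  flags[flags == FLAG_OK & (a < 0 | a > 1 | so2 < 0)] <- FLAG_NONPHYSICAL
  structure(list(a = a, sigma_o2 = so2, flags = flags),
            class = "hybrid_solution")
}

#' Pixelwise hybrid attenuation/dark-field retrieval
#'
#' Forms `Omega = (Ir/Is)^2` per pixel, converts the reference variance to
#' angular units, solves the hybrid quadratic with [hybrid_solve()] and
#' returns the hybrid dark-field map (the tomographic reconstruction input)
#' together with the attenuated fraction `a` and the implied transmission
#' `t = 1 - a`.
#'
#' @param Ir_map,Is_map reference and sample peak-intensity maps (equal
#'   shape).
#' @param gamma a `gamma_model`, or a single number in mrad⁻².
#' @param sigma_r2_um2 global reference curve variance (µm²); converted to
#'   mrad² with the geometry `g`.
#' @param g an [ei_geometry()].
#' @return A `hybrid_signals` list: `a`, `t`, `sigma_o2` (µm² at the
#'   detector-mask plane), `sigma_o2_mrad2`, `flags`, `gamma`.
#' @export
hybrid_retrieve <- function(Ir_map, Is_map, gamma, sigma_r2_um2 = 81,
                            g = ei_geometry()) {
  if (inherits(gamma, "gamma_model")) gamma <- gamma$gamma
  if (!all(dim(as.array(Ir_map)) == dim(as.array(Is_map)))) {
    stop("Ir and Is maps must share a shape")
  }
  omega <- (Ir_map / Is_map)^2
  sr2_mrad2 <- variance_um2_to_mrad2(sigma_r2_um2, g)
  sol <- hybrid_solve(omega, gamma, sr2_mrad2)
  structure(list(a = sol$a, t = 1 - sol$a,
                 sigma_o2 = variance_mrad2_to_um2(sol$sigma_o2, g),
                 sigma_o2_mrad2 = sol$sigma_o2,
                 flags = sol$flags, gamma = gamma),
            class = "hybrid_signals")
}
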