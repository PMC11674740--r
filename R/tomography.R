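#' Assemble a sinogram from retrieved per-angle maps
#'
#' Takes one detector row of a set of retrieved projection maps indexed
#' `(dither, angle)` and interleaves the dither steps into a single
#' high-resolution detector row per angle: dither step `d` occupies fine
#' columns `d, d + n_dither, d + 2*n_dither, ...`, undoing the sub-sampling
#' of [simulate_frames()]. The effective detector pitch of the sinogram is
#' the pixel pitch divided by the dither count.
#'
#' @param maps numeric array indexed `(row, col, dither, angle)` — e.g. one
#'   signal channel of a retrieval — or `(col, dither, angle)` for a single
#'   row.
#' @param angles_deg projection angles (degrees), strictly increasing, one
#'   per angle index.
#' @param signal_kind one of `"minus_log_t"`, `"sigma_o2"`, `"hybrid"`;
#'   recorded so the reconstruction can label its output units.
#' @param pitch_um fine-column pitch of the sinogram (µm), i.e. detector
#'   pixel pitch / n_dither.
#' @param row detector row to extract when `maps` has 4 dimensions.
#' @return A `sinogram`: list with `data` (angle x fine column), `angles_deg`,
#'   `signal_kind`, `pitch_um`.
#' @export
build_sinogram <- function(maps, angles_deg, signal_kind =
                             c("minus_log_t", "sigma_o2", "hybrid"),
                           pitch_um, row = 1L) {
  signal_kind <- match.arg(signal_kind)
  d <- dim(maps)
  if (length(d) == 4L) {
    maps <- maps[row, , , , drop = TRUE]
    if (d[3] == 1L || d[4] == 1L) {
      maps <- array(maps, d[2:4])  # keep dropped singleton dims
    }
    d <- dim(maps)
  }
  if (length(d) != 3L) stop("maps must be a (row, col, dither, angle) or (col, dither, angle) array")
  nc <- d[1]; ndith <- d[2]; nang <- d[3]
  if (length(angles_deg) != nang) stop("angles_deg does not match the angle extent")
  if (nang >= 2L && any(diff(angles_deg) <= 0)) {
    stop("angles must be strictly increasing")
  }
  if (anyNA(maps)) stop("missing values in projection maps (missing angle?)")
  sino <- matrix(NA_real_, nang, nc * ndith)
  for (a in seq_len(nang)) {
    fine <- numeric(nc * ndith)
    for (dd in seq_len(ndith)) {
      fine[seq.int(dd, nc * ndith, by = ndith)] <- maps[, dd, a]
    }
    sino[a, ] <- fine
  }
  structure(list(data = sino, angles_deg = as.numeric(angles_deg),
                 signal_kind = signal_kind, pitch_um = pitch_um),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d angles x %d columns, signal = %s, pitch = %g um\n",
              nrow(x$data), ncol(x$data), x$signal_kind, x$pitch_um))
  invisible(x)
}

# fft frequencies in cycles/sample, matching numpy's fftfreq layout
fft_freq <- function(n) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / n
}

# Ramp (and apodized) filters on the padded DFT grid.  The ramp is built
# from its sampled real-space impulse response (Ram-Lak), not as |f| on the
# DFT grid: sampling |f| directly under-weights the lowest frequencies and
# biases the reconstruction's mean level.
fbp_filter <- function(n, filter = c("ramp", "shepp-logan")) {
  filter <- match.arg(filter)
  idx <- c(seq.int(0L, n / 2), seq.int(n / 2 - 1L, 1L))  # |lag| on circular grid
  h_spatial <- numeric(n)
  h_spatial[1] <- 0.25
  odd <- idx %% 2 == 1
  h_spatial[odd] <- -1 / (pi * idx[odd])^2
  h <- 2 * Re(stats::fft(h_spatial))
  if (filter == "shepp-logan") {
    f <- fft_freq(n)
    s <- rep(1, n)
    nz <- f != 0
    s[nz] <- sin(pi * f[nz]) / (pi * f[nz])
    h <- h * s
  }
  h
}

#' Filtered back projection of a parallel-beam sinogram
#'
#' Standard FBP: each projection is ramp-filtered in the Fourier domain
#' (zero-padded to the next power of two), then smeared back across the
#' image grid with linear interpolation. Scans covering 360° are folded to
#' 180° by averaging opposing rays (with the detector axis reversed), so
#' redundant data is used rather than double-counted. The output is scaled
#' by the detector pitch so reconstructed values are per-unit-length
#' coefficients: 1/m for `minus_log_t` sinograms, µrad²/m for dark-field or
#' hybrid sinograms.
#'
#' @param s a [build_sinogram()] object with at least 2 angles spanning at
#'   least 180° (including the implicit closing interval).
#' @param filter `"ramp"` (default) or `"shepp-logan"`.
#' @return A `recon_slice`: list with `data` (n x n matrix, n = detector
#'   columns), `pixel_pitch_um`, `signal_kind`, `units`.
#' @export
fbp_reconstruct <- function(s, filter = c("ramp", "shepp-logan")) {
  filter <- match.arg(filter)
  stopifnot(inherits(s, "sinogram"))
  ang <- s$angles_deg
  data <- s$data
  if (length(ang) < 2L) stop("need at least 2 projection angles")
  dtheta <- mean(diff(ang))
  span <- (max(ang) - min(ang)) + dtheta
  if (span < 180 - 1e-6) stop("angular coverage below 180 degrees")

  if (span > 180 + 1e-6) {
    # fold opposing rays: p(theta + 180, s) = p(theta, -s)
    hi <- ang >= min(ang) + 180
    fold <- data
    keep <- !hi
    for (i in which(hi)) {
      j <- which(abs(ang - (ang[i] - 180)) < 1e-9)
      if (length(j) == 1L) {
        fold[j, ] <- (fold[j, ] + rev(data[i, ])) / 2
      } else {
        keep[i] <- TRUE  # no partner at theta - 180; keep as its own view
      }
    }
    data <- fold[keep, , drop = FALSE]
    ang <- ang[keep]
    ang <- ifelse(ang >= min(ang) + 180, ang - 180, ang)
    o <- order(ang)
    ang <- ang[o]; data <- data[o, , drop = FALSE]
  }

  n <- ncol(data)
  nang <- nrow(data)
  npad <- 2^ceiling(log2(max(64L, 2L * n)))
  h <- fbp_filter(npad, filter)
  filtered <- matrix(0, nang, n)
  for (i in seq_len(nang)) {
    p <- c(data[i, ], rep(0, npad - n))
    filtered[i, ] <- Re(stats::fft(stats::fft(p) * h, inverse = TRUE))[1:n] / npad
  }

  ctr <- (n + 1) / 2
  xy <- seq_len(n) - ctr
  xg <- matrix(xy, n, n, byrow = TRUE)   # columns: x
  yg <- matrix(xy, n, n)                 # rows: y (z axis at angle 0)
  recon <- matrix(0, n, n)
  th <- ang * pi / 180
  for (i in seq_len(nang)) {
    # detector coordinate of each pixel for this view; at angle 0 a pixel
    # maps to its own column, matching the row-sum forward projection
    sc <- xg * cos(th[i]) - yg * sin(th[i]) + ctr
    i0 <- floor(sc)
    fr <- sc - i0
    ok0 <- i0 >= 1 & i0 <= n
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= n
    v <- matrix(0, n, n)
    v[ok0] <- v[ok0] + filtered[i, i0[ok0]] * (1 - fr[ok0])
    v[ok1] <- v[ok1] + filtered[i, i0[ok1] + 1] * fr[ok1]
    recon <- recon + v
  }
  recon <- recon * pi / (2 * nang)
  # per-pixel-length -> per-metre
  recon <- recon / (s$pitch_um * 1e-6)
  units <- switch(s$signal_kind,
                  minus_log_t = "1/m",
                  sigma_o2 = "urad^2/m",
                  hybrid = "hybrid (eps-equivalent, urad^2/m)")
  structure(list(data = recon, pixel_pitch_um = s$pitch_um,
                 signal_kind = s$signal_kind, units = units,
                 filter = filter),
            class = "recon_slice")
}

#' @export
print.recon_slice <- function(x, ...) {
  cat(sprintf("recon_slice: %dx%d, %s [%s], filter = %s\n",
              nrow(x$data), ncol(x$data), x$signal_kind, x$units, x$filter))
  invisible(x)
}

#' Circular interior mask
#'
#' @param n grid size, or a `recon_slice`.
#' @param radius_px mask radius in pixels.
#' @param center centre (row, col); default grid centre.
#' @return Logical n x n matrix.
#' @export
interior_disk_mask <- function(n, radius_px, center = NULL) {
  if (inherits(n, "recon_slice")) n <- nrow(n$data)
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  r <- matrix(seq_len(n) - center[1], n, n)
  c <- matrix(seq_len(n) - center[2], n, n, byrow = TRUE)
  r^2 + c^2 <= radius_px^2
}

#' Cupping metric of a reconstructed slice
#'
#' Quantifies the radial bias ("cupping") of a reconstruction inside a
#' homogeneous object: the interior mask is split at half its equivalent
#' radius into a central disk and a peripheral annulus, and the metric is
#' `(mean(central) - mean(peripheral)) / mean(interior)`. A flat interior
#' gives 0; center-bright reconstructions are positive, center-dark
#' negative. Nonlinear (non-line-integral) projection signals, e.g. hybrid
#' retrieval with a misspecified gamma, show up as a growing |metric|.
#'
#' @param slice a `recon_slice` or plain matrix.
#' @param interior_mask logical mask lying inside the object (e.g.
#'   [interior_disk_mask()] at ~80% of the object radius).
#' @return Dimensionless cupping metric.
#' @export
cupping_metric <- function(slice, interior_mask) {
  data <- if (inherits(slice, "recon_slice")) slice$data else slice
  if (!is.logical(interior_mask) || !all(dim(interior_mask) == dim(data))) {
    stop("interior_mask must be a logical matrix matching the slice")
  }
  if (!any(interior_mask)) stop("empty interior mask")
  n <- nrow(data)
  idx <- which(interior_mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r_eq <- sqrt(sum(interior_mask) / pi)
  rho <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  vals <- data[interior_mask]
  central <- rho <= r_eq / 2
  if (!any(central) || all(central)) stop("mask too small to split")
  m_all <- mean(vals)
  if (m_all == 0) stop("interior mean is zero")
  (mean(vals[central]) - mean(vals[!central])) / m_all
}
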