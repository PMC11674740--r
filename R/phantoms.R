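#' Linear attenuation coefficient from the imaginary refractive index part
#'
#' For a complex refractive index `n = 1 - delta + i*beta`, the linear
#' attenuation coefficient is `mu = 4*pi*beta/lambda` with `lambda = hc/E`.
#'
#' @param beta imaginary part of the refractive index (dimensionless, >= 0).
#' @param energy_kev photon energy in keV (> 0). The package's design energy
#'   is the Mo K-alpha line, 17.48 keV, matching the molybdenum-anode source
#'   the printed delta/beta values refer to.
#' @return Attenuation coefficient in 1/m.
#' @examples
#' mu_from_beta(5.35e-12, 17.48)   # foamed polystyrene, ~0.95 /m
#' @export
mu_from_beta <- function(beta, energy_kev = 17.48) {
  if (!is.numeric(energy_kev) || any(energy_kev <= 0)) {
    stop("energy must be positive")
  }
  if (any(beta < 0)) stop("beta must be >= 0")
  lambda_m <- 1.23984198e-9 / energy_kev  # hc = 1239.84198 eV nm
  4 * pi * beta / lambda_m
}

#' Material definition
#'
#' A material couples the refractive-index parts `delta` (phase) and `beta`
#' (attenuation) at a design energy with a linear scattering coefficient
#' `eps` (angular dark-field variance accrued per unit path length,
#' µrad²/m). The attenuation coefficient `mu` (1/m) is derived from `beta`
#' via [mu_from_beta()] unless given directly. `eps` may be given directly
#' or derived from a known attenuation-to-scattering ratio
#' `gamma` (mrad⁻²) as `eps = mu / gamma`.
#'
#' @param name label.
#' @param delta refractive decrement (dimensionless).
#' @param beta imaginary refractive-index part (dimensionless); optional if
#'   `mu_per_m` is given.
#' @param energy_kev design energy (keV).
#' @param eps_urad2_per_m linear scattering coefficient (µrad²/m).
#' @param gamma_mrad2inv attenuation-to-scattering ratio (mrad⁻²), used to
#'   derive `eps` when `eps_urad2_per_m` is missing.
#' @param mu_per_m attenuation coefficient (1/m); overrides the value
#'   derived from `beta`.
#' @return An object of class `ei_material` with fields `name`, `delta`,
#'   `beta`, `energy_kev`, `mu_per_m`, `eps_urad2_per_m`.
#' @export
material <- function(name, delta = 0, beta = NULL, energy_kev = 17.48,
                     eps_urad2_per_m = NULL, gamma_mrad2inv = NULL,
                     mu_per_m = NULL) {
  if (is.null(mu_per_m)) {
    if (is.null(beta)) stop("supply beta or mu_per_m")
    mu_per_m <- mu_from_beta(beta, energy_kev)
  }
  if (is.null(eps_urad2_per_m)) {
    if (is.null(gamma_mrad2inv)) stop("supply eps_urad2_per_m or gamma_mrad2inv")
    if (gamma_mrad2inv <= 0) stop("gamma must be > 0 to derive eps")
    eps_urad2_per_m <- mrad2_to_urad2(mu_per_m / gamma_mrad2inv)
  }
  if (mu_per_m < 0 || eps_urad2_per_m < 0) stop("mu and eps must be >= 0")
  structure(list(name = name, delta = delta, beta = beta,
                 energy_kev = energy_kev, mu_per_m = mu_per_m,
                 eps_urad2_per_m = eps_urad2_per_m),
            class = "ei_material")
}

#' Built-in material presets
#'
#' Reads the material registry shipped in `inst/extdata/materials.json`:
#' `"polystyrene"` and `"paper"` carry the printed refractive-index parts of
#' the two wedge phantoms at the Mo K-alpha design energy;
#' `"benchmark_scatterer"` is a synthetic weakly attenuating material used
#' for the homogeneous-cylinder cupping benchmark.
#'
#' @param name preset name.
#' @return An `ei_material`.
#' @export
material_preset <- function(name) {
  path <- system.file("extdata", "materials.json", package = "eidark",
                      mustWork = TRUE)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!name %in% names(reg)) {
    stop("unknown material preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  args <- reg[[name]]
  args$comment <- NULL
  do.call(material, c(list(name = name), args))
}

#' Attenuation-to-scattering ratio of a material
#'
#' `gamma = mu / eps` with `mu` in 1/m and `eps` in mrad²/m, so `gamma` is in
#' mrad⁻². Constant gamma across a sample is the macroscopic-homogeneity
#' assumption behind the hybrid retrieval.
#'
#' @param m an `ei_material`.
#' @return gamma in mrad⁻².
#' @export
material_gamma <- function(m) {
  stopifnot(inherits(m, "ei_material"))
  eps_mrad2 <- urad2_to_mrad2(m$eps_urad2_per_m)
  if (eps_mrad2 <= 0) stop("material has no scattering (eps = 0)")
  m$mu_per_m / eps_mrad2
}

#' Voxel phantom
#'
#' A 2-D slice phantom holding voxel maps of the linear attenuation
#' coefficient `mu` (1/m), the linear scattering coefficient `eps`
#' (µrad²/m) and the refractive decrement `delta` (dimensionless) on a
#' square grid. Rows are the beam axis `z` at projection angle 0; columns
#' are the phase-sensitive `x` axis.
#'
#' @param mu,eps,delta equally shaped numeric matrices.
#' @param voxel_pitch_um voxel pitch (µm).
#' @return An object of class `ei_phantom`.
#' @export
phantom <- function(mu, eps, delta = NULL, voxel_pitch_um) {
  stopifnot(is.matrix(mu), is.matrix(eps))
  if (is.null(delta)) delta <- matrix(0, nrow(mu), ncol(mu))
  if (!all(dim(mu) == dim(eps)) || !all(dim(mu) == dim(delta))) {
    stop("mu, eps and delta maps must share a shape")
  }
  if (any(mu < 0) || any(eps < 0)) stop("mu and eps must be >= 0")
  if (!is.numeric(voxel_pitch_um) || voxel_pitch_um <= 0) {
    stop("voxel_pitch_um must be > 0")
  }
  structure(list(mu = mu, eps = eps, delta = delta,
                 voxel_pitch_um = voxel_pitch_um),
            class = "ei_phantom")
}

#' Uniform cylinder phantom
#'
#' A homogeneous disk of the given material centred on a square grid: the
#' canonical test object for signal-linearity and cupping studies, since its
#' reconstruction should be flat inside when the projected signal is a true
#' line integral.
#'
#' @param m an `ei_material`.
#' @param radius_mm cylinder radius (mm).
#' @param grid grid size (pixels per side).
#' @param fov_mm field of view (mm); default leaves a 25% margin around the
#'   cylinder.
#' @return An `ei_phantom`.
#' @export
make_cylinder <- function(m, radius_mm, grid = 128L, fov_mm = 2.5 * radius_mm) {
  stopifnot(inherits(m, "ei_material"), radius_mm > 0)
  if (2 * radius_mm > fov_mm) stop("cylinder does not fit the field of view")
  pitch_um <- fov_mm * 1000 / grid
  ctr <- (grid + 1) / 2
  idx <- seq_len(grid) - ctr
  r2 <- outer(idx^2, idx^2, `+`) * (pitch_um / 1000)^2
  inside <- r2 <= radius_mm^2
  phantom(mu = inside * m$mu_per_m, eps = inside * m$eps_urad2_per_m,
          delta = inside * m$delta, voxel_pitch_um = pitch_um)
}

# Rotate an image about its centre by angle_deg (counter-clockwise positive)
# with bilinear interpolation, zero outside the grid.  Used by the
# parallel-beam projector: projecting at angle theta equals rotating the
# phantom by -theta and summing along rows.
rotate_image <- function(img, angle_deg) {
  if (angle_deg %% 360 == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr) - cr, nr, nc)
  c <- matrix(seq_len(nc) - cc, nr, nc, byrow = TRUE)
  # source coordinates: rotate output grid by -angle
  sr <- cos(th) * r + sin(th) * c + cr
  sc <- -sin(th) * r + cos(th) * c + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
  matrix(v, nr, nc)
}

#' Parallel-beam line integrals of a phantom
#'
#' Forward-projects the phantom at one viewing angle and converts the line
#' integrals into per-column sample signals: `t = exp(-integral of mu)`,
#' `sigma_o2 = integral of eps` (µrad², returned in µm² at the detector-mask
#' plane via the geometry), and the refraction shift from the transverse
#' derivative of the projected `delta`-thickness (central differences,
#' one-sided at the borders).
#'
#' @param ph an `ei_phantom`.
#' @param angle_deg viewing angle in degrees (counter-clockwise positive).
#' @param g an [ei_geometry()] used for unit conversions.
#' @return A [sample_signals()] map of shape `1 x ncol(ph$mu)`.
#' @export
line_integrals <- function(ph, angle_deg, g = ei_geometry()) {
  stopifnot(inherits(ph, "ei_phantom"))
  pitch_m <- ph$voxel_pitch_um * 1e-6
  pr_mu <- colSums(rotate_image(ph$mu, -angle_deg)) * pitch_m      # dimensionless
  pr_eps <- colSums(rotate_image(ph$eps, -angle_deg)) * pitch_m    # urad^2
  pr_delta <- colSums(rotate_image(ph$delta, -angle_deg)) * pitch_m # m
  n <- length(pr_mu)
  grad <- numeric(n)
  if (n >= 3L) {
    grad[2:(n - 1)] <- (pr_delta[3:n] - pr_delta[1:(n - 2)]) / (2 * pitch_m)
  }
  if (n >= 2L) {
    grad[1] <- (pr_delta[2] - pr_delta[1]) / pitch_m
    grad[n] <- (pr_delta[n] - pr_delta[n - 1]) / pitch_m
  }
  # grad is the refraction angle in rad; shift at the detector-mask plane
  dx_um <- angle_to_shift(grad * 1e6, g)
  sample_signals(t = matrix(exp(-pr_mu), 1),
                 dx_ref = matrix(dx_um, 1),
                 sigma_o2 = matrix(angular_to_variance(pr_eps, g), 1))
}

#' Wedge phantom sample-signal maps
#'
#' A uniform-material wedge whose beam-path thickness rises linearly from 0
#' to `max_thickness_mm` across the columns of the map. Per column,
#' `t = exp(-mu * thickness)`, `sigma_o2 = eps * thickness` (converted to
#' µm² at the detector-mask plane) and the refraction shift follows from the
#' constant thickness gradient `delta * max_thickness / x_extent`.
#'
#' @param m an `ei_material`.
#' @param x_extent_mm lateral extent of the wedge along `x` (mm).
#' @param max_thickness_mm beam-path thickness at the thick edge (mm).
#' @param n_columns number of columns in the map.
#' @param n_rows number of (identical) rows, for ROI-averaged profiles.
#' @param g an [ei_geometry()] for unit conversions.
#' @return A [sample_signals()] map with attributes `thickness_mm`
#'   (per-column thickness) and `material`.
#' @export
make_wedge <- function(m, x_extent_mm = 16, max_thickness_mm = 16,
                       n_columns = 256L, n_rows = 1L, g = ei_geometry()) {
  stopifnot(inherits(m, "ei_material"), x_extent_mm > 0, max_thickness_mm > 0,
            n_columns >= 2L)
  thick_mm <- max_thickness_mm * (seq_len(n_columns) - 1) / (n_columns - 1)
  thick_m <- thick_mm / 1000
  t_col <- exp(-m$mu_per_m * thick_m)
  so2_urad2 <- m$eps_urad2_per_m * thick_m
  theta_rad <- m$delta * (max_thickness_mm / x_extent_mm)
  dx_um <- angle_to_shift(theta_rad * 1e6, g)
  rep_rows <- function(v) matrix(v, n_rows, n_columns, byrow = TRUE)
  s <- sample_signals(t = rep_rows(t_col),
                      dx_ref = rep_rows(rep(dx_um, n_columns)),
                      sigma_o2 = rep_rows(angular_to_variance(so2_urad2, g)))
  attr(s, "thickness_mm") <- thick_mm
  attr(s, "material") <- m$name
  s
}
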