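# Shared fixtures: the laboratory geometry preset, the typical reference
# curve (A = 200, sigma_r2 = 81 um^2) and small synthetic objects.

lab_geometry <- function() ei_geometry()

lab_ic <- function(...) ic_params(A = 200, x0 = 0, sigma_r2 = 81, ...)

# nine IC sampling points centred on the peak
ic_points <- function(p = lab_ic(), n = 9L, half_span = 13.5) {
  p$x0 + seq(-half_span, half_span, length.out = n)
}

# a moderately attenuating uniform wedge (t: 1 -> 0.9 across columns), the
# regime where the second-order hybrid expansion is accurate
moderate_wedge <- function(n_columns = 64L, g = lab_geometry()) {
  m <- material_preset("paper")
  make_wedge(m, x_extent_mm = 14.8,
             max_thickness_mm = -log(0.9) / m$mu_per_m * 1000,
             n_columns = n_columns, g = g)
}

# conventional retrieval of a single noise-free curve per wedge column,
# fitted against exact curve samples
fit_wedge_columns <- function(w, p = lab_ic(), positions = ic_points(p)) {
  vapply(seq_len(ncol(w$t)), function(j) {
    s <- sample_signals(w$t[1, j], w$dx_ref[1, j], w$sigma_o2[1, j],
                        physical = FALSE)
    I <- vapply(positions, function(x) ic_sample(x, p, s), numeric(1))
    f <- fit_illumination_curve(I, positions)
    c(t = f$area / p$A, dx = f$center - p$x0, so2 = f$width2 - p$sigma_r2)
  }, numeric(3))
}

# homogeneous weakly attenuating cylinder used by the cupping benchmarks:
# centre-chord attenuated fraction ~0.1, gamma = 200 mrad^-2
benchmark_cylinder <- function(grid = 128L) {
  m <- material_preset("benchmark_scatterer")
  list(material = m,
       phantom = make_cylinder(m, radius_mm = 20, grid = grid, fov_mm = 60),
       fov_mm = 60, radius_mm = 20)
}

# hybrid sinogram of a phantom acquired at the IC peak with gamma `gam`
hybrid_sinogram <- function(ph, angles, gam, p = lab_ic(), g = lab_geometry(),
                            pitch_um) {
  Ir <- ic_reference(p$x0, p)
  rows <- t(vapply(angles, function(a) {
    s <- line_integrals(ph, a, g)
    Is <- ic_sample(p$x0, p, s)
    h <- hybrid_retrieve(array(Ir, dim(Is)), Is, gam, p$sigma_r2, g)
    variance_to_angular(h$sigma_o2[1, ], g)
  }, numeric(ncol(ph$mu))))
  build_sinogram(rows2cube(rows), angles, signal_kind = "hybrid",
                 pitch_um = pitch_um)
}

# reshape an (angle x col) matrix into the (col, dither=1, angle) cube that
# build_sinogram expects
rows2cube <- function(rows) {
  array(t(rows), dim = c(ncol(rows), 1L, nrow(rows)))
}
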