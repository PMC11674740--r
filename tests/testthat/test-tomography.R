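test_that("dither interleave reassembles the fine-grid ground truth", {
  p <- lab_ic()
  g <- lab_geometry()
  nd <- 8L
  w0 <- moderate_wedge(8L * nd)         # fine grid: 64 columns
  # scatter-only version: the pure-phase retrieval assumes t = 1
  w <- sample_signals(matrix(1, 1, 8L * nd), w0$dx_ref, w0$sigma_o2,
                      physical = FALSE)
  st <- simulate_frames(w, p, ic_positions = 0, n_dither = nd,
                        angles_deg = 0)
  # single-shot retrieval per dither step, then interleave
  Ir <- ic_reference(0, p)
  so2 <- array(NA_real_, c(8, nd, 1))
  for (d in seq_len(nd)) {
    Is <- st$data[1, d, 1, 1, ]
    so2[, d, 1] <- single_shot_purephase(rep(Ir, 8), Is, p$sigma_r2)$sigma_o2
  }
  sino <- build_sinogram(so2, 0, signal_kind = "sigma_o2",
                         pitch_um = g$pixel_pitch_um / nd)
  expect_equal(ncol(sino$data), 64L)
  # neglecting refraction, the wedge has dx != 0; use truth with dx = 0
  truth <- w$sigma_o2[1, ]
  expect_equal(as.vector(sino$data[1, ]), truth, tolerance = 2e-4)
  # n_dither = 1 is a pass-through
  one <- build_sinogram(array(1:5, c(5, 1, 1)), 0, "sigma_o2", 50)
  expect_equal(as.vector(one$data), as.numeric(1:5))
  # inconsistent metadata errors
  expect_error(build_sinogram(so2, c(0, 1), "sigma_o2", 50), "angle")
  so2[2, 3, 1] <- NA
  expect_error(build_sinogram(so2, 0, "sigma_o2", 50), "missing")
  expect_error(build_sinogram(array(1, c(4, 1, 3)), c(0, 2, 1), "sigma_o2", 50),
               "increasing")
})

test_that("FBP reconstructs a centred point and respects linearity", {
  n <- 64L
  angles <- seq(0, 180, length.out = 33)[1:32]
  mkph <- function(mu) phantom(mu, 0 * mu, voxel_pitch_um = 500)
  g <- lab_geometry()
  proj <- function(ph) {
    rows <- t(vapply(angles, function(a) -log(line_integrals(ph, a, g)$t[1, ]),
                     numeric(n)))
    build_sinogram(rows2cube(rows), angles, "minus_log_t", 500)
  }
  mu <- matrix(0, n, n); mu[32, 32] <- 10
  sl <- fbp_reconstruct(proj(mkph(mu)))
  pk <- which(sl$data == max(sl$data), arr.ind = TRUE)
  expect_equal(as.integer(pk), c(32L, 32L))
  # near-symmetric PSF about the peak (discrete angular sampling)
  mx <- max(sl$data)
  expect_lt(abs(sl$data[32, 28] - sl$data[32, 36]), 0.02 * mx)
  expect_lt(abs(sl$data[28, 32] - sl$data[36, 32]), 0.02 * mx)
  # all-zero sinogram reconstructs to zero
  z <- proj(mkph(matrix(0, n, n)))
  expect_equal(max(abs(fbp_reconstruct(z)$data)), 0)
  # linearity: recon(s1 + s2) = recon(s1) + recon(s2)
  mu2 <- matrix(0, n, n); mu2[20:40, 10:30] <- 1
  s1 <- proj(mkph(mu)); s2 <- proj(mkph(mu2))
  s12 <- s1; s12$data <- s1$data + s2$data
  expect_equal(fbp_reconstruct(s12)$data,
               fbp_reconstruct(s1)$data + fbp_reconstruct(s2)$data,
               tolerance = 1e-10)
  # insufficient coverage errors
  short <- build_sinogram(rows2cube(matrix(1, 8, n)),
                          seq(0, 70, by = 10), "minus_log_t", 500)
  expect_error(fbp_reconstruct(short), "coverage")
  one_view <- build_sinogram(rows2cube(matrix(1, 1, n)), 0, "minus_log_t", 500)
  expect_error(fbp_reconstruct(one_view), "2 projection")
})

test_that("FBP of a uniform cylinder recovers mu quantitatively", {
  g <- lab_geometry()
  bench <- benchmark_cylinder(128L)
  angles <- seq(0, 180, length.out = 65)[1:64]
  rows <- t(vapply(angles,
                   function(a) -log(line_integrals(bench$phantom, a, g)$t[1, ]),
                   numeric(128L)))
  sino <- build_sinogram(rows2cube(rows), angles, "minus_log_t",
                         bench$fov_mm * 1000 / 128)
  for (flt in c("ramp", "shepp-logan")) {
    sl <- fbp_reconstruct(sino, filter = flt)
    mask <- interior_disk_mask(sl, radius_px = 0.8 * 20 / 60 * 128)
    expect_equal(mean(sl$data[mask]), bench$material$mu_per_m,
                 tolerance = 0.02)
  }
  # 360-degree scans fold onto the 180-degree result
  angles360 <- seq(0, 360, length.out = 65)[1:64]
  rows360 <- t(vapply(angles360,
                      function(a) -log(line_integrals(bench$phantom, a, g)$t[1, ]),
                      numeric(128L)))
  sino360 <- build_sinogram(rows2cube(rows360), angles360, "minus_log_t",
                            bench$fov_mm * 1000 / 128)
  sl180 <- fbp_reconstruct(sino)
  sl360 <- fbp_reconstruct(sino360)
  mask <- interior_disk_mask(sl180, radius_px = 0.8 * 20 / 60 * 128)
  expect_equal(mean(sl360$data[mask]), mean(sl180$data[mask]),
               tolerance = 5e-3)
})

test_that("cupping metric is zero for flat interiors and validates masks", {
  flat <- matrix(5, 32, 32)
  mask <- interior_disk_mask(32, 10)
  expect_equal(cupping_metric(flat, mask), 0)
  # a centre-bright dome gives a positive metric, a dip negative
  r2 <- outer((1:32 - 16.5)^2, (1:32 - 16.5)^2, `+`)
  dome <- 5 + pmax(0, 1 - r2 / 100)
  expect_gt(cupping_metric(dome, mask), 0)
  expect_lt(cupping_metric(10 - dome, mask), 0)
  expect_error(cupping_metric(flat, matrix(FALSE, 32, 32)), "empty")
  expect_error(cupping_metric(flat, mask[1:16, ]), "matching")
})

test_that("gamma misspecification produces monotonically growing cupping", {
  # scaled-down benchmark (64^2 grid, 32 views); the acceptance suite runs
  # the full-size version
  g <- lab_geometry()
  p <- lab_ic()
  bench <- benchmark_cylinder(64L)
  gam_true <- material_gamma(bench$material)
  angles <- seq(0, 180, length.out = 33)[1:32]
  pitch <- bench$fov_mm * 1000 / 64
  mask <- interior_disk_mask(64L, radius_px = 0.8 * 20 / 60 * 64)
  cup <- vapply(c(1, 2, 5, 10), function(k) {
    sl <- fbp_reconstruct(hybrid_sinogram(bench$phantom, angles, gam_true * k,
                                          p, g, pitch))
    abs(cupping_metric(sl, mask))
  }, numeric(1))
  expect_lt(cup[1], 0.02)
  expect_true(all(diff(cup) > 0))
})
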