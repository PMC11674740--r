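test_that("reference curve peak, tails and area behave as a normalized Gaussian", {
  p <- lab_ic()
  expect_equal(ic_reference(0, p), 200 / sqrt(2 * pi * 81), tolerance = 1e-12)
  expect_equal(ic_reference(0, p), 8.866, tolerance = 1e-4)
  expect_equal(ic_reference(c(-1e4, 1e4), p), c(0, 0))
  off <- ic_params(offset = 0.7)
  expect_equal(ic_reference(1e4, off), 0.7)
  # area under the curve is A (numerical quadrature oracle)
  area <- stats::integrate(function(x) ic_reference(x, p), -Inf, Inf)$value
  expect_equal(area, p$A, tolerance = 1e-8)
})

test_that("sample curve reduces to the reference for an identity sample", {
  p <- lab_ic()
  x <- seq(-30, 30, length.out = 101)
  expect_equal(ic_sample(x, p, sample_signals()), ic_reference(x, p))
})

test_that("peak drops from shift, broadening and attenuation match closed forms", {
  p <- lab_ic()
  ref_peak <- ic_reference(0, p)
  # pure 2 um refraction shift: ~2.44% drop ("around 2.5%")
  shift <- ic_sample(0, p, sample_signals(dx_ref = 2))
  expect_equal(as.numeric(shift / ref_peak), exp(-4 / (2 * 81)),
               tolerance = 1e-12)
  expect_equal(as.numeric(1 - shift / ref_peak), 0.0244, tolerance = 1e-2)
  # pure broadening sigma_o2 = 4 um^2: sqrt(81/85)
  broad <- ic_sample(0, p, sample_signals(sigma_o2 = 4))
  expect_equal(as.numeric(broad / ref_peak), sqrt(81 / 85), tolerance = 1e-12)
  # pure attenuation: factor t
  att <- ic_sample(0, p, sample_signals(t = 0.8))
  expect_equal(as.numeric(att / ref_peak), 0.8, tolerance = 1e-12)
})

test_that("peak_pair evaluates both curves at the alignment position", {
  p <- lab_ic()
  idp <- peak_pair(p, sample_signals())
  expect_equal(idp$reference, as.numeric(idp$sample))
  pp <- peak_pair(p, sample_signals(dx_ref = 2))
  expect_equal(pp$reference, 8.866, tolerance = 1e-4)
  pp$sample <- as.numeric(pp$sample)
  expect_equal(as.numeric(pp$sample), 8.650, tolerance = 1e-4)
  # scaling A scales both peaks linearly
  p2 <- ic_params(A = 3 * p$A, x0 = p$x0, sigma_r2 = p$sigma_r2)
  pp2 <- peak_pair(p2, sample_signals(dx_ref = 2))
  expect_equal(pp2$reference, 3 * pp$reference)
  expect_equal(as.numeric(pp2$sample), 3 * pp$sample)
})

test_that("sample-curve area is conserved as t * A", {
  p <- lab_ic()
  for (tt in c(1, 0.6)) {
    s <- sample_signals(t = tt, dx_ref = 1.5, sigma_o2 = 12)
    area <- stats::integrate(function(x) ic_sample(x, p, s), -Inf, Inf)$value
    expect_equal(area, tt * p$A, tolerance = 1e-8)
  }
})

test_that("simulated frames reproduce the reference curve for an empty phantom", {
  p <- lab_ic()
  pos <- ic_points(p)
  st <- simulate_frames(empty_signals(2, 8), p, pos, n_dither = 2)
  for (i in seq_along(pos)) {
    expect_equal(unname(st$data[i, , , , ]),
                 array(ic_reference(pos[i], p), c(2, 2, 4)))
  }
})

test_that("poisson frames are seed-reproducible with the correct mean", {
  p <- lab_ic()
  s <- sample_signals(0.9, 0, 5)
  a <- simulate_frames(s, p, ic_points(p), noise = "poisson", seed = 11,
                       exposure_scale = 20)
  b <- simulate_frames(s, p, ic_points(p), noise = "poisson", seed = 11,
                       exposure_scale = 20)
  expect_identical(a$data, b$data)
  expect_error(simulate_frames(s, p, 0, noise = "gaussian"), "arg")
  # sampling-theory oracle: mean of many repeats of one pixel within 3 SE
  n_rep <- 10000L
  st <- simulate_frames(s, p, rep(0, n_rep), noise = "poisson", seed = 4,
                        exposure_scale = 20)
  lam <- as.numeric(ic_sample(0, p, s)) * 20
  se <- sqrt(lam / n_rep)
  expect_lt(abs(mean(st$data) - lam), 3 * se)
  # counting statistics: variance ~ mean
  expect_lt(abs(var(as.vector(st$data)) / lam - 1), 5 / sqrt(n_rep / 2))
})

test_that("sensitivity curves peak and vanish where the physics says", {
  p <- lab_ic()
  grid <- seq(-30, 30, length.out = 241)
  sens <- sensitivity_curves(p, grid)
  i0 <- which(grid == 0)
  # attenuation sensitivity is highest at the peak
  expect_equal(which.max(sens$attenuation), i0)
  # refraction sensitivity nearly vanishes at the peak (exactly zero only in
  # the small-shift limit, where the change follows the curve gradient)
  expect_lt(sens$refraction[i0], 0.1)
  tiny <- sensitivity_curves(p, grid,
                             small_signals = list(t = 0.95, dx_ref = 0.01,
                                                  sigma_o2 = 4))
  expect_lt(tiny$refraction[i0], 2e-3)
  expect_lte(abs(which.min(tiny$refraction[abs(grid) < 15]) -
                 which(grid[abs(grid) < 15] == 0)), 1L)
  # scattering sensitivity is symmetric about the peak
  expect_equal(sens$scattering, rev(sens$scattering), tolerance = 1e-12)
  # the printed normalization makes the attenuation channel flat
  sref <- sensitivity_curves(p, grid, normalize = "reference")
  expect_equal(diff(range(sref$attenuation)), 0, tolerance = 1e-12)
})
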