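test_that("Gaussian fits recover exact curves and report failures", {
  p <- lab_ic()
  pos <- ic_points(p)
  f <- fit_illumination_curve(ic_reference(pos, p), pos)
  expect_true(f$converged)
  expect_equal(f$area, 200, tolerance = 1e-8)
  expect_equal(f$center, 0, tolerance = 1e-7)
  expect_equal(f$width2, 81, tolerance = 1e-8)
  # additive offset recovered when fitted
  poff <- ic_params(A = 200, sigma_r2 = 81, offset = 0.5)
  foff <- fit_illumination_curve(ic_reference(pos, poff), pos,
                                 with_offset = TRUE)
  expect_true(foff$converged)
  expect_equal(foff$offset, 0.5, tolerance = 1e-6)
  expect_equal(foff$width2, 81, tolerance = 1e-6)
  # degenerate flat curve: flagged, not an error
  flat <- fit_illumination_curve(rep(3, 9), pos)
  expect_false(flat$converged)
  expect_true(is.na(flat$width2))
  expect_error(fit_illumination_curve(1:3, pos[1:3]), "at least 4")
  expect_error(fit_illumination_curve(rep(1, 5), c(1, 1, 2, 3, 4)), "distinct")
})

test_that("conventional retrieval maps fit parameters to the three channels", {
  mk <- function(area, center, width2) {
    list(area = matrix(area), center = matrix(center),
         width2 = matrix(width2), flags = NULL)
  }
  idm <- conventional_retrieve(mk(200, 0, 81), mk(200, 0, 81))
  expect_equal(as.numeric(idm$t), 1)
  expect_equal(as.numeric(idm$dx_ref), 0)
  expect_equal(as.numeric(idm$sigma_o2), 0)
  expect_equal(as.integer(idm$flags), retrieval_flags()[["ok"]])
  # width increase of 4 um^2 is the dark-field signal
  w <- conventional_retrieve(mk(200, 0, 81), mk(200, 0, 85))
  expect_equal(as.numeric(w$sigma_o2), 4)
  # area ratio is the transmission
  a <- conventional_retrieve(mk(200, 0, 81), mk(100, 0.3, 81))
  expect_equal(as.numeric(a$t), 0.5)
  expect_equal(as.numeric(a$dx_ref), 0.3)
  # zero reference area is flagged, not propagated as Inf
  z <- conventional_retrieve(mk(0, 0, 81), mk(100, 0, 81))
  expect_equal(as.integer(z$flags), retrieval_flags()[["bad_input"]])
  expect_true(is.na(z$t))
  expect_error(conventional_retrieve(mk(1, 0, 1),
                                     list(area = matrix(1, 2, 2),
                                          center = matrix(0, 2, 2),
                                          width2 = matrix(1, 2, 2))),
               "match")
})

test_that("single-shot pure-phase retrieval inverts the peak ratio", {
  ss0 <- single_shot_purephase(8.9, 8.9, 81)
  expect_equal(as.numeric(ss0$sigma_o2), 0)
  # worked numbers: Ir = 8.866, Is = 8.655 -> ~4 um^2
  ss <- single_shot_purephase(8.866, 8.655, 81)
  expect_equal(as.numeric(ss$sigma_o2), 4.0, tolerance = 1e-2)
  # noise pushing Is above Ir gives a negative, flagged, preserved value
  neg <- single_shot_purephase(8.8, 9.0, 81)
  expect_lt(as.numeric(neg$sigma_o2), 0)
  expect_equal(as.integer(neg$flags), retrieval_flags()[["nonphysical"]])
  bad <- single_shot_purephase(8.8, 0, 81)
  expect_true(is.na(bad$sigma_o2))
  expect_equal(as.integer(bad$flags), retrieval_flags()[["bad_input"]])
})

test_that("gamma estimation matches hand values and phantom ground truth", {
  t_map <- matrix(0.9, 4, 4)
  so2 <- matrix(0.001, 4, 4)
  gm <- estimate_gamma(t_map, so2)
  expect_equal(gm$gamma, -log(0.9) / 0.001, tolerance = 1e-12)
  expect_equal(gm$gamma, 105.36, tolerance = 1e-4)
  expect_equal(gm$n_pixels, 16L)
  expect_error(estimate_gamma(matrix(1, 4, 4), so2), "mask")
  gm2 <- estimate_gamma(t_map, so2, method = "median_of_ratios")
  expect_equal(gm2$gamma, gm$gamma)
  expect_error(estimate_gamma(t_map, -so2), "not positive")
})

test_that("hybrid quadratic solves the worked example and its limits", {
  # forward-generated example: sigma_r2 = 0.003 mrad^2, gamma = 200 mrad^-2,
  # a_true = 0.2 gives Omega = 2.135417 and the quadratic
  # 0.78125 a^2 - 3.5625 a + 0.68125 = 0 with negative-root solution 0.2
  sol <- hybrid_solve(2.1354166666666667, 200, 0.003)
  expect_equal(as.numeric(sol$a), 0.2, tolerance = 1e-9)
  G <- 200 * 0.003 * 2.1354166666666667
  resid <- (G - 0.5) * sol$a^2 - (2 * G + 1) * sol$a + (G - 200 * 0.003)
  expect_lt(abs(resid), 1e-10)
  expect_equal(as.numeric(sol$sigma_o2), (0.2 + 0.02) / 200, tolerance = 1e-9)
  # no signal: Omega = 1
  s1 <- hybrid_solve(1, 150, 0.003)
  expect_equal(as.numeric(s1$a), 0)
  expect_equal(as.numeric(s1$sigma_o2), 0)
  # gamma = 0 is the exact pure-phase limit
  s0 <- hybrid_solve(1.5, 0, 0.003)
  expect_equal(as.numeric(s0$a), 0)
  expect_equal(as.numeric(s0$sigma_o2), 0.003 * 0.5)
  # negative discriminant (strong noise, Omega << 1) is flagged with a = 0
  nd <- hybrid_solve(0.01, 1 / 0.003, 0.003)
  expect_equal(as.integer(nd$flags),
               retrieval_flags()[["negative_discriminant"]])
  expect_equal(as.numeric(nd$a), 0)
  expect_error(hybrid_solve(2, -1, 0.003), "gamma")
})

test_that("hybrid round trip is exact over the (a, gamma, sigma_r2) grid", {
  grid_a <- seq(0.01, 0.6, length.out = 10)
  grid_g <- c(1, 20, 138, 200, 551, 1000, 5000, 2e4, 1e5, 1e6)
  grid_s <- c(2e-4, 1e-3, 0.003, 0.005, 0.01, 0.02, 0.05, 0.1, 0.5, 1)
  worst <- 0
  for (a in grid_a) for (gam in grid_g) for (sr2 in grid_s) {
    so2 <- (a + a^2 / 2) / gam
    om <- (sr2 + so2) / ((1 - a)^2 * sr2)
    sol <- hybrid_solve(om, gam, sr2)
    worst <- max(worst, abs(as.numeric(sol$a) - a))
    # the positive-root branch is unphysical on the same grid
    G <- gam * sr2 * om
    disc <- (2 * G + 1)^2 - 4 * (G - 0.5) * (G - gam * sr2)
    other <- ((2 * G + 1) + sqrt(disc)) / (2 * (G - 0.5))
    expect_true(other < 0 || other > 1)
  }
  expect_lt(worst, 1e-9)
})

test_that("the chosen branch is continuous down to gamma = 0", {
  sr2 <- 0.003
  om <- 1.8
  pure <- sr2 * (om - 1)
  gams <- 10^seq(2, -6, by = -1)
  so2 <- vapply(gams, function(g) as.numeric(hybrid_solve(om, g, sr2)$sigma_o2),
                numeric(1))
  # monotone approach to the pure-phase value, reached at gamma = 0
  expect_true(all(diff(abs(so2 - pure)) < 0))
  expect_equal(so2[length(so2)], pure, tolerance = 1e-6)
  expect_equal(as.numeric(hybrid_solve(om, 0, sr2)$sigma_o2), pure)
})

test_that("second-order expansion error stays within the stated domain", {
  rel_err <- function(a) abs((a + a^2 / 2) - (-log(1 - a))) / (-log(1 - a))
  expect_lt(max(vapply(seq(0.005, 0.1, by = 0.005), rel_err, numeric(1))),
            0.005)
  expect_lt(rel_err(0.6), 0.16)
})

test_that("neglected refraction masquerades as ~4.1 um^2 of scattering", {
  p <- lab_ic()
  pp <- peak_pair(p, sample_signals(dx_ref = 2))
  ss <- single_shot_purephase(pp$reference, pp$sample, p$sigma_r2)
  # closed form: sigma_r2 * (exp(dx^2 / sigma_r2) - 1)
  expect_equal(as.numeric(ss$sigma_o2), 81 * (exp(4 / 81) - 1),
               tolerance = 1e-10)
  expect_equal(as.numeric(ss$sigma_o2), 4.1, tolerance = 1e-2)
})

test_that("hybrid retrieval equals pure-phase retrieval when gamma is 0", {
  p <- lab_ic()
  g <- lab_geometry()
  w <- moderate_wedge(16)
  scatter_only <- sample_signals(matrix(1, 1, 16), matrix(0, 1, 16),
                                 w$sigma_o2, physical = FALSE)
  Is <- ic_sample(p$x0, p, scatter_only)
  Ir <- array(ic_reference(p$x0, p), dim(Is))
  hy <- hybrid_retrieve(Ir, Is, 0, p$sigma_r2, g)
  ss <- single_shot_purephase(Ir, Is, p$sigma_r2)
  expect_equal(hy$sigma_o2, ss$sigma_o2, tolerance = 1e-10)
  expect_equal(hy$t, array(1, dim(Is)))
  # gamma_model objects are accepted in place of numbers
  hy2 <- hybrid_retrieve(Ir, Is, gamma_model(0), p$sigma_r2, g)
  expect_equal(hy2$sigma_o2, hy$sigma_o2)
})
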