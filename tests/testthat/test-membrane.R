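test_that("empirical porosity follows the liquid-displacement identity", {
  g0 <- gravimetric_measurement(10, 10, rho_membrane = 1.2,
                                blank_apparent_porosity = 0)
  expect_equal(empirical_porosity(g0), 0)
  g <- gravimetric_measurement(10, 12, rho_membrane = 1.2,
                               blank_apparent_porosity = 0)
  expect_equal(empirical_porosity(g),
               (2 / 0.789) / ((2 / 0.789) + (10 / 1.2)), tolerance = 1e-12)
  gb <- gravimetric_measurement(10, 12, rho_membrane = 1.2,
                                blank_apparent_porosity = 0.093)
  expect_equal(empirical_porosity(gb), empirical_porosity(g) - 0.093,
               tolerance = 1e-12)
  expect_error(gravimetric_measurement(10, 9),
               class = "lungstretch_invalid_measurement")
})

test_that("empirical porosity is invariant to rescaling both masses", {
  for (k in c(0.5, 2, 10)) {
    a <- gravimetric_measurement(10, 12, rho_membrane = 1.2,
                                 blank_apparent_porosity = 0.05)
    b <- gravimetric_measurement(10 * k, 12 * k, rho_membrane = 1.2,
                                 blank_apparent_porosity = 0.05)
    expect_equal(empirical_porosity(a), empirical_porosity(b),
                 tolerance = 1e-12)
  }
})

test_that("dense membranes clamp corrected porosity at zero with a warning", {
  g <- gravimetric_measurement(10, 10.2, rho_membrane = 1.2,
                               blank_apparent_porosity = 0.093)
  expect_warning(p <- empirical_porosity(g), "clamping")
  expect_identical(p, 0)
})

test_that("theoretical porosity is the gelatin volume fraction", {
  expect_equal(theoretical_porosity(membrane_composition(9.35, 0)), 0)
  opt <- theoretical_porosity(membrane_composition(9.35, 6.34, 1.145, 1.30))
  expect_equal(opt, (6.34 / 1.30) / (6.34 / 1.30 + 9.35 / 1.145),
               tolerance = 1e-12)
  expect_equal(opt, 0.374, tolerance = 0.002)
  # equal phase volumes give 0.5 by symmetry
  expect_equal(theoretical_porosity(membrane_composition(1.145, 1.30,
                                                         1.145, 1.30)), 0.5)
  expect_error(membrane_composition(0, 0),
               class = "lungstretch_invalid_argument")
})

test_that("both porosity estimators are bounded and monotone in composition", {
  gels <- seq(0.5, 20, by = 0.5)
  p_gel <- vapply(gels, function(g)
    theoretical_porosity(membrane_composition(9.35, g)), numeric(1))
  expect_true(all(p_gel >= 0 & p_gel <= 1))
  expect_true(all(diff(p_gel) > 0))
  pcls <- seq(0.5, 20, by = 0.5)
  p_pcl <- vapply(pcls, function(p)
    theoretical_porosity(membrane_composition(p, 6.34)), numeric(1))
  expect_true(all(diff(p_pcl) < 0))
})

test_that("assay normalisations reproduce their worked examples", {
  expect_equal(wst1_viability(0.1, 0.1, 0.6), 0)
  expect_equal(wst1_viability(0.6, 0.1, 0.6), 100)
  expect_equal(wst1_viability(0.55, 0.10, 0.60), 90)
  expect_error(wst1_viability(0.5, 0.6, 0.6),
               class = "lungstretch_invalid_argument")

  expect_equal(ldh_release(0, 1.5, 600), 0)
  expect_equal(ldh_release(2, 1.5, 600), 0.5)
  expect_equal(ldh_release(2, 3, 600), 2 * ldh_release(2, 1.5, 600))
  expect_error(ldh_release(2, 1.5, 0),
               class = "lungstretch_invalid_argument")

  expect_equal(suppressWarnings(teer(60, 60, 1.3)), 0)
  expect_equal(teer(450, 60, 1.3), 507)
  expect_equal(teer(450, 60, 2.6), 2 * teer(450, 60, 1.3))
  expect_warning(teer(50, 60, 1.3), "non-positive")

  expect_equal(proliferation_fold(4.3e5, 1.5e5), 2.9)
  expect_equal(proliferation_fold(3e5, 3e5), 1.0)
  expect_equal(proliferation_fold(3e5, 1e5), 3.0)
})

test_that("the volume-weighted membrane density is mass over phase volume", {
  comp <- membrane_composition(9.35, 6.34, 1.145, 1.30)
  expect_equal(membrane_density(comp),
               (9.35 + 6.34) / (9.35 / 1.145 + 6.34 / 1.30),
               tolerance = 1e-12)
})
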