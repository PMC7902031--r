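test_that("reservoir overpressure converts to displaced volume in both modes", {
  cfg <- beta_chamber()
  expect_equal(volume_from_reservoir_pressure(98, cfg), 0)
  expect_equal(volume_from_reservoir_pressure(99.5, cfg), 1.5 * 30 / 98,
               tolerance = 1e-12)
  expect_equal(volume_from_reservoir_pressure(99.5, cfg, "isothermal"),
               30 * (1 - 98 / 99.5), tolerance = 1e-12)
  expect_warning(v <- volume_from_reservoir_pressure(97.5, cfg),
                 "clamped")
  expect_identical(v, 0)
  expect_error(volume_from_reservoir_pressure(-1, cfg),
               class = "lungstretch_invalid_argument")
})

test_that("linearized and isothermal modes agree to first order in dP/P0", {
  cfg <- beta_chamber()
  p2 <- seq(98.1, 101, by = 0.1)
  lin <- volume_from_reservoir_pressure(p2, cfg)
  iso <- volume_from_reservoir_pressure(p2, cfg, "isothermal")
  expect_true(all(abs(lin - iso) / lin <= (p2 - 98) / 98 + 1e-12))
})

test_that("bulge-test forward model behaves as the thin-membrane relation", {
  geom <- beta_geom()
  expect_equal(transmembrane_pressure_from_modulus(0, 0.78, geom), 0)
  # direct evaluation at 10% deflection: x = 0.1, t = 5e-4 cm, a = 1.26 cm
  x <- 0.1
  expected <- 780 * 4 * x * 5e-4 / (3 * 1.26 * (x^2 + 1)) *
    (1 - 1 / (1 + x^2)^3)
  expect_equal(transmembrane_pressure_from_modulus(0.126, 0.78, geom),
               expected, tolerance = 1e-12)
  # about 1.2 Pa, i.e. 1.2e-3 kPa
  expect_equal(expected, 1.2e-3, tolerance = 0.01)
  # linear in E
  expect_equal(transmembrane_pressure_from_modulus(0.126, 1.56, geom),
               2 * transmembrane_pressure_from_modulus(0.126, 0.78, geom))
  # strictly increasing in delta_h on (0, a]
  h <- seq(1e-3, 1.26, length.out = 200)
  expect_true(all(diff(transmembrane_pressure_from_modulus(h, 0.78, geom)) > 0))
  expect_error(transmembrane_pressure_from_modulus(0.1, -1, geom),
               class = "lungstretch_invalid_argument")
})

test_that("modulus inversion is the exact inverse of the forward model", {
  geom <- beta_geom()
  set.seed(7)
  E <- runif(100, 0.1, 10)
  h <- runif(100, 0.01, 1.2)
  for (i in seq_along(E)) {
    dpp <- transmembrane_pressure_from_modulus(h[i], E[i], geom)
    expect_equal(modulus_from_state(dpp, h[i], geom), E[i],
                 tolerance = 1e-10)
  }
  expect_error(modulus_from_state(0.001, 0, geom),
               class = "lungstretch_singular_state")
  expect_error(modulus_from_state(-0.001, 0.1, geom),
               class = "lungstretch_invalid_argument")
})

test_that("pressure trace constructor enforces its invariants", {
  expect_error(pressure_trace(1, 98, 98), class = "lungstretch_invalid_argument")
  expect_error(pressure_trace(c(0, 0), c(98, 98), c(98, 98)),
               class = "lungstretch_invalid_argument")
  expect_error(pressure_trace(c(0, 1), c(98, -1), c(98, 98)),
               class = "lungstretch_invalid_argument")
  tr <- pressure_trace(c(0, 1), c(98, 99), c(98, 98.5))
  expect_s3_class(tr, "pressure_trace")
})

test_that("noiseless synthetic traces are analysed back to their parameters", {
  spec <- simulation_spec(seed = 1, duration = 60, sample_rate = 25,
                          target_linear_strain = 0.10, frequency = 0.33,
                          true_E = 0.78)
  rep <- analyze_trace(simulate_pressure_trace(spec), beta_geom(),
                       beta_chamber())
  expect_equal(rep$frequency_hz, 0.33, tolerance = 0.01)
  expect_equal(rep$peak_linear_strain, 0.10, tolerance = 0.01)
  expect_equal(rep$modulus_mpa, 0.78, tolerance = 0.01)
  expect_gte(rep$cycle_count, 18)
  expect_true(all(rep$per_cycle$peak_linear_strain >= 0))
  expect_false(any(rep$per_cycle$over_stretch))
  # averaging estimator agrees with the peak estimator on clean data
  rep2 <- analyze_trace(simulate_pressure_trace(spec), beta_geom(),
                        beta_chamber(),
                        stretch_options(e_estimator = "mean_above_half_peak"))
  expect_equal(rep2$modulus_mpa, 0.78, tolerance = 0.01)
})

test_that("over-stretch cycles are flagged above the strain thresholds", {
  spec <- simulation_spec(seed = 2, duration = 30,
                          target_linear_strain = 0.20)
  rep <- analyze_trace(simulate_pressure_trace(spec))
  expect_true(all(rep$per_cycle$over_stretch))
  expect_false(any(rep$per_cycle$beyond_membrane_limit))
  spec_hi <- simulation_spec(seed = 2, duration = 30,
                             target_linear_strain = 0.30)
  rep_hi <- analyze_trace(simulate_pressure_trace(spec_hi))
  expect_true(all(rep_hi$per_cycle$beyond_membrane_limit))
})

test_that("a flat trace raises an insufficient-cycles error with samples", {
  t <- seq(0, 10, by = 0.1)
  tr <- pressure_trace(t, rep(98, length(t)), rep(98, length(t)))
  err <- tryCatch(analyze_trace(tr, beta_geom(), beta_chamber()),
                  lungstretch_insufficient_cycles = function(e) e)
  expect_s3_class(err, "lungstretch_insufficient_cycles")
  expect_true(is.data.frame(err$samples))
  expect_true(all(err$samples$linear_strain == 0))
})

test_that("clamped samples (P2 < P0 sensor drift) are flagged, not dropped", {
  spec <- simulation_spec(seed = 3, duration = 30, pressure_noise_sd = 0.02)
  rep <- suppressWarnings(analyze_trace(simulate_pressure_trace(spec)))
  expect_gt(rep$n_clamped, 0)
  expect_equal(nrow(rep$samples), 30 * 25 + 1)
  expect_true(all(rep$samples$delta_v_ml >= 0))
})
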