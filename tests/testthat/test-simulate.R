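test_that("pressure-trace generation is deterministic under a fixed seed", {
  spec <- simulation_spec(seed = 9, duration = 20, pressure_noise_sd = 0.01)
  a <- simulate_pressure_trace(spec)
  b <- simulate_pressure_trace(spec)
  expect_identical(a$p1_kpa, b$p1_kpa)
  expect_identical(a$p2_kpa, b$p2_kpa)
  c <- simulate_pressure_trace(simulation_spec(seed = 10, duration = 20,
                                               pressure_noise_sd = 0.01))
  expect_false(identical(a$p2_kpa, c$p2_kpa))
})

test_that("zero strain yields a flat trace at ambient pressure", {
  spec <- simulation_spec(seed = 1, duration = 10, target_linear_strain = 0)
  tr <- simulate_pressure_trace(spec)
  expect_true(all(tr$p1_kpa == 98))
  expect_true(all(tr$p2_kpa == 98))
})

test_that("undersampled generation is rejected as aliasing", {
  expect_error(simulate_pressure_trace(
    simulation_spec(seed = 1, sample_rate = 3, frequency = 0.33)),
    class = "lungstretch_aliasing")
})

test_that("generator substreams are independent of one another", {
  spec <- simulation_spec(seed = 5, duration = 10, pressure_noise_sd = 0.01)
  tr1 <- simulate_pressure_trace(spec)
  # drawing from another stream in between must not perturb the trace stream
  invisible(simulate_fluorescence_experiment(spec))
  tr2 <- simulate_pressure_trace(spec)
  expect_identical(tr1$p2_kpa, tr2$p2_kpa)
  expect_false(substream_seed(5, "pressure") == substream_seed(5, "fluorescence"))
})

test_that("noiseless fluorescence round trip recovers the true fraction", {
  spec <- simulation_spec(seed = 1,
                          fluorescence = list(relative_noise_sd = 0))
  sim <- simulate_fluorescence_experiment(spec)
  curve <- fit_standard_curve(sim$curve$conc_ug_ml, sim$curve$fluor_au,
                              sim$blanks)
  res <- translocated_fraction(mean(sim$basal), curve,
                               sim$truth$basal_volume_ml,
                               sim$truth$delivered_mass_ug)
  expect_equal(res$fraction_percent, 30, tolerance = 1e-9)
})

test_that("a zero true fraction reads below the limit of detection", {
  spec <- simulation_spec(seed = 3,
                          fluorescence = list(true_fraction_percent = 0,
                                              relative_noise_sd = 0.02))
  sim <- simulate_fluorescence_experiment(spec)
  curve <- fit_standard_curve(sim$curve$conc_ug_ml, sim$curve$fluor_au,
                              sim$blanks)
  res <- translocated_fraction(mean(sim$basal), curve,
                               sim$truth$basal_volume_ml,
                               sim$truth$delivered_mass_ug)
  expect_true(res$below_lod)
})

test_that("LOD-equivalent fractions sit near the assay detection limits", {
  # bioreactor configuration: 10.5 ug delivered into 16 mL -> LOD of a few %
  beta <- simulate_fluorescence_experiment(simulation_spec(seed = 4))
  cb <- fit_standard_curve(beta$curve$conc_ug_ml, beta$curve$fluor_au,
                           beta$blanks)
  lod_beta <- translocated_fraction(mean(beta$basal), cb, 16,
                                    10.5)$lod_fraction_percent
  expect_gt(lod_beta, 1)
  expect_lt(lod_beta, 6)
  # static insert: ~10 ug onto the insert, ~2.5 mL basal medium -> LOD ~ 1%
  tw <- simulate_fluorescence_experiment(simulation_spec(
    seed = 4, fluorescence = list(delivered_mass_ug = 10,
                                  basal_volume_ml = 2.5)))
  ct <- fit_standard_curve(tw$curve$conc_ug_ml, tw$curve$fluor_au, tw$blanks)
  lod_tw <- translocated_fraction(mean(tw$basal), ct, 2.5,
                                  10)$lod_fraction_percent
  expect_gt(lod_tw, 0.1)
  expect_lt(lod_tw, 2)
  expect_lt(lod_tw, lod_beta)
})

test_that("gravimetric generation closes the porosity loop", {
  spec <- simulation_spec(seed = 1)
  sims <- simulate_gravimetric(spec)
  expect_length(sims, 3)
  for (g in sims) {
    expect_equal(empirical_porosity(g), 0.153, tolerance = 1e-12)
  }
  # zero porosity with zero blank -> soaked equals dry mass
  z <- simulate_gravimetric(simulation_spec(
    seed = 1, gravimetric = list(true_porosity = 0,
                                 blank_apparent_porosity = 0)))
  expect_equal(z[[1]]$mass_soaked, z[[1]]$mass_dry)
})

test_that("noisy gravimetric porosity is recovered without bias", {
  spec <- simulation_spec(seed = 21,
                          gravimetric = list(n = 50L, noise_sd_mg = 0.05))
  sims <- simulate_gravimetric(spec)
  p <- vapply(sims, empirical_porosity, numeric(1))
  se <- stats::sd(p) / sqrt(length(p))
  expect_lt(abs(mean(p) - 0.153), 3 * se)
})

test_that("intensity stacks encode the configured uptake contrast", {
  sim <- simulate_intensity_stacks(simulation_spec(seed = 1))
  expect_length(sim$stretched, 5)
  fold <- uptake_fold_change(uptake_intensity(sim$stretched)$mean_au,
                             uptake_intensity(sim$static)$mean_au)
  expect_equal(fold, 2.4)
  eq <- simulate_intensity_stacks(simulation_spec(
    seed = 1, intensity = list(fold = 1)))
  expect_equal(uptake_fold_change(uptake_intensity(eq$stretched)$mean_au,
                                  uptake_intensity(eq$static)$mean_au), 1.0)
  a <- simulate_intensity_stacks(simulation_spec(
    seed = 2, intensity = list(noise_sd_au = 5)))
  b <- simulate_intensity_stacks(simulation_spec(
    seed = 2, intensity = list(noise_sd_au = 5)))
  expect_identical(a$stretched, b$stretched)
})
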