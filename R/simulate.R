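# Synthetic instrument-data generators. Each generator is the exact forward
# model of its paired analysis stage: pressure traces via the cap geometry
# and bulge-test relations, fluorescence via the standard-curve line,
# gravimetric masses via the liquid-displacement identity, image-field
# intensities as Gaussian field means. Noiseless closed loops are exact;
# noisy ones are unbiased within Monte-Carlo error. A single global seed
# fans out to per-stream substreams (see [substream_seed()]).

#' Simulation specification
#'
#' One configuration object for all generators. Defaults reproduce the study
#' conditions: 10% peak linear strain at 0.33 Hz (light-exercise breathing),
#' membrane modulus 0.78 MPa, 60 s traces sampled at 25 Hz; a translocation
#' experiment at 30% of the delivered dose (about 2.1 ug cm^-2 on 5 cm^2,
#' i.e. 10.5 ug, into 16 mL of circulating basal medium); gravimetric
#' porosity 0.153; and a 2.4-fold stretched/static uptake contrast over 5
#' imaging fields.
#'
#' @param seed Integer global seed; fixed seed implies bit-identical output.
#' @param duration Trace duration in s.
#' @param sample_rate Sampling rate in Hz; must be at least 10x `frequency`.
#' @param target_linear_strain Peak linear strain of the stretch waveform.
#' @param frequency Stretch frequency in Hz.
#' @param true_E Membrane Young's modulus in MPa used by the forward model.
#' @param pressure_noise_sd Additive Gaussian sensor noise SD in kPa,
#'   applied independently to both channels.
#' @param geometry A [membrane_geometry()].
#' @param chamber A [chamber_config()].
#' @param waveform `"raised_cosine"` (membrane returns to flat each cycle,
#'   matching positive-pressure actuation from a relaxed state) or
#'   `"sinusoid"` (same mean and amplitude, quarter-period phase shift).
#' @param fluorescence List of fluorescence-experiment parameters:
#'   `true_fraction_percent`, `delivered_mass_ug`, `basal_volume_ml`,
#'   `slope_au_per_ug_ml`, `intercept_au`, `relative_noise_sd`,
#'   `curve_concentrations`, `n_blanks`, `n_replicates`.
#' @param gravimetric List: `true_porosity`, `n`, `mass_dry_mg`,
#'   `rho_membrane`, `noise_sd_mg`, `blank_apparent_porosity`.
#' @param intensity List: `mean_static_au`, `fold`, `n_fields`, `noise_sd_au`.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(seed = 1L,
                            duration = 60,
                            sample_rate = 25,
                            target_linear_strain = 0.10,
                            frequency = 0.33,
                            true_E = 0.78,
                            pressure_noise_sd = 0,
                            geometry = membrane_geometry(),
                            chamber = chamber_config(),
                            waveform = c("raised_cosine", "sinusoid"),
                            fluorescence = list(),
                            gravimetric = list(),
                            intensity = list()) {
  waveform <- match.arg(waveform)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar(target_linear_strain, "target_linear_strain", nonneg = TRUE)
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  stopifnot_scalar(true_E, "true_E", positive = TRUE)
  stopifnot_scalar(pressure_noise_sd, "pressure_noise_sd", nonneg = TRUE)
  stopifnot(inherits(geometry, "membrane_geometry"),
            inherits(chamber, "chamber_config"))

  fl <- utils::modifyList(list(
    true_fraction_percent = 30.0,
    delivered_mass_ug = 10.5,
    basal_volume_ml = 16,
    slope_au_per_ug_ml = 100,
    intercept_au = 30,
    relative_noise_sd = 0.02,
    curve_concentrations = c(0.025, 0.05, 0.1, 0.25, 0.5, 1),
    n_blanks = 6L,
    n_replicates = 3L
  ), fluorescence)

  gv <- utils::modifyList(list(
    true_porosity = 0.153,
    n = 3L,
    mass_dry_mg = 10,
    rho_membrane = membrane_density(membrane_composition()),
    noise_sd_mg = 0,
    blank_apparent_porosity = 0.093
  ), gravimetric)

  it <- utils::modifyList(list(
    mean_static_au = 100,
    fold = 2.4,
    n_fields = 5L,
    noise_sd_au = 0
  ), intensity)

  structure(list(seed = as.integer(seed), duration = duration,
                 sample_rate = sample_rate,
                 target_linear_strain = target_linear_strain,
                 frequency = frequency, true_E = true_E,
                 pressure_noise_sd = pressure_noise_sd,
                 geometry = geometry, chamber = chamber,
                 waveform = waveform,
                 fluorescence = fl, gravimetric = gv, intensity = it),
            class = "simulation_spec")
}

#' Simulate a dual-sensor pressure trace
#'
#' Forward model of the monitored chamber. Per time step the apex deflection
#' follows the stretch waveform (raised cosine by default,
#' `delta_h(t) = a * eps * (1 - cos(2 pi f t)) / 2`), the displaced volume
#' follows the cap geometry, the reservoir pressure follows the linearized
#' gas law `P2 = P0 + dV * P0 / V0`, and the apical pressure adds the
#' bulge-test transmembrane pressure at the configured modulus. Independent
#' Gaussian sensor noise is added to both channels.
#'
#' @param spec A [simulation_spec()].
#' @return A [pressure_trace()] with attribute `"truth"` holding the
#'   generating parameters.
#' @export
#' @examples
#' tr <- simulate_pressure_trace(simulation_spec(seed = 7, duration = 20))
simulate_pressure_trace <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$sample_rate < 10 * spec$frequency) {
    ls_stop(sprintf(
      "sample_rate (%g Hz) must be at least 10x the stretch frequency (%g Hz)",
      spec$sample_rate, spec$frequency), "aliasing")
  }
  geom <- spec$geometry
  cfg <- spec$chamber
  t <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  amp <- geom$radius_a * spec$target_linear_strain
  phase <- 2 * pi * spec$frequency * t
  dh <- switch(spec$waveform,
               raised_cosine = amp * (1 - cos(phase)) / 2,
               sinusoid = amp * (1 + sin(phase)) / 2)
  dv <- cap_volume(dh, geom$radius_a)
  p2 <- cfg$ambient_P0 + dv * cfg$ambient_P0 / cfg$headspace_V0
  p1 <- p2 + spec$true_E * bulge_pressure_coefficient(dh, geom)
  if (spec$pressure_noise_sd > 0) {
    set.seed(substream_seed(spec$seed, "pressure"))
    p1 <- p1 + stats::rnorm(length(t), sd = spec$pressure_noise_sd)
    p2 <- p2 + stats::rnorm(length(t), sd = spec$pressure_noise_sd)
  }
  out <- pressure_trace(t, p1, p2)
  attr(out, "truth") <- list(frequency = spec$frequency,
                             peak_linear_strain = spec$target_linear_strain,
                             E = spec$true_E)
  out
}

#' Simulate a fluorescence translocation experiment
#'
#' Generates a standard-curve table, blank readings and basal-compartment
#' readings. All readings follow the calibration line
#' `F = intercept + slope * concentration` with Gaussian noise whose SD is
#' `relative_noise_sd` times the noiseless reading. The basal concentration
#' is derived from the configured true translocated fraction, basal volume
#' and delivered mass, so a noiseless round trip through
#' [fit_standard_curve()] and [translocated_fraction()] recovers the true
#' fraction exactly.
#'
#' @param spec A [simulation_spec()]; uses its `fluorescence` block and seed.
#' @return A list with `curve` (data.frame `conc_ug_ml`, `fluor_au`),
#'   `blanks` (numeric), `basal` (numeric readings), and `truth`.
#' @export
simulate_fluorescence_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fl <- spec$fluorescence
  set.seed(substream_seed(spec$seed, "fluorescence"))
  noisy <- function(clean) {
    if (fl$relative_noise_sd > 0) {
      clean + stats::rnorm(length(clean), sd = fl$relative_noise_sd * abs(clean))
    } else clean
  }
  conc <- fl$curve_concentrations
  curve <- data.frame(
    conc_ug_ml = conc,
    fluor_au = noisy(fl$intercept_au + fl$slope_au_per_ug_ml * conc)
  )
  blanks <- noisy(rep(fl$intercept_au, fl$n_blanks))
  basal_conc <- (fl$true_fraction_percent / 100) * fl$delivered_mass_ug /
    fl$basal_volume_ml
  basal <- noisy(rep(fl$intercept_au + fl$slope_au_per_ug_ml * basal_conc,
                     fl$n_replicates))
  list(curve = curve, blanks = blanks, basal = basal,
       truth = list(fraction_percent = fl$true_fraction_percent,
                    basal_concentration_ug_ml = basal_conc,
                    delivered_mass_ug = fl$delivered_mass_ug,
                    basal_volume_ml = fl$basal_volume_ml))
}

#' Simulate gravimetric liquid-displacement measurements
#'
#' Soaked masses are generated from the liquid-displacement identity so that
#' the raw (uncorrected) porosity equals the configured true porosity plus
#' the blank apparent porosity; [empirical_porosity()] on noiseless output
#' therefore returns the true porosity exactly. Weighing noise is added to
#' the soaked mass.
#'
#' @param spec A [simulation_spec()]; uses its `gravimetric` block and seed.
#' @return A list of [gravimetric_measurement()] objects with attribute
#'   `"truth"`.
#' @export
simulate_gravimetric <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  gv <- spec$gravimetric
  raw <- gv$true_porosity + gv$blank_apparent_porosity
  if (raw >= 1) {
    ls_stop("true_porosity + blank must be < 1", "invalid_argument")
  }
  set.seed(substream_seed(spec$seed, "gravimetric"))
  v_m <- gv$mass_dry_mg / gv$rho_membrane
  m_etoh <- raw / (1 - raw) * v_m * 0.789
  out <- lapply(seq_len(gv$n), function(i) {
    soaked <- gv$mass_dry_mg + m_etoh +
      if (gv$noise_sd_mg > 0) stats::rnorm(1, sd = gv$noise_sd_mg) else 0
    gravimetric_measurement(gv$mass_dry_mg, max(soaked, gv$mass_dry_mg),
                            rho_membrane = gv$rho_membrane,
                            blank_apparent_porosity = gv$blank_apparent_porosity)
  })
  attr(out, "truth") <- list(porosity = gv$true_porosity)
  out
}

#' Simulate per-field uptake intensity summaries for two conditions
#'
#' Per-field background-subtracted mean intensities are drawn as
#' `N(mean_condition, noise_sd)`, with the stretched-condition mean set to
#' `fold` times the static mean.
#'
#' @param spec A [simulation_spec()]; uses its `intensity` block and seed.
#' @return A list with numeric vectors `stretched` and `static` (per-field
#'   means) and `truth`.
#' @export
simulate_intensity_stacks <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  it <- spec$intensity
  set.seed(substream_seed(spec$seed, "intensity"))
  draw <- function(mu) {
    mu + if (it$noise_sd_au > 0) {
      stats::rnorm(it$n_fields, sd = it$noise_sd_au)
    } else rep(0, it$n_fields)
  }
  list(stretched = draw(it$mean_static_au * it$fold),
       static = draw(it$mean_static_au),
       truth = list(fold = it$fold, mean_static_au = it$mean_static_au))
}
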