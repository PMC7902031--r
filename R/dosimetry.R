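# Aerosol dose accounting: nebulized suspension -> deposited mass per cm^2
# of cell culture area -> particle surface-area dose.

#' Nebulization run description
#'
#' Parameters of one aerosol exposure: nebulized suspension volume and
#' concentration, the fraction of nebulized material that settles onto the
#' exposed area, and that area. Defaults describe the cloud-settling
#' exposure chamber used for static (unstretched) exposures: 250 uL of a
#' 1.25 mg mL^-1 suspension, deposition factor 0.97, exposed area 146 cm^2.
#'
#' @param nebulized_volume Nebulized suspension volume in uL; > 0.
#' @param suspension_concentration Particle concentration in mg mL^-1; > 0.
#' @param deposition_factor Fraction of nebulized mass deposited, in (0, 1].
#' @param exposure_area Aerosol-exposed area in cm^2; > 0.
#' @return An object of class `"nebulization_run"`.
#' @export
nebulization_run <- function(nebulized_volume = 250,
                             suspension_concentration = 1.25,
                             deposition_factor = 0.97,
                             exposure_area = 146) {
  stopifnot_scalar(nebulized_volume, "nebulized_volume", positive = TRUE)
  stopifnot_scalar(suspension_concentration, "suspension_concentration",
                   positive = TRUE)
  stopifnot_scalar(deposition_factor, "deposition_factor", positive = TRUE)
  if (deposition_factor > 1) {
    ls_stop("deposition_factor must be in (0, 1]", "invalid_argument")
  }
  stopifnot_scalar(exposure_area, "exposure_area", positive = TRUE)
  structure(list(nebulized_volume = nebulized_volume,
                 suspension_concentration = suspension_concentration,
                 deposition_factor = deposition_factor,
                 exposure_area = exposure_area),
            class = "nebulization_run")
}

#' Monodisperse spherical particle description
#'
#' @param diameter Particle diameter in nm; > 0.
#' @param material_density Material density in g cm^-3; > 0. Default 1.05
#'   (polystyrene).
#' @return An object of class `"particle_spec"`.
#' @export
particle_spec <- function(diameter, material_density = 1.05) {
  stopifnot_scalar(diameter, "diameter", positive = TRUE)
  stopifnot_scalar(material_density, "material_density", positive = TRUE)
  structure(list(diameter = diameter, material_density = material_density),
            class = "particle_spec")
}

#' Deposited mass dose of a nebulization run
#'
#' Nebulized mass times the deposition factor, per cm^2 of exposed area:
#' `(volume[mL] * concentration[ug/mL] * factor) / area`.
#'
#' @param run A [nebulization_run()].
#' @return Deposited dose in ug cm^-2.
#' @export
#' @examples
#' deposited_mass_dose(nebulization_run())   # 2.08 ug/cm^2
deposited_mass_dose <- function(run) {
  stopifnot(inherits(run, "nebulization_run"))
  vol_ml <- run$nebulized_volume / 1000
  conc_ug_ml <- run$suspension_concentration * 1000
  vol_ml * conc_ug_ml * run$deposition_factor / run$exposure_area
}

#' Particle surface-area dose from a mass dose
#'
#' For monodisperse spheres the specific surface area is `6 / (rho * d)`, so
#' the surface-area dose is the mass dose times that factor; inversely
#' proportional to particle diameter at fixed mass dose.
#'
#' @param mass_dose Deposited mass dose in ug cm^-2; >= 0 (vectorised).
#' @param particle A [particle_spec()].
#' @return Surface-area dose in cm^2 of particle surface per cm^2 of
#'   culture area.
#' @export
#' @examples
#' surface_area_dose(2.08, particle_spec(100))    # ~1.2
#' surface_area_dose(2.08, particle_spec(1000))   # ~0.12
surface_area_dose <- function(mass_dose, particle) {
  stopifnot(inherits(particle, "particle_spec"))
  if (any(mass_dose < 0)) {
    ls_stop("`mass_dose` must be >= 0", "invalid_argument")
  }
  d_cm <- particle$diameter * 1e-7       # nm -> cm
  mass_g <- mass_dose * 1e-6             # ug -> g
  mass_g * 6 / (particle$material_density * d_cm)
}

#' Delivered mass and dose for the bioreactor's integrated nebulizer
#'
#' The bioreactor's cloud-settling nebulizer delivers a known fraction
#' (default 52%) of the nebulized mass onto the membrane (default growth
#' area 5 cm^2).
#'
#' @param nebulized_mass Nebulized particle mass in ug; >= 0.
#' @param efficiency Delivery efficiency fraction in (0, 1]; default 0.52.
#' @param membrane_area Cell-covered membrane area in cm^2; default 5.
#' @return A list with `total_ug` (delivered mass) and `dose_ug_per_cm2`.
#' @export
#' @examples
#' civic_delivered_mass(20.2)   # total 10.5 ug, dose 2.1 ug/cm^2
civic_delivered_mass <- function(nebulized_mass, efficiency = 0.52,
                                 membrane_area = 5) {
  stopifnot_scalar(nebulized_mass, "nebulized_mass", nonneg = TRUE)
  stopifnot_scalar(efficiency, "efficiency", positive = TRUE)
  if (efficiency > 1) {
    ls_stop("efficiency must be in (0, 1]", "invalid_argument")
  }
  stopifnot_scalar(membrane_area, "membrane_area", positive = TRUE)
  total <- nebulized_mass * efficiency
  list(total_ug = total, dose_ug_per_cm2 = total / membrane_area)
}
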