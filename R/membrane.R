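# Membrane characterisation: porosity estimators and routine assay
# normalisations (WST-1 viability, LDH release, TEER, proliferation fold).

#' Polymer composition of a biphasic membrane
#'
#' Mass concentrations (% w/v of solvent) of the structural polymer (PCL)
#' and the sacrificial pore-forming phase (gelatin), with their densities.
#' Defaults are the optimum membrane composition (9.35% PCL, 6.34% gelatin)
#' and densities 1.145 / 1.30 g cm^-3.
#'
#' @param c_pcl PCL concentration, % w/v of solvent; >= 0.
#' @param c_gel Gelatin concentration, % w/v of solvent; >= 0. Not both zero.
#' @param rho_pcl PCL density in g cm^-3 (default 1.145; 1.45 is also quoted
#'   in the literature and may be passed explicitly).
#' @param rho_gel Gelatin density in g cm^-3 (default 1.30).
#' @return An object of class `"membrane_composition"`.
#' @export
membrane_composition <- function(c_pcl = 9.35, c_gel = 6.34,
                                 rho_pcl = 1.145, rho_gel = 1.30) {
  stopifnot_scalar(c_pcl, "c_pcl", nonneg = TRUE)
  stopifnot_scalar(c_gel, "c_gel", nonneg = TRUE)
  stopifnot_scalar(rho_pcl, "rho_pcl", positive = TRUE)
  stopifnot_scalar(rho_gel, "rho_gel", positive = TRUE)
  if (c_pcl + c_gel == 0) {
    ls_stop("composition must contain some polymer (c_pcl + c_gel > 0)",
            "invalid_argument")
  }
  structure(list(c_pcl = c_pcl, c_gel = c_gel,
                 rho_pcl = rho_pcl, rho_gel = rho_gel),
            class = "membrane_composition")
}

#' Volume-weighted density of a two-phase membrane
#'
#' Total mass over total volume of the PCL and gelatin phases; the membrane
#' density used in the gravimetric porosity estimate.
#'
#' @param comp A [membrane_composition()].
#' @return Density in g cm^-3.
#' @export
membrane_density <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  (comp$c_pcl + comp$c_gel) /
    (comp$c_pcl / comp$rho_pcl + comp$c_gel / comp$rho_gel)
}

#' Gravimetric liquid-displacement measurement
#'
#' Dry and ethanol-soaked membrane masses for the liquid-displacement 3D
#' porosity estimate, plus the constants of the method: ethanol density
#' 0.789 g cm^-3 and the apparent porosity of a pure PCL blank membrane
#' (0.093) that accounts for ethanol adsorption / PCL microporosity and is
#' subtracted from the raw estimate.
#'
#' @param mass_dry Dry membrane mass in mg; > 0.
#' @param mass_soaked Soaked mass in mg; >= `mass_dry`.
#' @param rho_membrane Volume-weighted membrane density in g cm^-3
#'   (see [membrane_density()]).
#' @param rho_etoh Ethanol density in g cm^-3 (default 0.789).
#' @param blank_apparent_porosity Blank correction fraction (default 0.093).
#' @return An object of class `"gravimetric_measurement"`.
#' @export
gravimetric_measurement <- function(mass_dry, mass_soaked,
                                    rho_membrane = membrane_density(membrane_composition()),
                                    rho_etoh = 0.789,
                                    blank_apparent_porosity = 0.093) {
  stopifnot_scalar(mass_dry, "mass_dry", positive = TRUE)
  stopifnot_scalar(mass_soaked, "mass_soaked")
  if (mass_soaked < mass_dry) {
    ls_stop("soaked mass cannot be below dry mass", "invalid_measurement")
  }
  stopifnot_scalar(rho_membrane, "rho_membrane", positive = TRUE)
  stopifnot_scalar(rho_etoh, "rho_etoh", positive = TRUE)
  stopifnot_scalar(blank_apparent_porosity, "blank_apparent_porosity",
                   nonneg = TRUE)
  structure(list(mass_dry = mass_dry, mass_soaked = mass_soaked,
                 rho_membrane = rho_membrane, rho_etoh = rho_etoh,
                 blank_apparent_porosity = blank_apparent_porosity),
            class = "gravimetric_measurement")
}

#' Empirical 3D porosity by liquid displacement
#'
#' The ethanol volume taken up by the pore network over the total (ethanol +
#' polymer) volume, corrected by the pure-PCL blank:
#' \deqn{\phi = \frac{V_{EtOH}}{V_{EtOH} + V_m} - \phi_{blank},}
#' where \eqn{V_{EtOH} = (m_{soaked} - m_{dry})/\rho_{EtOH}} and
#' \eqn{V_m = m_{dry}/\rho_m}. A negative corrected value clamps to 0 with a
#' warning (the blank correction can exceed the raw estimate for dense
#' membranes). Invariant to rescaling both masses by a common factor.
#'
#' @param g A [gravimetric_measurement()].
#' @return Corrected porosity fraction in \[0, 1\].
#' @export
#' @examples
#' g <- gravimetric_measurement(10, 12, rho_membrane = 1.2,
#'                              blank_apparent_porosity = 0)
#' empirical_porosity(g)   # 0.2333
empirical_porosity <- function(g) {
  stopifnot(inherits(g, "gravimetric_measurement"))
  v_etoh <- (g$mass_soaked - g$mass_dry) / g$rho_etoh
  v_m <- g$mass_dry / g$rho_membrane
  raw <- v_etoh / (v_etoh + v_m)
  out <- raw - g$blank_apparent_porosity
  if (out < 0) {
    warning("blank correction exceeds raw porosity; clamping to 0",
            call. = FALSE)
    out <- 0
  }
  out
}

#' Theoretical (maximum) porosity from membrane composition
#'
#' Upper bound on porosity assuming the sacrificial gelatin phase dissolves
#' completely: the gelatin volume fraction of the composite,
#' \deqn{\phi_{max} = \frac{c_{gel}/\rho_{gel}}
#'   {c_{gel}/\rho_{gel} + c_{PCL}/\rho_{PCL}},}
#' with concentrations taken as mass amounts per unit solvent volume so that
#' each ratio is a phase volume. Bounded in \[0, 1\], increasing in `c_gel`,
#' decreasing in `c_pcl`.
#'
#' @param comp A [membrane_composition()].
#' @return Porosity fraction in \[0, 1\].
#' @export
#' @examples
#' theoretical_porosity(membrane_composition())   # optimum membrane, 0.374
theoretical_porosity <- function(comp) {
  stopifnot(inherits(comp, "membrane_composition"))
  vg <- comp$c_gel / comp$rho_gel
  vp <- comp$c_pcl / comp$rho_pcl
  vg / (vg + vp)
}

#' WST-1 viability relative to a reference membrane
#'
#' Blank-subtracted absorbance of a sample expressed as a percentage of the
#' blank-subtracted reference (e.g. a standard Transwell insert).
#'
#' @param abs_sample Sample absorbance (AU).
#' @param abs_blank Blank (reagent only) absorbance (AU).
#' @param abs_reference Reference absorbance (AU); must exceed the blank.
#' @return Viability in percent.
#' @export
wst1_viability <- function(abs_sample, abs_blank, abs_reference) {
  stopifnot_scalar(abs_blank, "abs_blank")
  stopifnot_scalar(abs_reference, "abs_reference")
  if (abs_reference <= abs_blank) {
    ls_stop("reference absorbance must exceed the blank", "invalid_argument")
  }
  100 * (abs_sample - abs_blank) / (abs_reference - abs_blank)
}

#' LDH release as a percentage of the high control
#'
#' LDH dose (concentration times medium volume) in the culture medium over
#' the lysed-cell high control. Values below 10% are conventionally
#' considered non-cytotoxic.
#'
#' @param conc_sample LDH concentration in U mL^-1.
#' @param vol_sample Medium volume in mL.
#' @param dose_high_control High-control LDH dose in U; > 0.
#' @return Release in percent.
#' @export
ldh_release <- function(conc_sample, vol_sample, dose_high_control) {
  stopifnot_scalar(dose_high_control, "dose_high_control", positive = TRUE)
  100 * (conc_sample * vol_sample) / dose_high_control
}

#' Blank-corrected transepithelial electrical resistance
#'
#' `(R_measured - R_blank) * area`. A non-positive result indicates no
#' barrier above the bare membrane and is returned as-is with a warning.
#'
#' @param resistance_measured Measured resistance in Ohm.
#' @param resistance_blank Bare-membrane resistance in Ohm.
#' @param area Effective membrane area in cm^2; > 0.
#' @return TEER in Ohm cm^2.
#' @export
#' @examples
#' teer(450, 60, 1.3)   # 507
teer <- function(resistance_measured, resistance_blank, area) {
  stopifnot_scalar(area, "area", positive = TRUE)
  out <- (resistance_measured - resistance_blank) * area
  if (any(out <= 0)) {
    warning("non-positive TEER: no measurable barrier above the blank membrane",
            call. = FALSE)
  }
  out
}

#' Cell proliferation fold over seeding density
#'
#' @param final_density Final cell density in cells cm^-2; > 0.
#' @param seeding_density Seeding density in cells cm^-2; > 0.
#' @return Fold change, rounded to one decimal.
#' @export
#' @examples
#' proliferation_fold(4.3e5, 1.5e5)   # 2.9
proliferation_fold <- function(final_density, seeding_density) {
  stopifnot_scalar(final_density, "final_density", positive = TRUE)
  stopifnot_scalar(seeding_density, "seeding_density", positive = TRUE)
  round(final_density / seeding_density, 1)
}
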