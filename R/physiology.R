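# Breathing physiology <-> membrane strain mapping. Alveolar sacs are
# treated as spheres, so a fractional lung-volume expansion f maps to
# linear strain (1+f)^(1/3) - 1 and area strain (1+f)^(2/3) - 1.

#' Breathing pattern
#'
#' @param tidal_volume Tidal volume in L; > 0.
#' @param frc Functional residual capacity (lung volume at end of passive
#'   exhalation) in L; > 0.
#' @param frequency Breathing frequency in breaths per minute; > 0.
#' @return An object of class `"breathing_pattern"`.
#' @export
breathing_pattern <- function(tidal_volume, frc, frequency) {
  stopifnot_scalar(tidal_volume, "tidal_volume", positive = TRUE)
  stopifnot_scalar(frc, "frc", positive = TRUE)
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  structure(list(tidal_volume = tidal_volume, frc = frc,
                 frequency = frequency),
            class = "breathing_pattern")
}

#' Reference breathing patterns (ICRP population averages)
#'
#' Tidal volume, FRC and breathing frequency for light and heavy exercise,
#' by sex, as used when relating bench stretch conditions to clinical ones.
#'
#' @return A data.frame with columns `condition`, `sex`, `tidal_volume_l`,
#'   `frc_l`, `frequency_bpm`.
#' @export
icrp_breathing_patterns <- function() {
  data.frame(
    condition = c("heavy_exercise", "heavy_exercise",
                  "light_exercise", "light_exercise"),
    sex = c("male", "female", "male", "female"),
    tidal_volume_l = c(1.92, 1.36, 1.25, 0.99),
    frc_l = c(3.3, 2.7, 3.3, 2.7),
    frequency_bpm = c(26, 33, 20, 21)
  )
}

#' Fractional lung-volume expansion of a breathing pattern
#'
#' Tidal volume over FRC.
#'
#' @param pattern A [breathing_pattern()], or a tidal volume in L if `frc`
#'   is supplied.
#' @param frc FRC in L (only when `pattern` is numeric).
#' @return Expansion fraction (dimensionless).
#' @export
#' @examples
#' volume_expansion(1.92, 3.3)   # 0.58
volume_expansion <- function(pattern, frc = NULL) {
  if (inherits(pattern, "breathing_pattern")) {
    pattern$tidal_volume / pattern$frc
  } else {
    stopifnot_scalar(pattern, "tidal_volume", positive = TRUE)
    stopifnot_scalar(frc, "frc", positive = TRUE)
    pattern / frc
  }
}

#' Alveolar strain from fractional volume expansion
#'
#' Assuming spherical alveolar sacs, a volume expansion `f` gives linear
#' strain `(1+f)^(1/3) - 1` and area strain `(1+f)^(2/3) - 1`. The identity
#' `(1 + linear)^2 - 1 == area` holds exactly.
#'
#' @param f Volume expansion fraction; >= 0 (vectorised).
#' @return A list with components `linear` and `area`.
#' @export
#' @examples
#' strain_from_volume_expansion(0.58)   # ~17% linear, ~36% area
strain_from_volume_expansion <- function(f) {
  if (any(f < 0)) {
    ls_stop("volume expansion must be >= 0", "invalid_argument")
  }
  list(linear = (1 + f)^(1 / 3) - 1, area = (1 + f)^(2 / 3) - 1)
}

#' Tidal volume equivalent to a given alveolar linear strain
#'
#' Exact inverse of [strain_from_volume_expansion()]:
#' `((1 + linear)^3 - 1) * frc`.
#'
#' @param linear Linear strain fraction; >= 0 (vectorised).
#' @param frc FRC in L; > 0.
#' @return Tidal volume in L.
#' @export
#' @examples
#' tidal_volume_from_linear_strain(0.10, 3.3)   # 1.09 L
tidal_volume_from_linear_strain <- function(linear, frc) {
  if (any(linear < 0)) {
    ls_stop("linear strain must be >= 0", "invalid_argument")
  }
  stopifnot_scalar(frc, "frc", positive = TRUE)
  ((1 + linear)^3 - 1) * frc
}

#' Classify a linear strain into physiologic / over-stretch / beyond limit
#'
#' Up to 17% linear strain is physiologic; 17-25% is non-physiologic
#' over-stretch (as during positive-pressure ventilation); above 25% exceeds
#' the membrane's reversible stretch tolerance.
#'
#' @param linear Linear strain fraction(s); >= 0.
#' @return A character vector with values `"physiologic"`, `"overstretch"`,
#'   or `"beyond_membrane_limit"`.
#' @export
#' @examples
#' classify_strain(c(0.10, 0.20, 0.30))
classify_strain <- function(linear) {
  if (any(linear < 0)) {
    ls_stop("linear strain must be >= 0", "invalid_argument")
  }
  ifelse(linear <= 0.17, "physiologic",
         ifelse(linear <= 0.25, "overstretch", "beyond_membrane_limit"))
}

#' Gas-exchange area to perfusion-rate ratio
#'
#' Area (given in cm^2) over perfusion rate (given in uL min^-1), reported
#' in m^2 per (L min^-1) for comparison with the lung (about 100 m^2 of
#' alveolar surface perfused at about 5 L min^-1 cardiac output, i.e.
#' 20 m^2/(L min^-1)).
#'
#' @param area_cm2 Exchange area in cm^2; > 0.
#' @param flow_ul_min Perfusion rate in uL min^-1; > 0.
#' @return Ratio in m^2 per (L min^-1).
#' @export
#' @examples
#' area_perfusion_ratio(5, 400)   # 1.25
area_perfusion_ratio <- function(area_cm2, flow_ul_min) {
  stopifnot_scalar(area_cm2, "area_cm2", positive = TRUE)
  stopifnot_scalar(flow_ul_min, "flow_ul_min", positive = TRUE)
  (area_cm2 * 1e-4) / (flow_ul_min * 1e-6)
}
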