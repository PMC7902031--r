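# Spherical-cap deflection geometry of a circular elastic membrane.
#
# A flat circular membrane of radius a bulges under apical overpressure into
# a (shallow) spherical cap of apex height delta_h. All public interfaces use
# the bench units: cm, mL (= cm^3), kPa, um, uL/min.

#' Circular membrane geometry
#'
#' Describes the circular elastic membrane of a cell-stretch bioreactor:
#' radius, thickness and reference (flat) area. Defaults are the standard
#' bioreactor membrane: radius 1.26 cm (5 cm^2 growth area), thickness 5 um.
#'
#' @param radius_a Membrane radius in cm; must be > 0.
#' @param thickness_t Membrane thickness in um; must be > 0.
#' @param area_S0 Reference membrane area in cm^2. Defaults to `pi * radius_a^2`.
#'   A supplied value differing from `pi * radius_a^2` by more than 0.5% is
#'   rejected unless `check_area = FALSE` (explicit override).
#' @param check_area Logical; set `FALSE` to accept a nominal area that is not
#'   consistent with the radius (e.g. a rounded catalogue value).
#' @return An object of class `"membrane_geometry"`.
#' @export
#' @examples
#' membrane_geometry()                      # 1.26 cm, 5 um, 5 cm^2 (nominal)
#' membrane_geometry(radius_a = 1, thickness_t = 10)
membrane_geometry <- function(radius_a = 1.26, thickness_t = 5,
                              area_S0 = NULL, check_area = TRUE) {
  stopifnot_scalar(radius_a, "radius_a", positive = TRUE)
  stopifnot_scalar(thickness_t, "thickness_t", positive = TRUE)
  circle <- pi * radius_a^2
  if (is.null(area_S0)) {
    area_S0 <- circle
  } else {
    stopifnot_scalar(area_S0, "area_S0", positive = TRUE)
    if (check_area && abs(area_S0 / circle - 1) > 0.005) {
      ls_stop(sprintf(
        "area_S0 = %g cm^2 differs from pi*a^2 = %g cm^2 by more than 0.5%%; pass check_area = FALSE to override",
        area_S0, circle), "invalid_argument")
    }
  }
  structure(list(radius_a = radius_a, thickness_t = thickness_t,
                 area_S0 = area_S0),
            class = "membrane_geometry")
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat(sprintf("<membrane_geometry> a = %g cm, t = %g um, S0 = %g cm^2\n",
              x$radius_a, x$thickness_t, x$area_S0))
  invisible(x)
}

#' Sealed-chamber configuration
#'
#' Ambient pressure, reservoir headspace volume and basal medium perfusion
#' rate of the two-compartment bioreactor chamber. Defaults match the bench
#' setup: 98.0 kPa ambient, 30 mL headspace, 400 uL/min perfusion.
#'
#' @param ambient_P0 Ambient pressure in kPa; > 0.
#' @param headspace_V0 Air headspace volume of the medium reservoir in mL; > 0.
#' @param perfusion_rate Basal medium perfusion rate in uL/min; > 0.
#' @return An object of class `"chamber_config"`.
#' @export
chamber_config <- function(ambient_P0 = 98.0, headspace_V0 = 30,
                           perfusion_rate = 400) {
  stopifnot_scalar(ambient_P0, "ambient_P0", positive = TRUE)
  stopifnot_scalar(headspace_V0, "headspace_V0", positive = TRUE)
  stopifnot_scalar(perfusion_rate, "perfusion_rate", positive = TRUE)
  structure(list(ambient_P0 = ambient_P0, headspace_V0 = headspace_V0,
                 perfusion_rate = perfusion_rate),
            class = "chamber_config")
}

#' @export
print.chamber_config <- function(x, ...) {
  cat(sprintf("<chamber_config> P0 = %g kPa, V0 = %g mL, perfusion = %g uL/min\n",
              x$ambient_P0, x$headspace_V0, x$perfusion_rate))
  invisible(x)
}

#' Spherical-cap volume from apex deflection
#'
#' Volume displaced by a circular membrane of radius `radius_a` bulged into a
#' spherical cap of apex height `delta_h`:
#' \deqn{\Delta V = \pi \Delta h (a^2/2 + \Delta h^2/6).}
#' At `delta_h == radius_a` this is the hemisphere volume `2*pi*a^3/3`.
#'
#' @param delta_h Apex deflection in cm; >= 0 (vectorised).
#' @param radius_a Membrane radius in cm; > 0.
#' @return Displaced volume in mL.
#' @export
#' @examples
#' cap_volume(0.126, 1.26)
cap_volume <- function(delta_h, radius_a) {
  stopifnot_scalar(radius_a, "radius_a", positive = TRUE)
  if (!is.numeric(delta_h) || any(!is.finite(delta_h))) {
    ls_stop("`delta_h` must be finite numeric", "invalid_argument")
  }
  if (any(delta_h < 0)) {
    ls_stop("`delta_h` must be >= 0", "invalid_argument")
  }
  pi * delta_h * (radius_a^2 / 2 + delta_h^2 / 6)
}

#' Apex deflection from displaced cap volume
#'
#' Inverts [cap_volume()]: finds the unique non-negative root of the monotone
#' cubic `pi*h^3/6 + pi*a^2*h/2 - delta_V = 0` by a safeguarded Newton
#' iteration started from the thin-cap (linear) overestimate `2V/(pi a^2)`.
#' The cubic is increasing and convex on `h >= 0`, so the iteration converges
#' monotonically; iteration stops when the volume residual is below
#' `tol * max(1, delta_V)`.
#'
#' @param delta_V Displaced volume in mL; >= 0 (vectorised).
#' @param radius_a Membrane radius in cm; > 0.
#' @param tol Relative residual tolerance (default 1e-12).
#' @return Apex deflection in cm.
#' @export
#' @examples
#' h <- cap_height_from_volume(cap_volume(0.2, 1.26), 1.26)  # 0.2
cap_height_from_volume <- function(delta_V, radius_a, tol = 1e-12) {
  stopifnot_scalar(radius_a, "radius_a", positive = TRUE)
  if (!is.numeric(delta_V) || any(!is.finite(delta_V))) {
    ls_stop("`delta_V` must be finite numeric", "invalid_argument")
  }
  if (any(delta_V < 0)) {
    ls_stop("`delta_V` must be >= 0", "invalid_argument")
  }
  a2 <- radius_a^2
  h <- 2 * delta_V / (pi * a2)          # linear overestimate (cap <= cylinder)
  scale <- pmax(1, delta_V)
  for (i in 1:100) {
    f <- pi * (h^3 / 6 + a2 * h / 2) - delta_V
    if (all(abs(f) <= tol * scale)) break
    h <- h - f / (pi * (h^2 / 2 + a2 / 2))
    h[h < 0] <- 0
  }
  h
}

#' Linear and area strain of a stretched spherical cap
#'
#' Linear strain is always the apex deflection over the membrane radius,
#' `delta_h / radius_a`. Two conventions for area strain are supported:
#' \describe{
#'   \item{`"text"` (default)}{`(1 + delta_h/a)^2 - 1`; reproduces the
#'     standard worked pairing of 10% linear with 21% area strain.}
#'   \item{`"eq4"`}{`(delta_h/a)^2`, the small-deflection cap form.}
#' }
#'
#' @param delta_h Apex deflection in cm; `0 <= delta_h <= radius_a`
#'   (vectorised).
#' @param radius_a Membrane radius in cm; > 0.
#' @param convention `"text"` or `"eq4"`.
#' @return A list with numeric components `linear` and `area`.
#' @export
#' @examples
#' strain_from_height(0.126, 1.26)        # linear 0.10, area 0.21
strain_from_height <- function(delta_h, radius_a,
                               convention = c("text", "eq4")) {
  convention <- match.arg(convention)
  stopifnot_scalar(radius_a, "radius_a", positive = TRUE)
  if (any(delta_h < 0) || any(delta_h > radius_a)) {
    ls_stop("`delta_h` must lie in [0, radius_a]", "invalid_argument")
  }
  linear <- delta_h / radius_a
  area <- switch(convention,
                 text = (1 + linear)^2 - 1,
                 eq4  = linear^2)
  list(linear = linear, area = area)
}
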