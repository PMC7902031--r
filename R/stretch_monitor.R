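# Pressure-based stretch monitoring.
#
# Two sensors watch the sealed two-compartment chamber: P1 in the apical
# (air) compartment drives the membrane downwards; P2 in the reservoir
# headspace rises as the displaced cap volume compresses the trapped air.
# P2 - P0 gives the displaced volume (gas law), the cap geometry gives the
# apex deflection and strain, and the transmembrane pressure P1 - P2 gives
# the membrane's triaxial Young's modulus through the bulge-test relation.

#' Dual-sensor pressure trace
#'
#' Validating constructor for a timestamped apical/reservoir pressure record.
#'
#' @param time_s Sample times in seconds; strictly increasing, length >= 2.
#' @param p1_kpa Apical compartment pressure in kPa; > 0.
#' @param p2_kpa Reservoir headspace pressure in kPa; > 0.
#' @return A `data.frame` of class `"pressure_trace"` with columns
#'   `time_s`, `p1_kpa`, `p2_kpa`.
#' @export
pressure_trace <- function(time_s, p1_kpa, p2_kpa) {
  if (length(time_s) < 2L) {
    ls_stop("a pressure trace needs at least 2 samples", "invalid_argument")
  }
  if (length(p1_kpa) != length(time_s) || length(p2_kpa) != length(time_s)) {
    ls_stop("time_s, p1_kpa, p2_kpa must have equal length", "invalid_argument")
  }
  if (any(diff(time_s) <= 0)) {
    ls_stop("time_s must be strictly increasing", "invalid_argument")
  }
  if (any(p1_kpa <= 0) || any(p2_kpa <= 0)) {
    ls_stop("pressures must be > 0 kPa", "invalid_argument")
  }
  structure(data.frame(time_s = time_s, p1_kpa = p1_kpa, p2_kpa = p2_kpa),
            class = c("pressure_trace", "data.frame"))
}

#' Displaced volume from reservoir overpressure
#'
#' Converts reservoir headspace pressure into the volume displaced by the
#' bulging membrane. Mode `"linearized"` (default) uses the first-order gas
#' law \eqn{\Delta V = (P_2 - P_0) V_0 / P_0}; mode `"isothermal"` uses the
#' exact Boyle form \eqn{\Delta V = V_0 (1 - P_0/P_2)}. Samples with
#' `p2 < P0` (sensor drift) are clamped to zero volume with a warning.
#'
#' @param p2 Reservoir pressure(s) in kPa; > 0.
#' @param config A [chamber_config()].
#' @param mode `"linearized"` or `"isothermal"`.
#' @return Displaced volume(s) in mL.
#' @export
#' @examples
#' volume_from_reservoir_pressure(99.5, chamber_config())  # 1.5 * 30 / 98
volume_from_reservoir_pressure <- function(p2, config = chamber_config(),
                                           mode = c("linearized", "isothermal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "chamber_config"))
  if (!is.numeric(p2) || any(!is.finite(p2))) {
    ls_stop("`p2` must be finite numeric", "invalid_argument")
  }
  if (any(p2 <= 0)) {
    ls_stop("`p2` must be > 0 kPa", "invalid_argument")
  }
  P0 <- config$ambient_P0
  V0 <- config$headspace_V0
  dv <- switch(mode,
               linearized = (p2 - P0) * V0 / P0,
               isothermal = V0 * (1 - P0 / p2))
  n_neg <- sum(dv < 0)
  if (n_neg > 0) {
    warning(sprintf("%d sample(s) with P2 < P0 clamped to zero displaced volume",
                    n_neg), call. = FALSE)
    dv[dv < 0] <- 0
  }
  dv
}

# kPa of transmembrane pressure per MPa of Young's modulus at deflection
# delta_h; the purely geometric factor of the bulge-test relation.
bulge_pressure_coefficient <- function(delta_h, geometry) {
  x <- delta_h / geometry$radius_a
  t_cm <- geometry$thickness_t * 1e-4      # um -> cm
  1000 * 4 * x * t_cm / (3 * geometry$radius_a * (x^2 + 1)) *
    (1 - 1 / (1 + x^2)^3)
}

#' Transmembrane pressure from Young's modulus (bulge-test forward model)
#'
#' The pressure difference P1 - P2 needed to hold a membrane of triaxial
#' Young's modulus `E` at apex deflection `delta_h`:
#' \deqn{\Delta P' = \frac{4 E (\Delta h/a) t}{3 a ((\Delta h/a)^2 + 1)}
#'   \left(1 - \frac{1}{(1 + (\Delta h/a)^2)^3}\right).}
#' Zero at zero deflection, strictly increasing in `delta_h` on (0, a], and
#' linear in `E`.
#'
#' @param delta_h Apex deflection in cm; >= 0 (vectorised).
#' @param E Young's modulus in MPa; > 0.
#' @param geometry A [membrane_geometry()].
#' @return Transmembrane pressure in kPa.
#' @export
#' @examples
#' transmembrane_pressure_from_modulus(0.126, 0.78, membrane_geometry())
transmembrane_pressure_from_modulus <- function(delta_h, E,
                                                geometry = membrane_geometry()) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  stopifnot_scalar(E, "E", positive = TRUE)
  if (any(delta_h < 0)) {
    ls_stop("`delta_h` must be >= 0", "invalid_argument")
  }
  E * bulge_pressure_coefficient(delta_h, geometry)
}

#' Young's modulus from a deflection state (bulge-test inversion)
#'
#' Algebraic inversion of [transmembrane_pressure_from_modulus()]: since the
#' forward relation is linear in `E`, the modulus is the measured
#' transmembrane pressure divided by the geometric coefficient at the
#' observed deflection. Unidentifiable at zero deflection.
#'
#' @param delta_p_prime Transmembrane pressure P1 - P2 in kPa; > 0.
#' @param delta_h Apex deflection in cm; > 0.
#' @param geometry A [membrane_geometry()].
#' @return Young's modulus in MPa.
#' @export
modulus_from_state <- function(delta_p_prime, delta_h,
                               geometry = membrane_geometry()) {
  stopifnot(inherits(geometry, "membrane_geometry"))
  stopifnot_scalar(delta_h, "delta_h")
  if (delta_h == 0) {
    ls_stop("modulus is unidentifiable at zero deflection", "singular_state")
  }
  if (delta_h < 0) {
    ls_stop("`delta_h` must be > 0", "invalid_argument")
  }
  stopifnot_scalar(delta_p_prime, "delta_p_prime", positive = TRUE)
  delta_p_prime / bulge_pressure_coefficient(delta_h, geometry)
}

#' Options for [analyze_trace()]
#'
#' @param mode Volume conversion mode, `"linearized"` or `"isothermal"`.
#' @param convention Area-strain convention, see [strain_from_height()].
#' @param e_estimator Per-cycle modulus estimator: `"peak"` uses the sample
#'   at maximum deflection in each cycle (highest signal-to-noise);
#'   `"mean_above_half_peak"` averages over all cycle samples with deflection
#'   above 50% of the cycle peak.
#' @param overstretch_threshold Linear strain above which a cycle is flagged
#'   as over-stretch (default 0.17).
#' @param limit_threshold Linear strain above which a cycle exceeds the
#'   membrane's reversible-stretch tolerance (default 0.25).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   trace's peak-to-trough range (default 0.25).
#' @param min_separation_frac Minimum peak separation as a fraction of the
#'   dominant period from the autocorrelation maximum (default 0.4).
#' @return A list of class `"stretch_options"`.
#' @export
stretch_options <- function(mode = c("linearized", "isothermal"),
                            convention = c("text", "eq4"),
                            e_estimator = c("peak", "mean_above_half_peak"),
                            overstretch_threshold = 0.17,
                            limit_threshold = 0.25,
                            prominence_frac = 0.25,
                            min_separation_frac = 0.4) {
  structure(list(mode = match.arg(mode),
                 convention = match.arg(convention),
                 e_estimator = match.arg(e_estimator),
                 overstretch_threshold = overstretch_threshold,
                 limit_threshold = limit_threshold,
                 prominence_frac = prominence_frac,
                 min_separation_frac = min_separation_frac),
            class = "stretch_options")
}

# Strict-ish local maxima (rising on the left, non-rising on the right) with
# a topographic prominence filter and a greedy minimum-separation rule.
find_cycle_peaks <- function(x, prominence_frac, min_sep_samples) {
  n <- length(x)
  if (n < 3L) return(integer())
  core <- 2:(n - 1L)
  cand <- core[x[core] > x[core - 1L] & x[core] >= x[core + 1L]]
  if (!length(cand)) return(integer())
  rng <- max(x) - min(x)
  if (rng == 0) return(integer())
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= prominence_frac * rng]
  if (length(cand) < 2L) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep_samples)) kept <- c(kept, i)
  }
  sort(kept)
}

# Dominant period (in samples) from the lag of the highest positive local
# maximum of the autocorrelation function.
dominant_period_samples <- function(x) {
  n <- length(x)
  if (n < 5L || stats::sd(x) == 0) return(NA_integer_)
  ac <- stats::acf(x, lag.max = min(n - 2L, 5000L), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1][-1]
  if (length(ac) < 3L || any(!is.finite(ac))) return(NA_integer_)
  core <- 2:(length(ac) - 1L)
  locs <- core[ac[core] > ac[core - 1L] & ac[core] >= ac[core + 1L]]
  locs <- locs[ac[locs] > 0]
  if (!length(locs)) return(NA_integer_)
  locs[which.max(ac[locs])]
}

# Residual sum of squares of a single-harmonic (mean + cos + sin) fit at
# frequency f; used to refine the cycle-spacing frequency estimate.
harmonic_rss <- function(f, t, y) {
  X <- cbind(1, cos(2 * pi * f * t), sin(2 * pi * f * t))
  sum(stats::lm.fit(X, y)$residuals^2)
}

refine_frequency <- function(f0, t, y) {
  grid <- f0 * seq(0.9, 1.1, length.out = 81L)
  rss <- vapply(grid, harmonic_rss, numeric(1), t = t, y = y)
  k <- which.min(rss)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  if (lo == hi) return(grid[k])
  stats::optimize(harmonic_rss, c(lo, hi), t = t, y = y,
                  tol = f0 * 1e-8)$minimum
}

#' Analyse a cyclic pressure trace into stretch parameters and modulus
#'
#' Per sample, converts reservoir overpressure into displaced volume, apex
#' deflection, linear/area strain and transmembrane pressure P1 - P2.
#' Detects stretch cycles by prominence-filtered peak-finding on the
#' mean-subtracted reservoir signal (minimum separation taken from the
#' autocorrelation's dominant period), then:
#' \itemize{
#'   \item estimates stretch frequency by refining the median peak-spacing
#'     estimate against a single-harmonic least-squares fit;
#'   \item estimates the peak linear/area strain from the amplitude of a
#'     harmonic fit to the signed displaced volume (robust to sensor noise,
#'     which biases a naive per-cycle maximum upwards);
#'   \item estimates a per-cycle Young's modulus from the bulge-test
#'     inversion at the cycle's maximum-deflection sample (or averaged over
#'     the upper half of the cycle, see [stretch_options()]);
#'   \item flags cycles exceeding the over-stretch (17%) and membrane-limit
#'     (25%) linear-strain thresholds.
#' }
#'
#' @param trace A [pressure_trace()] (or data.frame with the same columns)
#'   covering at least 2 full stretch cycles.
#' @param geometry A [membrane_geometry()].
#' @param config A [chamber_config()].
#' @param options A [stretch_options()].
#' @return An object of class `"stretch_report"`: a list with elements
#'   `frequency_hz`, `cycle_count`, `peak_linear_strain`, `peak_area_strain`,
#'   `modulus_mpa` (mean), `modulus_sd_mpa`, `strain_mean`, `strain_sd`,
#'   `per_cycle` (data.frame: `peak_time_s`, `peak_linear_strain`,
#'   `modulus_mpa`, `over_stretch`, `beyond_membrane_limit`), `samples`
#'   (per-sample data.frame), and `n_clamped`.
#'   If fewer than 2 cycles are detected an error of class
#'   `"lungstretch_insufficient_cycles"` is signalled carrying the per-sample
#'   table in its `samples` field.
#' @export
#' @examples
#' spec <- simulation_spec(seed = 1, duration = 30)
#' rep <- analyze_trace(simulate_pressure_trace(spec))
#' rep$frequency_hz
analyze_trace <- function(trace, geometry = membrane_geometry(),
                          config = chamber_config(),
                          options = stretch_options()) {
  stopifnot(inherits(geometry, "membrane_geometry"),
            inherits(config, "chamber_config"))
  if (!all(c("time_s", "p1_kpa", "p2_kpa") %in% names(trace))) {
    ls_stop("trace must have columns time_s, p1_kpa, p2_kpa",
            "invalid_argument")
  }
  t <- trace$time_s
  p1 <- trace$p1_kpa
  p2 <- trace$p2_kpa
  if (length(t) < 2L) {
    ls_stop("a pressure trace needs at least 2 samples", "invalid_argument")
  }

  P0 <- config$ambient_P0
  V0 <- config$headspace_V0
  dv_signed <- switch(options$mode,
                      linearized = (p2 - P0) * V0 / P0,
                      isothermal = V0 * (1 - P0 / p2))
  clamped <- dv_signed < 0
  dv <- pmax(dv_signed, 0)
  dh <- cap_height_from_volume(dv, geometry$radius_a)
  st <- strain_from_height(pmin(dh, geometry$radius_a), geometry$radius_a,
                           options$convention)
  dpp <- p1 - p2
  samples <- data.frame(time_s = t, delta_v_ml = dv, delta_h_cm = dh,
                        linear_strain = st$linear, area_strain = st$area,
                        dp_prime_kpa = dpp, clamped = clamped)

  x <- p2 - mean(p2)
  period <- dominant_period_samples(x)
  min_sep <- if (is.na(period)) 1L else
    max(1L, floor(options$min_separation_frac * period))
  peaks <- find_cycle_peaks(x, options$prominence_frac, min_sep)
  if (length(peaks) < 2L) {
    ls_stop("fewer than 2 stretch cycles detected; per-sample output attached",
            "insufficient_cycles", samples = samples)
  }

  f0 <- 1 / stats::median(diff(t[peaks]))
  frequency <- refine_frequency(f0, t, x)

  # Trace-level peak strain from a 3-harmonic least-squares fit to the
  # signed displaced volume (unclamped, so sensor noise in the flat phase
  # does not bias the mean). Three harmonics represent the cubic
  # cap-volume waveform exactly; the fit is evaluated at the fundamental's
  # peak phase, which keeps the estimator linear in the coefficients and
  # hence unbiased under sensor noise (a naive per-cycle maximum is
  # noise-max-biased upward).
  w <- 2 * pi * frequency
  Xh <- cbind(1, cos(w * t), sin(w * t), cos(2 * w * t), sin(2 * w * t),
              cos(3 * w * t), sin(3 * w * t))
  cf <- stats::lm.fit(Xh, dv_signed)$coefficients
  phi <- atan2(cf[3], cf[2])          # fundamental peaks where w*t == phi
  eval_phase <- function(th) {
    cf[1] + cf[2] * cos(th) + cf[3] * sin(th) +
      cf[4] * cos(2 * th) + cf[5] * sin(2 * th) +
      cf[6] * cos(3 * th) + cf[7] * sin(3 * th)
  }
  peak_dv <- max(0, eval_phase(phi))
  peak_dh <- cap_height_from_volume(peak_dv, geometry$radius_a)
  peak_st <- strain_from_height(min(peak_dh, geometry$radius_a),
                                geometry$radius_a, options$convention)

  # Per-cycle estimates at the fitted peak times (phase phi + k full
  # periods). Using the deterministic fitted peak instead of the noisy
  # per-cycle argmax decouples sample selection from the sensor noise that
  # also enters dP' = P1 - P2, which would otherwise bias the modulus.
  period <- 1 / frequency
  k0 <- ceiling((t[1] - phi / w) / period)
  k1 <- floor((t[length(t)] - phi / w) / period)
  peak_times <- phi / w + (k0:k1) * period
  half_window <- 0.5 * period
  per_cycle <- do.call(rbind, lapply(peak_times, function(tk) {
    i_pk <- which.min(abs(t - tk))
    eps <- st$linear[i_pk]
    coeff <- bulge_pressure_coefficient(dh[i_pk], geometry)
    E <- if (options$e_estimator == "peak") {
      if (coeff > 0) dpp[i_pk] / coeff else NA_real_
    } else {
      idx <- which(abs(t - tk) <= half_window)
      sel <- idx[dh[idx] > 0.5 * dh[i_pk]]
      cc <- bulge_pressure_coefficient(dh[sel], geometry)
      ok <- cc > 0
      if (any(ok)) mean(dpp[sel][ok] / cc[ok]) else NA_real_
    }
    data.frame(peak_time_s = t[i_pk], peak_linear_strain = eps,
               modulus_mpa = E,
               over_stretch = eps > options$overstretch_threshold,
               beyond_membrane_limit = eps > options$limit_threshold)
  }))

  structure(list(
    frequency_hz = frequency,
    cycle_count = nrow(per_cycle),
    peak_linear_strain = peak_st$linear,
    peak_area_strain = peak_st$area,
    modulus_mpa = mean(per_cycle$modulus_mpa, na.rm = TRUE),
    modulus_sd_mpa = stats::sd(per_cycle$modulus_mpa, na.rm = TRUE),
    strain_mean = mean(per_cycle$peak_linear_strain),
    strain_sd = stats::sd(per_cycle$peak_linear_strain),
    per_cycle = per_cycle,
    samples = samples,
    n_clamped = sum(clamped)
  ), class = "stretch_report")
}

#' @export
print.stretch_report <- function(x, ...) {
  cat("<stretch_report>\n")
  cat(sprintf("  frequency:        %.4f Hz over %d cycles\n",
              x$frequency_hz, x$cycle_count))
  cat(sprintf("  peak strain:      %.3f linear / %.3f area (harmonic fit)\n",
              x$peak_linear_strain, x$peak_area_strain))
  cat(sprintf("  per-cycle strain: %.3f +/- %.3f\n", x$strain_mean, x$strain_sd))
  cat(sprintf("  Young's modulus:  %.3f +/- %.3f MPa\n",
              x$modulus_mpa, x$modulus_sd_mpa))
  n_over <- sum(x$per_cycle$over_stretch)
  if (n_over > 0) cat(sprintf("  over-stretch cycles: %d\n", n_over))
  if (x$n_clamped > 0) cat(sprintf("  clamped samples (P2 < P0): %d\n",
                                   x$n_clamped))
  invisible(x)
}
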