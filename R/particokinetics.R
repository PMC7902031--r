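# Transepithelial translocation from basal-medium fluorescence, and
# cellular-uptake intensity summaries from image-stack quantification.

#' Fit a fluorescence standard curve with limit of detection
#'
#' Ordinary least-squares line of fluorescence against concentration, with
#' the conventional spectroscopic limit of detection: the concentration at
#' which the calibration line reaches `mean(blanks) + 3 * sd(blanks)`,
#' floored at zero. The intercept is fitted by default because culture
#' medium autofluorescence is nonzero; `force_origin = TRUE` constrains the
#' line through zero.
#'
#' @param concentrations Standard concentrations in ug mL^-1; >= 3 distinct
#'   levels.
#' @param fluorescence Matching fluorescence readings (AU).
#' @param blanks Blank (particle-free medium) readings (AU); >= 3 values.
#' @param force_origin Logical; constrain the intercept to zero.
#' @return An object of class `"standard_curve"`: list with `slope`,
#'   `intercept`, `residual_sd`, `lod_concentration` (ug mL^-1), `n_points`.
#' @export
#' @examples
#' fit_standard_curve(c(1, 2, 4), c(3, 5, 9), blanks = c(1, 1, 1))
fit_standard_curve <- function(concentrations, fluorescence, blanks,
                               force_origin = FALSE) {
  if (length(unique(concentrations)) < 3L) {
    ls_stop("need at least 3 distinct concentration levels",
            "invalid_argument")
  }
  if (length(fluorescence) != length(concentrations)) {
    ls_stop("concentrations and fluorescence must have equal length",
            "invalid_argument")
  }
  if (length(blanks) < 3L) {
    ls_stop("need at least 3 blank readings", "invalid_argument")
  }
  fit <- if (force_origin) {
    stats::lm(fluorescence ~ concentrations + 0)
  } else {
    stats::lm(fluorescence ~ concentrations)
  }
  cf <- stats::coef(fit)
  slope <- unname(cf[["concentrations"]])
  intercept <- if (force_origin) 0 else unname(cf[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0) {
    ls_stop("fitted slope is not positive; calibration curve is degenerate",
            "degenerate_curve")
  }
  lod <- max(0, (mean(blanks) + 3 * stats::sd(blanks) - intercept) / slope)
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = stats::sigma(fit),
                 lod_concentration = lod,
                 n_points = length(concentrations)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> F = %.4g + %.4g * C (AU); LOD = %.4g ug/mL (%d points)\n",
              x$intercept, x$slope, x$lod_concentration, x$n_points))
  invisible(x)
}

#' Translocated particle fraction from basal-medium fluorescence
#'
#' Converts a basal-compartment fluorescence reading to a particle
#' concentration through the standard curve, then to a percentage of the
#' cell-delivered dose: `100 * concentration * basal_volume / delivered_mass`.
#' Readings whose back-calculated concentration falls below the curve's
#' limit of detection are flagged `below_lod`; such results are never
#' reported as zero but carry the LOD-equivalent fraction as an upper bound.
#'
#' @param basal_fluorescence Basal medium fluorescence reading (AU).
#' @param curve A [fit_standard_curve()] result.
#' @param basal_volume Basal medium volume in mL; > 0.
#' @param delivered_mass Cell-delivered particle mass in ug; > 0.
#' @return An object of class `"translocation_result"`: list with
#'   `fraction_percent`, `below_lod` (logical), `lod_fraction_percent`,
#'   `concentration_ug_ml`.
#' @export
translocated_fraction <- function(basal_fluorescence, curve, basal_volume,
                                  delivered_mass) {
  stopifnot(inherits(curve, "standard_curve"))
  stopifnot_scalar(basal_volume, "basal_volume", positive = TRUE)
  stopifnot_scalar(delivered_mass, "delivered_mass", positive = TRUE)
  conc <- (basal_fluorescence - curve$intercept) / curve$slope
  fraction <- 100 * conc * basal_volume / delivered_mass
  lod_fraction <- 100 * curve$lod_concentration * basal_volume / delivered_mass
  structure(list(fraction_percent = fraction,
                 below_lod = conc < curve$lod_concentration,
                 lod_fraction_percent = lod_fraction,
                 concentration_ug_ml = conc),
            class = "translocation_result")
}

#' @export
print.translocation_result <- function(x, ...) {
  if (x$below_lod) {
    cat(sprintf("<translocation_result> < LOD (%.2f%% of delivered dose)\n",
                x$lod_fraction_percent))
  } else {
    cat(sprintf("<translocation_result> %.2f%% of delivered dose (LOD %.2f%%)\n",
                x$fraction_percent, x$lod_fraction_percent))
  }
  invisible(x)
}

#' Mean cellular-uptake intensity over imaging fields
#'
#' Mean and SD over independent fields of view of background-subtracted
#' mean fluorescence intensities (as exported from image-stack
#' quantification).
#'
#' @param field_means Numeric vector of per-field background-subtracted mean
#'   intensities (AU); at least one field.
#' @return A list with `mean_au`, `sd_au`, `n_fields`.
#' @export
#' @examples
#' uptake_intensity(c(10, 20, 30))
uptake_intensity <- function(field_means) {
  if (!is.numeric(field_means) || length(field_means) < 1L) {
    ls_stop("need at least one field intensity", "invalid_argument")
  }
  list(mean_au = mean(field_means),
       sd_au = if (length(field_means) > 1L) stats::sd(field_means) else NA_real_,
       n_fields = length(field_means))
}

#' Uptake fold change between two conditions
#'
#' Ratio of mean uptake intensities (e.g. stretched over static), reported
#' to one decimal.
#'
#' @param condition_a Mean intensity of the numerator condition (AU); >= 0.
#' @param condition_b Mean intensity of the denominator condition (AU); > 0.
#' @return Fold change, rounded to one decimal.
#' @export
uptake_fold_change <- function(condition_a, condition_b) {
  stopifnot_scalar(condition_a, "condition_a", nonneg = TRUE)
  stopifnot_scalar(condition_b, "condition_b", positive = TRUE)
  round(condition_a / condition_b, 1)
}
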