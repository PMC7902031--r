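# File interfaces and the two assembled workflows: stretch monitoring and
# the translocation (particokinetics) table. CSV via utils, config via
# yaml, reports via jsonlite; numeric JSON fields carry units in their
# names (_kpa, _hz, _ug_per_cm2, ...) to prevent silent unit mistakes.

#' Read a dual-sensor pressure trace CSV
#'
#' Expects a header `time_s,p1_kpa,p2_kpa` (extra columns are ignored).
#'
#' @param path Path to the CSV file.
#' @return A [pressure_trace()].
#' @export
read_pressure_trace <- function(path) {
  if (!file.exists(path)) {
    ls_stop(sprintf("trace file not found: %s", path), "file_not_found")
  }
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) ls_stop(
                   sprintf("cannot parse trace CSV %s: %s", path,
                           conditionMessage(e)), "invalid_argument"))
  need <- c("time_s", "p1_kpa", "p2_kpa")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    ls_stop(sprintf("trace CSV %s is missing column(s): %s", path,
                    paste(missing, collapse = ", ")), "schema")
  }
  pressure_trace(df$time_s, df$p1_kpa, df$p2_kpa)
}

#' Read a run configuration YAML
#'
#' Recognised blocks: `geometry` (`radius_a`, `thickness_t`, `area_S0`),
#' `chamber` (`ambient_P0`, `headspace_V0`, `perfusion_rate`), `particle`
#' (`diameter`, `material_density`), `nebulization` (fields of
#' [nebulization_run()]), `assay` (`basal_volume_ml`, `delivered_mass_ug`),
#' `options` (fields of [stretch_options()]), `simulation` (fields of
#' [simulation_spec()] other than objects). Unknown blocks are rejected so
#' misspelled configuration does not fail silently.
#'
#' @param path Path to the YAML file.
#' @return A list with validated `geometry`, `chamber`, `options` objects
#'   and the remaining blocks as lists.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    ls_stop(sprintf("config file not found: %s", path), "file_not_found")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("geometry", "chamber", "particle", "nebulization", "assay",
             "options", "simulation", "output_dir", "verbosity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    ls_stop(sprintf("unknown config block(s): %s",
                    paste(unknown, collapse = ", ")), "schema")
  }
  geometry <- do.call(membrane_geometry, as.list(raw$geometry))
  chamber <- do.call(chamber_config, as.list(raw$chamber))
  options <- do.call(stretch_options, as.list(raw$options))
  list(geometry = geometry, chamber = chamber, options = options,
       particle = raw$particle, nebulization = raw$nebulization,
       assay = raw$assay, simulation = raw$simulation,
       output_dir = raw$output_dir, verbosity = raw$verbosity)
}

#' Write a stretch report to per-sample CSV and summary JSON
#'
#' @param report A `"stretch_report"` from [analyze_trace()].
#' @param samples_csv Path for the per-sample CSV
#'   (`time_s,delta_v_ml,delta_h_cm,linear_strain,area_strain,dp_prime_kpa`).
#' @param report_json Path for the summary JSON.
#' @return The report, invisibly.
#' @export
write_stretch_report <- function(report, samples_csv, report_json) {
  stopifnot(inherits(report, "stretch_report"))
  cols <- c("time_s", "delta_v_ml", "delta_h_cm", "linear_strain",
            "area_strain", "dp_prime_kpa")
  utils::write.csv(report$samples[, cols], samples_csv, row.names = FALSE)
  summary <- list(
    frequency_hz = report$frequency_hz,
    cycle_count = report$cycle_count,
    peak_linear_strain = report$peak_linear_strain,
    peak_area_strain = report$peak_area_strain,
    modulus_mean_mpa = report$modulus_mpa,
    modulus_sd_mpa = report$modulus_sd_mpa,
    per_cycle_strain_mean = report$strain_mean,
    per_cycle_strain_sd = report$strain_sd,
    over_stretch_cycles = sum(report$per_cycle$over_stretch),
    beyond_membrane_limit_cycles = sum(report$per_cycle$beyond_membrane_limit),
    clamped_samples = report$n_clamped
  )
  jsonlite::write_json(summary, report_json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Run the stretch-monitoring workflow on a trace file
#'
#' Reads a pressure-trace CSV (and optionally a YAML run configuration),
#' analyses it with [analyze_trace()], and writes the per-sample CSV and
#' summary JSON next to `out_stem`.
#'
#' @param trace_csv Path to the trace CSV.
#' @param config Optional path to a YAML config, or a list as returned by
#'   [read_run_config()]; defaults apply otherwise.
#' @param out_stem Output path stem; writes `<out_stem>_samples.csv` and
#'   `<out_stem>_report.json`.
#' @return The `"stretch_report"`, invisibly.
#' @export
run_monitor <- function(trace_csv, config = NULL, out_stem = "stretch") {
  cfg <- if (is.character(config)) read_run_config(config)
         else if (is.null(config)) list(geometry = membrane_geometry(),
                                        chamber = chamber_config(),
                                        options = stretch_options())
         else config
  trace <- read_pressure_trace(trace_csv)
  report <- analyze_trace(trace, cfg$geometry, cfg$chamber, cfg$options)
  write_stretch_report(report, paste0(out_stem, "_samples.csv"),
                       paste0(out_stem, "_report.json"))
  invisible(report)
}

#' Run the translocation workflow on standard-curve, blank and sample CSVs
#'
#' Builds the condition-by-particle-size transport table. Input dialects:
#' \itemize{
#'   \item `curve_csv`: columns `conc_ug_ml,fluor_au`;
#'   \item `blanks_csv`: column `fluor_au`;
#'   \item `samples_csv`: columns `condition,particle_nm,fluor_au,
#'     basal_volume_ml,delivered_mass_ug` (one row per replicate).
#' }
#' Replicates are summarised per condition x size as mean and SD of the
#' per-replicate fractions; groups whose mean back-calculated concentration
#' is below the limit of detection are displayed as `"<LOD (x%)"` with the
#' LOD-equivalent fraction as the upper bound.
#'
#' @param curve_csv,blanks_csv,samples_csv Input CSV paths.
#' @param out_json Optional path for a JSON report of the table.
#' @param out_csv Optional path for a CSV of the table.
#' @return A data.frame with one row per condition x particle size:
#'   `condition`, `particle_nm`, `n`, `fraction_percent`, `sd_percent`,
#'   `below_lod`, `lod_fraction_percent`, `display`.
#' @export
run_particokinetics <- function(curve_csv, blanks_csv, samples_csv,
                                out_json = NULL, out_csv = NULL) {
  for (p in c(curve_csv, blanks_csv, samples_csv)) {
    if (!file.exists(p)) {
      ls_stop(sprintf("input file not found: %s", p), "file_not_found")
    }
  }
  curve_df <- utils::read.csv(curve_csv)
  blanks_df <- utils::read.csv(blanks_csv)
  samples_df <- utils::read.csv(samples_csv)
  for (spec in list(list(curve_df, c("conc_ug_ml", "fluor_au"), curve_csv),
                    list(blanks_df, "fluor_au", blanks_csv),
                    list(samples_df, c("condition", "particle_nm", "fluor_au",
                                       "basal_volume_ml", "delivered_mass_ug"),
                         samples_csv))) {
    missing <- setdiff(spec[[2]], names(spec[[1]]))
    if (length(missing)) {
      ls_stop(sprintf("%s is missing column(s): %s", spec[[3]],
                      paste(missing, collapse = ", ")), "schema")
    }
  }
  curve <- fit_standard_curve(curve_df$conc_ug_ml, curve_df$fluor_au,
                              blanks_df$fluor_au)
  groups <- unique(samples_df[, c("condition", "particle_nm")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- samples_df[samples_df$condition == groups$condition[i] &
                    samples_df$particle_nm == groups$particle_nm[i], ]
    per_rep <- lapply(seq_len(nrow(g)), function(j) {
      translocated_fraction(g$fluor_au[j], curve, g$basal_volume_ml[j],
                            g$delivered_mass_ug[j])
    })
    fr <- vapply(per_rep, `[[`, numeric(1), "fraction_percent")
    res <- translocated_fraction(mean(g$fluor_au), curve,
                                 g$basal_volume_ml[1], g$delivered_mass_ug[1])
    data.frame(
      condition = groups$condition[i],
      particle_nm = groups$particle_nm[i],
      n = nrow(g),
      fraction_percent = res$fraction_percent,
      sd_percent = if (nrow(g) > 1) stats::sd(fr) else NA_real_,
      below_lod = res$below_lod,
      lod_fraction_percent = res$lod_fraction_percent,
      display = if (res$below_lod) {
        sprintf("<LOD (%.1f%%)", res$lod_fraction_percent)
      } else {
        sprintf("%.1f", res$fraction_percent)
      }
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_json)) {
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
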