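# Readers and writers for the pipeline's table and grid formats.
# Gridded fields travel as long-format CSV (one row per cell-year) so the
# whole exchange surface is plain text.

.MEASUREMENT_COLS <- c("seal_id", "amino_acid", "replicate_index",
                       "d15n_measured", "standard_measured",
                       "standard_known", "catch_year", "age_years")

.schema_check <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  .assert(length(missing_cols) == 0L,
          sprintf("%s missing columns: %s", what,
                  paste(missing_cols, collapse = ", ")),
          "schema_error")
  bad <- required[vapply(required, function(cl) anyNA(df[[cl]]), logical(1))]
  .assert(length(bad) == 0L,
          sprintf("%s has missing values in: %s", what,
                  paste(bad, collapse = ", ")),
          "schema_error")
  invisible(df)
}

#' Read a measurement table
#'
#' @param path CSV file with the replicate measurement schema (`seal_id`,
#'   `amino_acid`, `replicate_index`, `d15n_measured`, `standard_measured`,
#'   `standard_known`, `catch_year`, `age_years`).
#' @return data frame; errors with class `schema_error` listing offending
#'   columns if the schema is violated.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .schema_check(df, .MEASUREMENT_COLS, "measurement table")
  df
}

#' Write a measurement table
#'
#' @param measurements data frame in the measurement schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  .schema_check(measurements, .MEASUREMENT_COLS, "measurement table")
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' Read and write per-seal record tables
#'
#' @param records data frame from [build_seal_records()].
#' @param path CSV path.
#' @return the records (read) or `path` invisibly (write).
#' @export
write_records <- function(records, path) {
  .schema_check(records, c("seal_id", "year", "d15n_phe", "qc_flag"),
                "record table")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .schema_check(df, c("seal_id", "year", "d15n_phe", "qc_flag"),
                "record table")
  df
}

#' Write a trend report as JSON
#'
#' @param fit a `trend_fit` from [fit_trend()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_trend_report <- function(fit, path) {
  .assert(inherits(fit, "trend_fit"), "fit must be a trend_fit",
          "invalid_input")
  keep <- c("slope_per_year", "slope_per_decade", "slope_se",
            "slope_se_per_decade", "intercept", "r_squared",
            "r_squared_pct", "f_statistic", "df_resid", "n", "p_value")
  jsonlite::write_json(fit[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read a section series as long-format CSV
#'
#' One row per (depth level, latitude index, year) with the velocity,
#' hydrography and isotope variables; grid geometry travels in the table.
#' The round trip `read_section_csv(write_section_csv(s))` is lossless.
#'
#' @param section a `section_series`.
#' @param path CSV path.
#' @return the section (read) or `path` invisibly (write).
#' @export
write_section_csv <- function(section, path) {
  d <- dim(section$u)
  g <- expand.grid(depth_idx = seq_len(d[1]), lat_idx = seq_len(d[2]),
                   year = section$years)
  g$uo <- as.vector(section$u)
  g$thetao <- as.vector(section$theta)
  g$so <- as.vector(section$salinity)
  g$no3 <- as.vector(section$no3)
  g$d15n_no3 <- as.vector(section$d15n_no3)
  g$cell_area <- as.vector(section$cell_area)[
    (g$lat_idx - 1L) * d[1] + g$depth_idx]
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_section_csv
#' @export
read_section_csv <- function(path) {
  g <- read.csv(path)
  .schema_check(g, c("depth_idx", "lat_idx", "year", "uo", "thetao", "so",
                     "no3", "d15n_no3", "cell_area"), "section table")
  # canonicalize: rows may arrive in any order
  g <- g[order(g$year, g$lat_idx, g$depth_idx), ]
  nd <- max(g$depth_idx)
  nl <- max(g$lat_idx)
  years <- sort(unique(g$year))
  d <- c(nd, nl, length(years))
  shape <- function(v) array(v, d)
  first_year <- g[g$year == years[1], ]
  structure(list(u = shape(g$uo), theta = shape(g$thetao),
                 salinity = shape(g$so), no3 = shape(g$no3),
                 d15n_no3 = shape(g$d15n_no3),
                 cell_area = matrix(first_year$cell_area, nd, nl),
                 years = years, truth = NULL),
            class = "section_series")
}

#' Write a box-model trajectory as CSV
#'
#' @param trajectory a `box_trajectory` from [run_scenario()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' The file may contain `forcing`, `inflow`, `box` and `experiment`
#' sections whose keys match the arguments of [deposition_forcing()],
#' [inflow_scenario()], [box_params()] and [paired_experiment()]. Unknown
#' keys are rejected by name.
#'
#' @param path YAML file.
#' @return list with `forcing`, `scenario`, `params`, `years`,
#'   `trend_window`.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_sections <- c("forcing", "inflow", "box", "experiment")
  unknown <- setdiff(names(cfg), known_sections)
  .assert(length(unknown) == 0L,
          paste("unknown config keys:", paste(unknown, collapse = ", ")),
          "schema_error")
  check_args <- function(given, fun, section) {
    unknown <- setdiff(names(given), names(formals(fun)))
    .assert(length(unknown) == 0L,
            sprintf("unknown keys in %s: %s", section,
                    paste(unknown, collapse = ", ")),
            "schema_error")
    given
  }
  forcing <- do.call(deposition_forcing,
                     check_args(cfg$forcing %||% list(), deposition_forcing,
                                "forcing"))
  scenario <- do.call(inflow_scenario,
                      check_args(cfg$inflow %||% list(), inflow_scenario,
                                 "inflow"))
  params <- do.call(box_params,
                    check_args(cfg$box %||% list(), box_params, "box"))
  exp_cfg <- cfg$experiment %||% list()
  allowed <- c("year_start", "year_end", "trend_start", "trend_end")
  unknown <- setdiff(names(exp_cfg), allowed)
  .assert(length(unknown) == 0L,
          paste("unknown keys in experiment:", paste(unknown, collapse = ", ")),
          "schema_error")
  years <- seq(exp_cfg$year_start %||% 1851, exp_cfg$year_end %||% 2019)
  tw <- seq(exp_cfg$trend_start %||% 1970, exp_cfg$trend_end %||% 2019)
  list(forcing = forcing, scenario = scenario, params = params,
       years = years, trend_window = intersect(tw, years))
}
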