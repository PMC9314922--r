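# Diagnostics on gridded ocean fields: water-mass masking, transport and its
# velocity/volume trend decomposition, nitrate flux, masked averages,
# regional means, integrated NPP, per-cell decadal trend maps and
# attribution percentages.
#
# A section is a depth x latitude grid per year; a region cube is a
# depth x latitude x longitude grid per year.

#' Atlantic Water mask
#'
#' A cell is Atlantic Water iff potential temperature exceeds 2 degC and
#' salinity exceeds 34.5 psu (strict inequalities; boundary cells are
#' excluded).
#'
#' @param theta potential temperature array (degC).
#' @param salinity salinity array (psu), same shape.
#' @return logical array of the same shape.
#' @export
aw_mask <- function(theta, salinity) {
  .assert(identical(dim(theta), dim(salinity)) &&
            length(theta) == length(salinity),
          "theta and salinity shapes differ", "invalid_input")
  theta > 2 & salinity > 34.5
}

# resolve the per-year mask for a section: user-supplied or from theta/S
.section_mask <- function(section, mask) {
  if (is.null(mask)) aw_mask(section$theta, section$salinity) else mask
}

#' Volume transport across a section
#'
#' Integrates the zonal velocity over the masked cells in depth and latitude:
#' `sum(u * cell_area) / 1e6` Sv per year.
#'
#' @param section a `section_series` (see [gen_section_series()]): list with
#'   arrays `u`, `theta`, `salinity`, `no3`, `d15n_no3` of shape
#'   depth x lat x year, `cell_area` (m^2, depth x lat) and `years`.
#' @param mask optional logical array depth x lat x year; defaults to the
#'   Atlantic Water mask computed from the section's theta and salinity.
#' @return numeric vector of transports (Sv) per year. Years with an empty
#'   mask are 0 and flagged in the `"empty_mask"` attribute (with a warning).
#' @export
transport <- function(section, mask = NULL) {
  mask <- .section_mask(section, mask)
  ny <- length(section$years)
  out <- numeric(ny)
  empty <- logical(ny)
  for (t in seq_len(ny)) {
    m <- mask[, , t]
    if (!any(m)) {
      empty[t] <- TRUE
      next
    }
    out[t] <- sum(section$u[, , t][m] * section$cell_area[m]) / 1e6
  }
  if (any(empty)) warning(sprintf("%d year(s) with empty mask: transport 0",
                                  sum(empty)))
  attr(out, "empty_mask") <- empty
  out
}

#' Nitrate flux across a section
#'
#' `sum(no3 * u * cell_area)` over masked cells, with nitrate converted from
#' mmol m^-3 to mol m^-3, giving mol s^-1 per year; also returns the running
#' cumulative transport of nitrate in mol.
#'
#' @inheritParams transport
#' @return data frame with `year`, `flux_mol_s` and `cumulative_mol`.
#' @export
nitrate_flux <- function(section, mask = NULL) {
  mask <- .section_mask(section, mask)
  ny <- length(section$years)
  flux <- numeric(ny)
  for (t in seq_len(ny)) {
    m <- mask[, , t]
    if (!any(m)) next
    flux[t] <- sum(section$no3[, , t][m] * 1e-3 * section$u[, , t][m] *
                     section$cell_area[m])
  }
  data.frame(year = section$years, flux_mol_s = flux,
             cumulative_mol = cumsum(flux * .SECONDS_PER_YEAR))
}

#' Masked weighted mean of a section field
#'
#' Area-weighted mean over masked cells per year; optionally transport
#' weighted (weights `u * cell_area`) for properties carried by the flow.
#'
#' @param field array depth x lat x year.
#' @param mask logical array of the same shape.
#' @param cell_area matrix depth x lat of cell areas (m^2); default equal
#'   weights.
#' @param flux_weight optional velocity array depth x lat x year; when given,
#'   weights are `u * cell_area` (transport weighting).
#' @return numeric vector per year; `NA` (flagged) for years with empty mask.
#' @export
masked_mean <- function(field, mask, cell_area = NULL, flux_weight = NULL) {
  .assert(identical(dim(field), dim(mask)), "field and mask shapes differ",
          "invalid_input")
  ny <- dim(field)[3]
  if (is.null(cell_area)) cell_area <- matrix(1, dim(field)[1], dim(field)[2])
  out <- rep(NA_real_, ny)
  for (t in seq_len(ny)) {
    m <- mask[, , t]
    if (!any(m)) next
    w <- cell_area[m]
    if (!is.null(flux_weight)) w <- w * flux_weight[, , t][m]
    out[t] <- sum(field[, , t][m] * w) / sum(w)
  }
  attr(out, "empty_mask") <- is.na(out)
  out
}

#' Upper-ocean regional mean of a cube field
#'
#' Volume-weighted mean over the upper layers (the first 10 levels when the
#' grid has at least 10, otherwise all levels no deeper than `max_depth_m`)
#' within a horizontal region mask, per year; also returns the per-cell
#' vertical means used for trend mapping.
#'
#' @param cube a `region_cube` (see [gen_region_fields()]).
#' @param field name of the cube field to average (e.g. `"d15n_pom"`).
#' @param region_mask logical matrix lat x lon; default all cells.
#' @param max_depth_m depth bound when fewer than 10 levels (default 100).
#' @return list with `mean` (numeric per year) and `per_cell` (array
#'   lat x lon x year of upper-ocean vertical means).
#' @export
regional_upper_mean <- function(cube, field, region_mask = NULL,
                                max_depth_m = 100) {
  arr <- cube[[field]]
  .assert(!is.null(arr), paste("cube has no field", field), "invalid_input")
  d <- dim(arr)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, d[2], d[3])
  .assert(all(dim(region_mask) == d[2:3]),
          "region mask shape must be lat x lon", "invalid_input")
  .assert(any(region_mask), "region mask is empty", "invalid_input")
  lev <- if (d[1] >= 10) 1:10 else which(cube$depth_bottom <= max_depth_m)
  thick <- cube$thickness[lev]
  # vertical (thickness-weighted) mean per column
  per_cell <- apply(arr[lev, , , , drop = FALSE], c(2, 3, 4), function(v) {
    sum(v * thick) / sum(thick)
  })
  w <- cube$cell_area * region_mask
  mean_series <- apply(per_cell, 3, function(sl) sum(sl * w) / sum(w))
  list(mean = mean_series, per_cell = per_cell)
}

#' Regionally averaged, vertically integrated net primary production
#'
#' Integrates the volumetric production rate vertically over each column
#' (sum of rate times layer thickness) and averages the column integrals,
#' area-weighted, over the region.
#'
#' @param cube a `region_cube` with an `npp` field (g C m^-3 yr^-1).
#' @param region_mask logical matrix lat x lon; default all cells.
#' @return numeric vector (g C m^-2 yr^-1) per year.
#' @export
integrate_npp <- function(cube, region_mask = NULL) {
  arr <- cube$npp
  .assert(!is.null(arr), "cube has no npp field", "invalid_input")
  d <- dim(arr)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, d[2], d[3])
  .assert(any(region_mask), "region mask is empty", "invalid_input")
  thick <- cube$thickness
  column <- apply(arr, c(2, 3, 4), function(v) sum(v * thick))
  w <- cube$cell_area * region_mask
  apply(column, 3, function(sl) sum(sl * w) / sum(w))
}

#' Decadal linear trend of an annual series
#'
#' OLS slope of `values` on `years`, scaled to per decade, with its standard
#' error and p-value.
#'
#' @param years numeric year axis (at least 3 distinct values).
#' @param values numeric series, same length.
#' @return list with `trend` (per decade), `se`, `p_value`.
#' @export
decadal_trend <- function(years, values) {
  .assert(length(years) >= 3L && length(values) == length(years),
          "need at least 3 paired years/values", "invalid_input")
  .assert(length(unique(years)) >= 2L, "year axis is constant",
          "singular_design")
  fit <- lm(values ~ years)
  s <- suppressWarnings(summary(fit))$coefficients
  list(trend = 10 * unname(s[2, 1]), se = 10 * unname(s[2, 2]),
       p_value = unname(s[2, 4]))
}

#' Per-cell decadal trend map
#'
#' Applies [decadal_trend()] to every cell of a lat x lon x year array and
#' summarizes the map (min, max, area-weighted mean). Cells with any missing
#' year are flagged `NA` and excluded from the summaries.
#'
#' @param per_cell array lat x lon x year (e.g. from
#'   [regional_upper_mean()]).
#' @param years year axis.
#' @param cell_area optional lat x lon weights for the mean (default equal).
#' @param region_mask optional logical lat x lon; cells outside are `NA`.
#' @return list with `map` (lat x lon of decadal trends), `min`, `max`,
#'   `mean` (area-weighted).
#' @export
trend_map <- function(per_cell, years, cell_area = NULL, region_mask = NULL) {
  d <- dim(per_cell)
  .assert(length(d) == 3L && d[3] == length(years),
          "per_cell must be lat x lon x year matching years", "invalid_input")
  if (is.null(cell_area)) cell_area <- matrix(1, d[1], d[2])
  if (is.null(region_mask)) region_mask <- matrix(TRUE, d[1], d[2])
  tmap <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!region_mask[i, j]) next
      v <- per_cell[i, j, ]
      if (anyNA(v)) next
      tmap[i, j] <- decadal_trend(years, v)$trend
    }
  }
  ok <- !is.na(tmap)
  list(map = tmap,
       min = min(tmap[ok]),
       max = max(tmap[ok]),
       mean = sum(tmap[ok] * cell_area[ok]) / sum(cell_area[ok]))
}

#' Velocity versus volume decomposition of a transport trend
#'
#' The transport trend through a section reflects both faster flow and a
#' growing Atlantic Water cross-sectional area. Dividing each year's
#' transport by that year's AW area and rescaling by the record-mean AW area
#' gives the volume-normalized transport; its decadal trend is the velocity
#' contribution, and the remainder of the total transport trend is the
#' volume contribution (the identity `velocity + volume = total` holds by
#' construction).
#'
#' @inheritParams transport
#' @param min_years minimum record length (default 10).
#' @param min_presence minimum fraction of years with a nonempty AW mask
#'   (default 0.8).
#' @return object of class `transport_decomposition`: list with
#'   `trend_total`, `trend_velocity`, `trend_volume` (Sv per decade),
#'   `mean_aw_area` (m^2) and the per-year series.
#' @export
transport_decomposition <- function(section, mask = NULL, min_years = 10,
                                    min_presence = 0.8) {
  mask <- .section_mask(section, mask)
  ny <- length(section$years)
  .assert(ny >= min_years, sprintf("need at least %d years", min_years),
          "invalid_input")
  area <- vapply(seq_len(ny), function(t) sum(section$cell_area[mask[, , t]]),
                 numeric(1))
  present <- area > 0
  .assert(mean(present) >= min_presence,
          "Atlantic Water absent in too many years", "invalid_input")
  if (!all(present)) warning(sprintf("%d year(s) without AW excluded",
                                     sum(!present)))
  tr <- suppressWarnings(transport(section, mask))
  yrs <- section$years[present]
  t_tot <- tr[present]
  a <- area[present]
  mean_area <- mean(a)
  t_norm <- t_tot / a * mean_area
  trend_total <- decadal_trend(yrs, t_tot)$trend
  trend_velocity <- decadal_trend(yrs, t_norm)$trend
  structure(list(trend_total = trend_total,
                 trend_velocity = trend_velocity,
                 trend_volume = trend_total - trend_velocity,
                 mean_aw_area = mean_area,
                 years = yrs, transport_sv = t_tot,
                 normalized_sv = t_norm, aw_area_m2 = a),
            class = "transport_decomposition")
}

#' @export
print.transport_decomposition <- function(x, ...) {
  cat(sprintf(paste0("Transport trend %.4f Sv/decade = velocity %.4f",
                     " + volume %.4f (mean AW area %.3g m^2)\n"),
              x$trend_total, x$trend_velocity, x$trend_volume, x$mean_aw_area))
  invisible(x)
}

#' Percent attribution between paired simulations
#'
#' `100 * (with - without) / without`, elementwise; used on cumulative
#' quantities (nitrate delivered, NPP) from the paired experiment. Zero
#' denominators give `NA`.
#'
#' @param with_series,without_series numeric series on the same year axis.
#' @return numeric vector of percent differences.
#' @export
attribution_pct <- function(with_series, without_series) {
  .assert(length(with_series) == length(without_series),
          "series lengths differ", "invalid_input")
  out <- 100 * (with_series - without_series) / without_series
  out[without_series == 0] <- NA_real_
  out
}
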