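# Seeded generators for every input the pipeline consumes, with known
# ground truth recorded alongside, so each downstream stage is testable
# without external downloads.

#' Ground truth for a synthetic seal isotope record
#'
#' The defaults emulate the study conditions of the archived record: 72
#' seals whose combined second/third-year growth-layer windows span
#' 1951-2012, a baseline near 11.7 permil declining at 0.36 permil per
#' decade, and 0.5 permil Gaussian noise (the reported single-measurement
#' precision of phenylalanine), acting both between individuals and between
#' replicates.
#'
#' @param baseline_delta d15N_Phe at the reference year (permil).
#' @param slope_per_year linear trend (permil yr^-1; -0.036 is -0.36 per
#'   decade).
#' @param noise_sd Gaussian noise sd (permil), applied independently at the
#'   individual and replicate level.
#' @param year_range two-year window coverage, `[start, end]`.
#' @param n_seals number of individuals (>= 2).
#' @param reference_year year at which `baseline_delta` applies.
#' @param drift_sd sd of the per-standard instrument offset that the
#'   nearest-standard correction removes (permil).
#' @param age_range inclusive range of ages at catch (minimum 5).
#' @param seed RNG seed.
#' @return object of class `seal_truth`.
#' @export
seal_truth <- function(baseline_delta = 11.7, slope_per_year = -0.036,
                       noise_sd = 0.5, year_range = c(1951, 2012),
                       n_seals = 72, reference_year = year_range[1],
                       drift_sd = 0.1, age_range = c(5, 15), seed = 1L) {
  .assert(noise_sd >= 0, "noise_sd must be non-negative")
  .assert(year_range[1] < year_range[2], "year_range must increase")
  .assert(n_seals >= 2, "n_seals must be at least 2")
  .assert(age_range[1] >= 5, "minimum age must be at least 5")
  structure(list(baseline_delta = baseline_delta,
                 slope_per_year = slope_per_year, noise_sd = noise_sd,
                 year_range = year_range, n_seals = n_seals,
                 reference_year = reference_year, drift_sd = drift_sd,
                 age_range = age_range, seed = seed),
            class = "seal_truth")
}

#' Generate a synthetic seal measurement table
#'
#' One row per replicate per seal, in the measurement CSV schema. Each seal
#' gets a two-year growth-layer window placed uniformly at random in the
#' year range; the expected d15N_Phe at the window midpoint follows the
#' prescribed linear baseline. Duplicate replicates carry independent noise
#' plus the offset of the nearest mixed standard (standards run every 4
#' sample injections), so the nearest-standard correction is exercisable
#' and, once applied, recovers the drift-free values exactly. Following the
#' measurement protocol, a third replicate is generated whenever the
#' duplicates disagree by more than `qc_tolerance`, so downstream QC
#' triplicates rather than discards such animals.
#'
#' @param truth a [seal_truth()].
#' @param qc_tolerance duplicate-range threshold triggering a third
#'   replicate (permil, default 1.0, matching [qc_replicates()]).
#' @return object of class `seal_dataset`: list with `measurements` (the
#'   replicate table) and `truth` (per-seal window, midpoint, true value).
#' @export
gen_seal_dataset <- function(truth, qc_tolerance = 1.0) {
  .assert(inherits(truth, "seal_truth"), "truth must be a seal_truth",
          "invalid_input")
  .with_seed(truth$seed, {
    n <- truth$n_seals
    yr <- truth$year_range
    ws <- sample(seq(yr[1], yr[2] - 1L), n, replace = TRUE)
    age <- sample(seq(truth$age_range[1], truth$age_range[2]), n,
                  replace = TRUE)
    catch <- ws + age - 1L   # window = [catch - age + 1, catch - age + 2]
    midpoint <- ws + 0.5
    true_val <- truth$baseline_delta +
      truth$slope_per_year * (midpoint - truth$reference_year)
    seal_eff <- rnorm(n, 0, truth$noise_sd)

    std_known <- 10.0   # certified phenylalanine value of the mixed standard
    rows <- vector("list", n)
    # standards run before every block of 4 sample injections; triplicated
    # samples can push the run long, so lay out enough standards for 3n
    std_pos <- seq(0.5, 3 * n + 0.5, by = 4)
    std_offset <- rnorm(length(std_pos), 0, truth$drift_sd)
    inj <- 0L
    for (i in seq_len(n)) {
      noise <- rnorm(2L, 0, truth$noise_sd)
      # duplicates outside the expected measurement error get a third run
      if (abs(noise[1] - noise[2]) > qc_tolerance) {
        noise <- c(noise, rnorm(1L, 0, truth$noise_sd))
      }
      n_repl <- length(noise)
      repl_idx <- seq_len(n_repl)
      inj_pos <- inj + repl_idx
      inj <- inj + n_repl
      nearest <- nearest_standard(inj_pos, std_pos)
      measured <- true_val[i] + seal_eff[i] + noise + std_offset[nearest]
      rows[[i]] <- data.frame(
        seal_id = sprintf("seal_%03d", i),
        amino_acid = "phenylalanine",
        replicate_index = repl_idx,
        d15n_measured = measured,
        standard_measured = std_known + std_offset[nearest],
        standard_known = std_known,
        catch_year = catch[i],
        age_years = age[i],
        stringsAsFactors = FALSE)
    }
    structure(list(
      measurements = do.call(rbind, rows),
      truth = data.frame(seal_id = sprintf("seal_%03d", seq_len(n)),
                         window_start = ws, window_end = ws + 1L,
                         midpoint_year = midpoint, true_d15n = true_val,
                         seal_effect = seal_eff, stringsAsFactors = FALSE),
      params = truth
    ), class = "seal_dataset")
  })
}

#' Specification of a synthetic ocean section
#'
#' A depth x latitude section per year with a rectangular Atlantic Water
#' core (warm, salty, eastward-flowing) embedded in ambient water that fails
#' the AW test. The core's velocity and width follow prescribed linear
#' trends, so the transport decomposition truth is known analytically.
#'
#' @param n_depth,n_lat,n_years grid dimensions (all >= 1).
#' @param year_start first simulated year.
#' @param cell_thickness cell height (m per depth level).
#' @param cell_width cell width (m per latitude step).
#' @param aw list describing the core: `depth_levels` (indices), `lat_start`
#'   (first core column), `width0` (initial width in cells),
#'   `growth_cells_per_year` (area trend, realized as whole columns),
#'   `u0` (m s^-1), `u_trend` (m s^-1 yr^-1), `t_c` (degC > 2), `s`
#'   (psu > 34.5), `no3` (mmol m^-3), `d15n0` (permil), `d15n_trend`
#'   (permil yr^-1).
#' @param ambient list with fields `u`, `t_c` (<= 2 or with `s` <= 34.5),
#'   `s`, `no3`, `d15n` for non-core cells.
#' @param noise_sd Gaussian noise added to u, no3 and d15n fields (0 keeps
#'   the analytic truths exact).
#' @return object of class `section_spec`.
#' @export
section_spec <- function(n_depth = 20, n_lat = 30, n_years = 50,
                         year_start = 1970, cell_thickness = 25,
                         cell_width = 1e4,
                         aw = list(depth_levels = 1:10, lat_start = 5,
                                   width0 = 6, growth_cells_per_year = 0.2,
                                   u0 = 0.1, u_trend = 0.002, t_c = 4,
                                   s = 35, no3 = 11, d15n0 = 5,
                                   d15n_trend = -0.01),
                         ambient = list(u = 0, t_c = 0.5, s = 34,
                                        no3 = 6, d15n = 6),
                         noise_sd = 0) {
  .assert(n_depth >= 1 && n_lat >= 1 && n_years >= 1, "all counts must be >= 1")
  .assert(cell_thickness > 0 && cell_width > 0,
          "cell geometry must be strictly positive")
  .assert(aw$t_c > 2 && aw$s > 34.5,
          "AW core must satisfy theta > 2 and S > 34.5")
  .assert(ambient$t_c <= 2 || ambient$s <= 34.5,
          "ambient water must fail the AW test")
  max_width <- aw$width0 +
    floor(aw$growth_cells_per_year * (n_years - 1))
  .assert(aw$lat_start + max_width - 1 <= n_lat && max(aw$depth_levels) <= n_depth,
          "AW core exceeds the grid")
  structure(list(n_depth = n_depth, n_lat = n_lat, n_years = n_years,
                 year_start = year_start, cell_thickness = cell_thickness,
                 cell_width = cell_width, aw = aw, ambient = ambient,
                 noise_sd = noise_sd),
            class = "section_spec")
}

#' Generate a synthetic section series with analytic transport truth
#'
#' @param spec a [section_spec()].
#' @param seed RNG seed (noise only).
#' @return object of class `section_series`: arrays `u`, `theta`,
#'   `salinity`, `no3`, `d15n_no3` (depth x lat x year), `cell_area`
#'   (depth x lat, m^2), `years`, and a `truth` list with the realized core
#'   velocity, AW area and transport per year plus the analytic trend
#'   decomposition (velocity contribution `10 * slope(u) * mean(A) / 1e6`,
#'   exact for the uniform core).
#' @export
gen_section_series <- function(spec, seed = 1L) {
  .assert(inherits(spec, "section_spec"), "spec must be a section_spec",
          "invalid_input")
  .with_seed(seed, {
    d <- c(spec$n_depth, spec$n_lat, spec$n_years)
    amb <- spec$ambient
    aw <- spec$aw
    u <- array(amb$u, d)
    theta <- array(amb$t_c, d)
    sal <- array(amb$s, d)
    no3 <- array(amb$no3, d)
    d15 <- array(amb$d15n, d)
    tt <- seq_len(spec$n_years) - 1L
    width <- aw$width0 + floor(aw$growth_cells_per_year * tt)
    u_core <- aw$u0 + aw$u_trend * tt
    d15_core <- aw$d15n0 + aw$d15n_trend * tt
    cell_area <- matrix(spec$cell_thickness * spec$cell_width,
                        spec$n_depth, spec$n_lat)
    for (t in seq_len(spec$n_years)) {
      cols <- seq(aw$lat_start, aw$lat_start + width[t] - 1L)
      u[aw$depth_levels, cols, t] <- u_core[t]
      theta[aw$depth_levels, cols, t] <- aw$t_c
      sal[aw$depth_levels, cols, t] <- aw$s
      no3[aw$depth_levels, cols, t] <- aw$no3
      d15[aw$depth_levels, cols, t] <- d15_core[t]
    }
    if (spec$noise_sd > 0) {
      u <- u + array(rnorm(prod(d), 0, spec$noise_sd * aw$u0), d)
      no3 <- no3 + array(rnorm(prod(d), 0, spec$noise_sd), d)
      d15 <- d15 + array(rnorm(prod(d), 0, spec$noise_sd), d)
    }
    area <- length(aw$depth_levels) * width *
      spec$cell_thickness * spec$cell_width
    transport_sv <- u_core * area / 1e6
    mean_area <- mean(area)
    years <- spec$year_start + tt
    truth <- list(
      u_core = u_core, aw_area_m2 = area, transport_sv = transport_sv,
      trend_total = 10 * .ols_slope(years, transport_sv),
      trend_velocity = 10 * .ols_slope(years, u_core * mean_area / 1e6))
    truth$trend_volume <- truth$trend_total - truth$trend_velocity
    structure(list(u = u, theta = theta, salinity = sal, no3 = no3,
                   d15n_no3 = d15, cell_area = cell_area, years = years,
                   truth = truth),
              class = "section_series")
  })
}

#' Generate synthetic regional field cubes with a prescribed trend map
#'
#' Builds depth x lat x lon x year cubes of d15N_POM, d15N_NO3, nitrate and
#' volumetric NPP in which each column's upper-ocean value follows a
#' prescribed per-cell decadal trend; with zero noise the per-cell OLS
#' decadal trends equal the prescribed map exactly.
#'
#' @param n_lon,n_lat,n_depth,n_years grid dimensions (all >= 1).
#' @param trend_map lat x lon matrix of decadal d15N_POM trends
#'   (permil per decade); default all `-0.05`.
#' @param base mean d15N_POM (permil) at the first year.
#' @param noise_sd Gaussian noise per cell-year (permil).
#' @param year_start first year.
#' @param thickness vector of layer thicknesses (m, default 10 m layers so
#'   ten levels span the upper 100 m).
#' @param cell_area horizontal cell area (m^2).
#' @param no3_base nitrate (mmol m^-3), constant.
#' @param npp_base volumetric NPP (g C m^-3 yr^-1) in the upper 100 m.
#' @param seed RNG seed.
#' @return object of class `region_cube` with the cube arrays, geometry
#'   (`depth_bottom`, `thickness`, `cell_area`), `years` and the prescribed
#'   `truth` trend map.
#' @export
gen_region_fields <- function(n_lon = 8, n_lat = 6, n_depth = 12,
                              n_years = 50, trend_map = NULL, base = 5,
                              noise_sd = 0, year_start = 1970,
                              thickness = rep(10, n_depth),
                              cell_area = 1e8, no3_base = 8, npp_base = 1,
                              seed = 1L) {
  .assert(n_lon >= 1 && n_lat >= 1 && n_depth >= 1 && n_years >= 1,
          "all dims must be >= 1")
  if (is.null(trend_map)) trend_map <- matrix(-0.05, n_lat, n_lon)
  .assert(all(dim(trend_map) == c(n_lat, n_lon)),
          "trend_map must be lat x lon", "invalid_input")
  .with_seed(seed, {
    d <- c(n_depth, n_lat, n_lon, n_years)
    tt <- seq_len(n_years) - 1L
    depth_bottom <- cumsum(thickness)
    d15n_pom <- array(0, d)
    for (t in seq_len(n_years)) {
      sl <- base + trend_map / 10 * tt[t]
      if (noise_sd > 0) sl <- sl + matrix(rnorm(n_lat * n_lon, 0, noise_sd),
                                          n_lat, n_lon)
      d15n_pom[, , , t] <- aperm(array(sl, c(n_lat, n_lon, n_depth)),
                                 c(3, 1, 2))
    }
    upper <- depth_bottom <= 100
    npp <- array(0, d)
    npp[upper, , , ] <- npp_base
    structure(list(d15n_pom = d15n_pom,
                   d15n_no3 = d15n_pom + 1,  # offset proxy, same trends
                   no3 = array(no3_base, d),
                   npp = npp,
                   thickness = thickness, depth_bottom = depth_bottom,
                   cell_area = matrix(cell_area, n_lat, n_lon),
                   years = year_start + tt,
                   truth = list(trend_map = trend_map, base = base)),
              class = "region_cube")
  })
}

#' Generate synthetic telemetry fixes from a Gaussian mixture
#'
#' Fix locations are drawn in the equal-area plane around a geographic
#' centre from a mixture of isotropic Gaussians, back-projected to lon/lat,
#' and dealt round-robin to animals. The mixture density is retained so
#' utilization-distribution estimates can be checked against the truth.
#'
#' @param n_animals number of tagged animals (>= 1).
#' @param n_fixes total number of fixes (>= 10).
#' @param centers_km matrix (k x 2) of component centres in km.
#' @param weights mixture weights (length k, normalized internally).
#' @param sigma_km isotropic component standard deviations (km, length k or
#'   1; must be positive).
#' @param center_lon,center_lat geographic centre of the study area.
#' @param seed RNG seed.
#' @return object of class `telemetry_dataset`: `fixes` (animal_id,
#'   timestamp, lon, lat) and `truth` (components, `density(x, y)` in the
#'   projected plane, `sample(m)` drawing fresh truth points, projection).
#' @export
gen_telemetry <- function(n_animals = 15, n_fixes = 2000,
                          centers_km = matrix(0, 1, 2), weights = 1,
                          sigma_km = 100, center_lon = 40, center_lat = 74,
                          seed = 1L) {
  .assert(n_animals >= 1, "n_animals must be >= 1")
  .assert(n_fixes >= 10, "n_fixes must be >= 10")
  k <- nrow(centers_km)
  if (length(sigma_km) == 1L) sigma_km <- rep(sigma_km, k)
  .assert(all(is.finite(sigma_km)) && all(sigma_km > 0),
          "degenerate component covariance")
  .assert(length(weights) == k && all(weights > 0), "invalid mixture weights")
  weights <- weights / sum(weights)
  proj <- laea_proj(center_lon, center_lat)
  draw <- function(m) {
    comp <- sample.int(k, m, replace = TRUE, prob = weights)
    cbind(x = rnorm(m, centers_km[comp, 1], sigma_km[comp]),
          y = rnorm(m, centers_km[comp, 2], sigma_km[comp]))
  }
  .with_seed(seed, {
    xy <- draw(n_fixes)
    ll <- laea_unproject(xy[, 1], xy[, 2], proj)
    fixes <- data.frame(
      animal_id = sprintf("srdl_%02d", rep_len(seq_len(n_animals), n_fixes)),
      timestamp = as.POSIXct("1995-03-01", tz = "UTC") +
        86400 * seq(0, length.out = n_fixes, by = 0.25),
      lon = ll[, "lon"], lat = ll[, "lat"])
    density_fun <- function(x, y) {
      out <- 0
      for (j in seq_len(k)) {
        out <- out + weights[j] *
          dnorm(x, centers_km[j, 1], sigma_km[j]) *
          dnorm(y, centers_km[j, 2], sigma_km[j])
      }
      out
    }
    structure(list(fixes = fixes,
                   truth = list(centers_km = centers_km, weights = weights,
                                sigma_km = sigma_km, proj = proj,
                                density = density_fun, sample = draw)),
              class = "telemetry_dataset")
  })
}
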