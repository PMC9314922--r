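test_that("the Atlantic Water definition uses strict thresholds", {
  expect_true(aw_mask(3.0, 35.0))
  expect_false(aw_mask(1.0, 35.0))
  expect_false(aw_mask(3.0, 34.0))
  # boundary values are excluded
  expect_false(aw_mask(2.0, 34.5))
  expect_false(aw_mask(2.0, 35.0))
  expect_false(aw_mask(3.0, 34.5))
  th <- array(c(3, 1), c(1, 2, 1))
  expect_error(aw_mask(th, array(35, c(2, 2, 1))), class = "invalid_input")
  # idempotent and invariant under positive scaling of unrelated fields
  m <- aw_mask(array(runif(8, 0, 5), c(2, 2, 2)),
               array(runif(8, 34, 35), c(2, 2, 2)))
  expect_identical(m & m, m)
})

test_that("transport integrates u over the masked section", {
  # 0.1 m/s over 10 masked cells of 1e5 m^2 = 1e6 m^2 -> 0.1 Sv
  sec <- uniform_section(0.1, nd = 2, nl = 5, ny = 3)
  tr <- transport(sec)
  expect_equal(as.numeric(tr), rep(0.1, 3))
  expect_equal(as.numeric(transport(uniform_section(0))), rep(0, 12))
  # randomized fields against the explicit cell loop
  set.seed(53)
  d <- c(4, 6, 8)
  sec2 <- make_section(u = array(rnorm(prod(d), 0.1, 0.05), d),
                       theta = array(runif(prod(d), 0, 5), d),
                       salinity = array(runif(prod(d), 34, 35.5), d),
                       no3 = array(runif(prod(d), 4, 14), d),
                       d15n = array(5, d),
                       cell_area = matrix(runif(24, 1e4, 1e6), 4, 6),
                       years = 2001:2008)
  msk <- aw_mask(sec2$theta, sec2$salinity)
  expect_equal(as.numeric(transport(sec2, msk)), loop_transport(sec2, msk),
               tolerance = 1e-12)
  # an all-false year yields zero with a warning and a flag
  msk[, , 3] <- FALSE
  expect_warning(tr3 <- transport(sec2, msk), "empty mask")
  expect_equal(tr3[3], 0)
  expect_true(attr(tr3, "empty_mask")[3])
})

test_that("nitrate flux factorizes for uniform fields and matches the loop", {
  sec <- uniform_section(0.1, nd = 2, nl = 5, ny = 3, no3 = 10)
  fl <- nitrate_flux(sec)
  tr <- transport(sec)
  # flux = c * T with units: 10 mmol/m3 * 0.1 Sv = 1000 mol/s
  expect_equal(fl$flux_mol_s, 10 * 1e-3 * as.numeric(tr) * 1e6,
               tolerance = 1e-12)
  expect_equal(nitrate_flux(uniform_section(0))$flux_mol_s, rep(0, 12))
  set.seed(59)
  d <- c(3, 4, 6)
  sec2 <- make_section(u = array(rnorm(prod(d), 0.1, 0.05), d),
                       theta = array(4, d), salinity = array(35, d),
                       no3 = array(runif(prod(d), 2, 14), d),
                       d15n = array(5, d),
                       cell_area = matrix(runif(12, 1e4, 1e6), 3, 4),
                       years = 2001:2006)
  msk <- array(TRUE, d)
  expect_equal(nitrate_flux(sec2, msk)$flux_mol_s,
               loop_nitrate_flux(sec2, msk), tolerance = 1e-12)
})

test_that("masked means are weighted correctly", {
  d <- c(1, 2, 1)
  sec_field <- array(c(4, 6), d)
  msk <- array(TRUE, d)
  expect_equal(as.numeric(masked_mean(sec_field, msk)), 5)
  # uniform field returns its value under any weighting
  f7 <- array(7, c(3, 4, 2))
  expect_equal(as.numeric(masked_mean(f7, array(TRUE, c(3, 4, 2)),
                                      matrix(runif(12), 3, 4))), c(7, 7))
  # area-weighted against an explicit loop
  set.seed(61)
  dd <- c(3, 5, 4)
  fld <- array(rnorm(prod(dd), 5), dd)
  mm <- array(runif(prod(dd)) > 0.3, dd)
  area <- matrix(runif(15, 1, 10), 3, 5)
  got <- masked_mean(fld, mm, area)
  want <- vapply(1:4, function(t) {
    num <- den <- 0
    for (i in 1:3) for (j in 1:5) if (mm[i, j, t]) {
      num <- num + fld[i, j, t] * area[i, j]
      den <- den + area[i, j]
    }
    num / den
  }, numeric(1))
  expect_equal(as.numeric(got), want, tolerance = 1e-12)
  # transport weighting shifts the mean toward fast cells
  u <- array(rep(c(1, 9), each = 1), c(1, 2, 1))
  fld2 <- array(c(4, 6), c(1, 2, 1))
  got2 <- masked_mean(fld2, array(TRUE, c(1, 2, 1)), flux_weight = u)
  expect_equal(as.numeric(got2), (4 * 1 + 6 * 9) / 10)
})

test_that("upper-ocean regional means honour the 100 m rule", {
  cube <- gen_region_fields(n_lon = 3, n_lat = 2, n_depth = 12, n_years = 4,
                            trend_map = matrix(0, 2, 3), base = 5)
  up <- regional_upper_mean(cube, "d15n_pom")
  expect_equal(up$mean, rep(5, 4))
  # value present only below 100 m is excluded from the mean
  cube$d15n_pom[11:12, , , ] <- 50
  expect_equal(regional_upper_mean(cube, "d15n_pom")$mean, rep(5, 4))
  # per-cell loop oracle on a perturbed cube
  set.seed(67)
  cube$d15n_pom[1:10, , , ] <- rnorm(10 * 2 * 3 * 4, 5)
  up2 <- regional_upper_mean(cube, "d15n_pom")
  for (t in 1:4) {
    acc <- 0
    for (i in 1:2) for (j in 1:3) {
      col <- sum(cube$d15n_pom[1:10, i, j, t] * cube$thickness[1:10]) /
        sum(cube$thickness[1:10])
      expect_equal(up2$per_cell[i, j, t], col, tolerance = 1e-12)
      acc <- acc + col * cube$cell_area[i, j]
    }
    expect_equal(up2$mean[t], acc / sum(cube$cell_area), tolerance = 1e-12)
  }
  expect_error(regional_upper_mean(cube, "d15n_pom",
                                   region_mask = matrix(FALSE, 2, 3)),
               class = "invalid_input")
})

test_that("vertically integrated production matches uniform closed forms", {
  cube <- gen_region_fields(n_lon = 2, n_lat = 2, n_depth = 12, n_years = 3,
                            trend_map = matrix(0, 2, 2), npp_base = 1)
  # 1 g C m^-3 yr^-1 over the 100 m of productive layers -> 100 g C m^-2
  expect_equal(integrate_npp(cube), rep(100, 3))
  cube$npp[] <- 0
  expect_equal(integrate_npp(cube), rep(0, 3))
})

test_that("decadal trends equal closed-form OLS at tight tolerance", {
  yrs <- 1970:2019
  got <- decadal_trend(yrs, 3 + 0.02 * yrs)
  expect_equal(got$trend, 0.2, tolerance = 1e-10)
  expect_equal(decadal_trend(yrs, rep(4, 50))$trend, 0)
  set.seed(71)
  for (i in 1:10) {
    y <- rnorm(50)
    expect_lt(abs(decadal_trend(yrs, y)$trend - 10 * ne_slope(yrs, y)),
              1e-10)
  }
  expect_error(decadal_trend(rep(2000, 5), rnorm(5)),
               class = "singular_design")
})

test_that("transport decomposition recovers constructed truths exactly", {
  # constant uniform velocity with growing AW area: all trend is volume
  sp <- section_spec(aw = modifyList(section_spec()$aw,
                                     list(u_trend = 0,
                                          growth_cells_per_year = 0.4)))
  dec <- transport_decomposition(gen_section_series(sp, seed = 1))
  expect_equal(dec$trend_velocity, 0, tolerance = 1e-10)
  expect_equal(dec$trend_volume, dec$trend_total, tolerance = 1e-10)
  # constant area with trending velocity: all trend is velocity
  sp2 <- section_spec(aw = modifyList(section_spec()$aw,
                                      list(growth_cells_per_year = 0)))
  dec2 <- transport_decomposition(gen_section_series(sp2, seed = 1))
  expect_equal(dec2$trend_volume, 0, tolerance = 1e-10)
  # mixed case against the generator's analytic truth
  sec3 <- gen_section_series(section_spec(), seed = 1)
  dec3 <- transport_decomposition(sec3)
  expect_equal(dec3$trend_total, sec3$truth$trend_total, tolerance = 1e-8)
  expect_equal(dec3$trend_velocity, sec3$truth$trend_velocity,
               tolerance = 1e-8)
  expect_equal(dec3$trend_volume, sec3$truth$trend_volume, tolerance = 1e-8)
  # the identity holds by construction
  expect_equal(dec3$trend_velocity + dec3$trend_volume, dec3$trend_total,
               tolerance = 1e-14)
  expect_error(transport_decomposition(uniform_section(0.1, ny = 5)),
               class = "invalid_input")
})

test_that("attribution percentages compare paired series", {
  x <- c(10, 20, 30)
  expect_equal(attribution_pct(x, x), c(0, 0, 0))
  expect_equal(attribution_pct(1.05 * x, x), rep(5, 3), tolerance = 1e-12)
  expect_true(is.na(attribution_pct(1, 0)))
  # cumulative and instantaneous flavours agree for proportional series
  yrs <- 1:30
  inst_wo <- 100 + 3 * yrs
  inst_w <- 1.05 * inst_wo
  cum_pct <- attribution_pct(cumsum(inst_w), cumsum(inst_wo))
  expect_equal(cum_pct, rep(5, 30), tolerance = 1e-10)
})
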