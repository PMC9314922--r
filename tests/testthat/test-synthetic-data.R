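test_that("seal dataset generation is deterministic and validates inputs", {
  tr <- seal_truth(seed = 42)
  d1 <- gen_seal_dataset(tr)
  d2 <- gen_seal_dataset(tr)
  expect_identical(d1$measurements, d2$measurements)
  expect_identical(d1$truth, d2$truth)
  expect_error(seal_truth(n_seals = 1), class = "invalid_parameter")
  expect_error(seal_truth(noise_sd = -1), class = "invalid_parameter")
  expect_error(seal_truth(year_range = c(2000, 1990)),
               class = "invalid_parameter")
  # schema: one row per replicate per seal; duplicates, triplicated when
  # the duplicates disagree by more than the measurement tolerance
  n_repl <- table(d1$measurements$seal_id)
  expect_true(all(n_repl %in% 2:3))
  # zero noise never triggers triplication
  d0 <- gen_seal_dataset(seal_truth(noise_sd = 0, seed = 42))
  expect_equal(nrow(d0$measurements), 2 * tr$n_seals)
  expect_true(all(d1$measurements$age_years >= 5))
  # every seal survives QC: disagreeing duplicates were triplicated
  rec <- build_seal_records(d1$measurements)
  expect_equal(nrow(rec[rec$qc_flag != "fail", ]), tr$n_seals)
  # window sits inside the year range and is consistent with catch/age
  m <- d1$measurements[d1$measurements$replicate_index == 1, ]
  expect_true(all(d1$truth$window_start >= 1951 &
                    d1$truth$window_end <= 2012))
  expect_equal(m$catch_year - m$age_years + 1, d1$truth$window_start)
})

test_that("zero-noise seal dataset yields exact slope recovery downstream", {
  tr <- seal_truth(noise_sd = 0, slope_per_year = -0.036, seed = 5)
  ds <- gen_seal_dataset(tr)
  rec <- build_seal_records(ds$measurements)
  fit <- fit_trend(rec)
  expect_equal(fit$slope_per_decade, -0.36, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # the instrument drift is fully removed by the nearest-standard correction
  expect_equal(rec$d15n_phe[order(rec$seal_id)],
               ds$truth$true_d15n[order(ds$truth$seal_id)],
               tolerance = 1e-12)
})

test_that("fitted slopes are unbiased across Monte Carlo replicates", {
  n_rep <- 200
  slopes <- vapply(seq_len(n_rep), function(i) {
    ds <- gen_seal_dataset(seal_truth(noise_sd = 0.5, seed = 1000 + i))
    fit_trend(build_seal_records(ds$measurements))$slope_per_year
  }, numeric(1))
  se_mean <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) - (-0.036)), 2 * se_mean + 1e-12)
})

test_that("section generator records analytic transport truths", {
  # pure volume change: constant velocity, growing core
  sp <- section_spec(aw = modifyList(section_spec()$aw,
                                     list(u_trend = 0,
                                          growth_cells_per_year = 0.4)))
  sec <- gen_section_series(sp, seed = 1)
  expect_equal(sec$truth$trend_velocity, 0)
  expect_equal(sec$truth$trend_volume, sec$truth$trend_total)
  # pure velocity change: constant core, trending velocity
  sp2 <- section_spec(aw = modifyList(section_spec()$aw,
                                      list(growth_cells_per_year = 0)))
  sec2 <- gen_section_series(sp2, seed = 1)
  expect_equal(sec2$truth$trend_volume, 0, tolerance = 1e-12)
  # 0.1 m/s over 1e6 m^2 is 0.1 Sv
  sp3 <- section_spec(n_depth = 4, n_lat = 6, n_years = 3,
                      cell_thickness = 100, cell_width = 2500,
                      aw = list(depth_levels = 1:4, lat_start = 2, width0 = 1,
                                growth_cells_per_year = 0, u0 = 0.1,
                                u_trend = 0, t_c = 4, s = 35, no3 = 11,
                                d15n0 = 5, d15n_trend = 0))
  sec3 <- gen_section_series(sp3, seed = 1)
  expect_equal(sec3$truth$aw_area_m2, rep(1e6, 3))
  expect_equal(sec3$truth$transport_sv, rep(0.1, 3))
  # invalid: core exceeding grid
  expect_error(section_spec(n_lat = 8,
                            aw = modifyList(section_spec()$aw,
                                            list(width0 = 10))),
               class = "invalid_parameter")
  # AW core and ambient definitions are enforced
  expect_error(section_spec(aw = modifyList(section_spec()$aw,
                                            list(t_c = 1.5))),
               class = "invalid_parameter")
  expect_error(section_spec(ambient = list(u = 0, t_c = 3, s = 35,
                                           no3 = 6, d15n = 6)),
               class = "invalid_parameter")
})

test_that("region cubes reproduce the prescribed per-cell trend map", {
  tm <- matrix(seq(-0.2, 0.1, length.out = 12), 3, 4)
  cube <- gen_region_fields(n_lon = 4, n_lat = 3, n_years = 20,
                            trend_map = tm, noise_sd = 0, seed = 2)
  up <- regional_upper_mean(cube, "d15n_pom")
  rec <- trend_map(up$per_cell, cube$years)
  expect_equal(rec$map, tm, tolerance = 1e-10)
  # constant field has zero trend everywhere
  cube0 <- gen_region_fields(n_lon = 2, n_lat = 2, n_years = 10,
                             trend_map = matrix(0, 2, 2), seed = 2)
  rec0 <- trend_map(regional_upper_mean(cube0, "d15n_pom")$per_cell,
                    cube0$years)
  expect_equal(rec0$map, matrix(0, 2, 2), tolerance = 1e-12)
})

test_that("noisy region trends are recovered without bias across cells", {
  tm <- matrix(-0.05, 10, 20)   # 200 cells
  cube <- gen_region_fields(n_lon = 20, n_lat = 10, n_depth = 3,
                            n_years = 40, trend_map = tm, noise_sd = 0.3,
                            thickness = rep(10, 3), seed = 9)
  rec <- trend_map(regional_upper_mean(cube, "d15n_pom")$per_cell,
                   cube$years)
  errs <- rec$map - tm
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 1e-12)
})

test_that("telemetry generator is deterministic and validates the mixture", {
  t1 <- gen_telemetry(n_fixes = 100, seed = 3)
  t2 <- gen_telemetry(n_fixes = 100, seed = 3)
  expect_identical(t1$fixes, t2$fixes)
  expect_error(gen_telemetry(n_fixes = 5), class = "invalid_parameter")
  expect_error(gen_telemetry(sigma_km = 0), class = "invalid_parameter")
  expect_equal(nrow(t1$fixes), 100)
  expect_true(all(abs(t1$fixes$lat) <= 90))
})
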