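test_that("delta mixing is mass-weighted and close to exact ratio mixing", {
  expect_equal(mix_delta(c(1, 1), c(5, 3)), 4)
  expect_equal(mix_delta(2.5, 7.1), 7.1)
  expect_error(mix_delta(c(0, 0), c(5, 3)), class = "invalid_input")
  expect_error(mix_delta(c(-1, 2), c(5, 3)), class = "invalid_input")
  # three-component mixes against the exact 15N/14N-ratio oracle
  set.seed(31)
  for (i in 1:25) {
    m <- runif(3, 0.1, 10)
    d <- runif(3, -10, 10)
    expect_lt(abs(mix_delta(m, d) - ratio_mix_delta(m, d)), 0.01)
  }
})

test_that("Rayleigh fractionation obeys closed forms, limits and mass balance", {
  got <- rayleigh_product(5, 0.5, 5)
  expect_equal(got$delta_pom, 5 - 5 * log(2), tolerance = 1e-12)
  expect_equal(got$delta_residual, 5 + 5 * log(2), tolerance = 1e-12)
  # complete consumption returns the supply delta; zero eps is inert
  expect_equal(rayleigh_product(5, 0, 5)$delta_pom, 5)
  for (f in c(0.1, 0.5, 0.9)) {
    expect_equal(rayleigh_product(4.2, f, 0)$delta_pom, 4.2)
  }
  expect_error(rayleigh_product(5, 1.2, 5), class = "invalid_input")
  # mass balance f d_resid + (1 - f) d_pom = d_supply, both model forms
  set.seed(37)
  for (i in 1:50) {
    ds <- runif(1, -5, 10)
    f <- runif(1, 0.01, 0.99)
    eps <- runif(1, 0, 10)
    for (mode in c("rayleigh", "open")) {
      r <- rayleigh_product(ds, f, eps, mode = mode)
      expect_lt(abs(f * r$delta_residual + (1 - f) * r$delta_pom - ds), 1e-10)
    }
  }
})

test_that("a null step leaves the state unchanged", {
  p <- box_params(uptake_mode = "fraction", u_frac = 0, export_frac = 0,
                  remin_frac = 0)
  st <- box_state(p)
  st$p_barents <- 0
  f <- list(year = 2000, q_sv = 0, no3_in = 0, delta_end = 5,
            dep_atlantic = 0, dep_barents = 0, delta_dep = -4)
  out <- step_year(st, p, f)
  for (nm in names(st)) expect_equal(out$state[[nm]], st[[nm]], tolerance = 1e-12)
  expect_equal(out$diagnostics$npp, 0)
  f$q_sv <- -1
  expect_error(step_year(st, p, f), class = "invalid_input")
})

test_that("light deposition lowers the supplied nitrate delta in one step", {
  p <- box_params(uptake_mode = "fraction", u_frac = 0.5)
  st <- box_state(p)
  f_on <- list(year = 2000, q_sv = 2, no3_in = 11, delta_end = 5,
               dep_atlantic = 0, dep_barents = 5e10, delta_dep = -4)
  f_off <- modifyList(f_on, list(dep_barents = 0))
  on <- step_year(st, p, f_on)
  off <- step_year(st, p, f_off)
  expect_lt(on$diagnostics$delta_pom, off$diagnostics$delta_pom)
  expect_lt(on$state$delta_no3, off$state$delta_no3)
})

test_that("closed-system stepping conserves total 15N-equivalent mass", {
  # no exchange with the outside: no inflow, no deposition, no export
  set.seed(41)
  for (i in 1:5) {
    p <- box_params(uptake_mode = "fraction", u_frac = runif(1, 0.1, 0.9),
                    export_frac = 0, remin_frac = runif(1, 0.1, 0.9),
                    eps_assim = runif(1, 0, 10))
    st <- box_state(p)
    f <- list(year = 2000, q_sv = 0, no3_in = 0, delta_end = 5,
              dep_atlantic = 0, dep_barents = 0, delta_dep = -4)
    m0 <- state_isotope_mass(st)
    total0 <- st$n_barents + st$p_barents
    for (k in 1:10) st <- step_year(st, p, f)$state
    expect_equal(st$n_barents + st$p_barents, total0, tolerance = 1e-12)
    expect_lt(abs(state_isotope_mass(st) - m0) / abs(m0), 1e-9)
  }
})

test_that("constant forcing reaches a steady state with zero trends", {
  p <- box_params(capacity_trend = 0, spinup_tol = 1e-12)
  f <- deposition_forcing(regional_scaling = 0.02)
  sc <- inflow_scenario(q_trend = 0, f_subtropical_trend = 0)
  traj <- run_scenario(p, f, sc, 1970:2019, anthropogenic = FALSE)
  expect_lt(abs(decadal_trend(traj$year, traj$delta_in)$trend), 1e-8)
  expect_lt(abs(decadal_trend(traj$year, traj$delta_pom)$trend), 1e-8)
  expect_lt(abs(decadal_trend(traj$year, traj$npp)$trend), 1e-8)
})

test_that("spin-up failure is reported with diagnostics", {
  p <- box_params(spinup_tol = 0, spinup_max = 5)
  expect_error(run_scenario(p, deposition_forcing(), inflow_scenario(),
                            1970:2019, FALSE),
               class = "spinup_error")
})

test_that("nitrate delivery is linear in transport at fixed concentrations", {
  f <- deposition_forcing(regional_scaling = 0)   # keeps c_A = no3_in
  p <- box_params(capacity_trend = 0, spinup_tol = 1e-10)
  t1 <- run_scenario(p, f, inflow_scenario(q0 = 1, q_trend = 0,
                                           f_subtropical_trend = 0),
                     2000:2010, FALSE)
  t2 <- run_scenario(p, f, inflow_scenario(q0 = 2, q_trend = 0,
                                           f_subtropical_trend = 0),
                     2000:2010, FALSE)
  expect_equal(t2$nitrate_delivered[1] / t1$nitrate_delivered[1], 2,
               tolerance = 1e-6)
})

test_that("the historical ramp drives a negative inflow delta trend", {
  d <- demo_experiment()
  traj <- run_scenario(d$params, d$forcing, d$scenario, d$years, TRUE)
  w <- traj[traj$year >= 1970, ]
  expect_lt(decadal_trend(w$year, w$delta_in)$trend, 0)
})

test_that("a zero deposition scaling collapses the paired experiment", {
  f0 <- deposition_forcing(regional_scaling = 0)
  rep0 <- paired_experiment(box_params(), f0, inflow_scenario(),
                            years = 1960:2019, trend_window = 1970:2019)
  expect_equal(rep0$pct_nitrate, 0)
  expect_equal(rep0$pct_npp, 0)
  expect_equal(rep0$trends$with_deposition, rep0$trends$without_deposition)
  # with no deposition flux the run is independent of delta_dep and anchors
  fA <- deposition_forcing(delta_dep = -4, regional_scaling = 0)
  fB <- deposition_forcing(delta_dep = -12, regional_scaling = 0,
                           modern_multiple = 5)
  tA <- run_scenario(box_params(), fA, inflow_scenario(), 1990:2010, TRUE)
  tB <- run_scenario(box_params(), fB, inflow_scenario(), 1990:2010, TRUE)
  expect_equal(tA$delta_pom, tB$delta_pom, tolerance = 1e-12)
  # the control run is independent of the anchor magnitudes
  tC <- run_scenario(box_params(), deposition_forcing(modern_multiple = 3),
                     inflow_scenario(), 1990:2010, FALSE)
  tD <- run_scenario(box_params(), deposition_forcing(modern_multiple = 5),
                     inflow_scenario(), 1990:2010, FALSE)
  expect_equal(tC$delta_pom, tD$delta_pom, tolerance = 1e-12)
})

test_that("deposition pushes new-production delta trends down across scenarios", {
  set.seed(43)
  for (i in 1:20) {
    f <- deposition_forcing(regional_scaling = runif(1, 0.01, 0.05),
                            modern_multiple = runif(1, 2.5, 4.5))
    sc <- inflow_scenario(q0 = runif(1, 1.5, 3),
                          q_trend = runif(1, 0, 0.012),
                          f_subtropical0 = runif(1, 0, 0.4),
                          f_subtropical_trend = runif(1, 0, 0.005))
    p <- box_params(capacity_trend = runif(1, 0, 0.007),
                    eps_assim = runif(1, 3, 7))
    rep_ <- paired_experiment(p, f, sc, years = 1900:2019,
                              trend_window = 1970:2019)
    tr <- rep_$trends
    expect_lt(tr$with_deposition[tr$quantity == "delta_pom"],
              tr$without_deposition[tr$quantity == "delta_pom"])
    expect_lt(tr$with_deposition[tr$quantity == "delta_in"],
              tr$without_deposition[tr$quantity == "delta_in"])
    expect_gt(rep_$pct_nitrate, 0)
  }
})

test_that("delta_pom responds monotonically to deposition and utilization", {
  # finite differences on random parameter draws
  set.seed(47)
  mean_dpom <- function(scaling, u) {
    f <- deposition_forcing(regional_scaling = scaling)
    p <- box_params(uptake_mode = "fraction", u_frac = u,
                    capacity_trend = 0)
    traj <- run_scenario(p, f, inflow_scenario(), 1990:2010, TRUE)
    mean(traj$delta_pom)
  }
  for (i in 1:5) {
    s0 <- runif(1, 0.005, 0.04)
    u0 <- runif(1, 0.3, 0.85)
    expect_lte(mean_dpom(s0 + 0.01, u0), mean_dpom(s0, u0) + 1e-10)
    expect_gte(mean_dpom(s0, u0 + 0.05), mean_dpom(s0, u0) - 1e-10)
  }
})

test_that("uptake converts to areal production with the C:N ratio", {
  p <- box_params(barents_area = 1)
  expect_equal(npp_from_uptake(0, p), 0)
  expect_equal(npp_from_uptake(1, p), 6.625 * 12.011, tolerance = 1e-12)
  expect_equal(npp_from_uptake(3, p), 3 * npp_from_uptake(1, p))
  expect_error(npp_from_uptake(-1, p), class = "invalid_input")
})
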