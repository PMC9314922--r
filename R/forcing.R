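# Historical atmospheric reactive-nitrogen deposition forcing and the
# Atlantic-inflow scenario functions that drive the box model.

#' Atmospheric reactive-nitrogen deposition forcing
#'
#' Global deposition is held at its preindustrial rate (11 Tg N yr^-1) up to
#' 1850 and then increases piecewise linearly through anchor years 1850, 2000
#' and 2030, with the additional constraint that 60% of the 1850-2000 rate
#' increase occurs from 1950 onwards (a kink at 1950). Deposited nitrogen
#' carries a fixed, isotopically light signature (default -4 permil).
#'
#' The 2000 and 2030 anchor magnitudes are not fixed by the historical rule
#' itself; they default to `modern_multiple` (and `1.08 * modern_multiple`)
#' times the preindustrial rate, a configurable stand-in consistent with
#' modern global deposition estimates of roughly 35-45 Tg N yr^-1.
#'
#' @param preindustrial_rate Tg N yr^-1 before 1851 (default 11).
#' @param modern_multiple year-2000 rate as a multiple of preindustrial
#'   (default 3.5, i.e. 38.5 Tg N yr^-1).
#' @param multiple_2030 year-2030 rate as a multiple of the year-2000 rate
#'   (default 1.08).
#' @param post1950_fraction fraction of the 1850-2000 increase occurring
#'   after 1950 (default 0.60).
#' @param delta_dep delta15N of deposited nitrogen (permil, default -4).
#' @param regional_scaling fraction of the global deposition rate delivered
#'   to the model domain (Atlantic source box + Barents box); default 0.028,
#'   chosen so the with/without difference in cumulative nitrate delivered
#'   across the Barents Sea Opening is about 5% in demonstration runs.
#' @param atlantic_fraction share of the regional deposition entering the
#'   Atlantic source box (the rest falls directly on the Barents box).
#' @return object of class `deposition_forcing`.
#' @export
deposition_forcing <- function(preindustrial_rate = 11,
                               modern_multiple = 3.5,
                               multiple_2030 = 1.08,
                               post1950_fraction = 0.60,
                               delta_dep = -4,
                               regional_scaling = 0.028,
                               atlantic_fraction = 0.9) {
  .assert(.is_number(preindustrial_rate) && preindustrial_rate > 0,
          "preindustrial_rate must be positive")
  .assert(.is_number(modern_multiple) && modern_multiple >= 1,
          "modern_multiple must be >= 1")
  .assert(.is_number(post1950_fraction) && post1950_fraction >= 0 &&
            post1950_fraction <= 1, "post1950_fraction must be in [0, 1]")
  .assert(.is_number(regional_scaling) && regional_scaling >= 0,
          "regional_scaling must be non-negative")
  .assert(.is_number(atlantic_fraction) && atlantic_fraction >= 0 &&
            atlantic_fraction <= 1, "atlantic_fraction must be in [0, 1]")
  rate_1850 <- preindustrial_rate
  rate_2000 <- modern_multiple * preindustrial_rate
  rate_2030 <- multiple_2030 * rate_2000
  # 60%-post-1950 rule pins the 1950 rate between the 1850 and 2000 anchors
  rate_1950 <- rate_1850 + (1 - post1950_fraction) * (rate_2000 - rate_1850)
  structure(list(
    preindustrial_rate = preindustrial_rate,
    anchor_years = c(1850, 1950, 2000, 2030),
    anchor_rates = c(rate_1850, rate_1950, rate_2000, rate_2030),
    post1950_fraction = post1950_fraction,
    delta_dep = delta_dep,
    regional_scaling = regional_scaling,
    atlantic_fraction = atlantic_fraction,
    year_range = c(1648, 2030)
  ), class = "deposition_forcing")
}

#' Global deposition rate for a given year
#'
#' @param year calendar year(s) within the supported range (1648-2030).
#' @param forcing a [deposition_forcing()].
#' @param anthropogenic if `FALSE` (the control experiment), the
#'   preindustrial rate is returned for every year; if `TRUE`, the piecewise
#'   linear historical ramp applies from 1851 onwards.
#' @return deposition rate(s) in Tg N yr^-1.
#' @export
deposition_rate <- function(year, forcing, anthropogenic = TRUE) {
  .assert(inherits(forcing, "deposition_forcing"),
          "forcing must be a deposition_forcing", "invalid_input")
  .assert(all(is.finite(year)), "year must be finite", "invalid_input")
  .assert(all(year >= forcing$year_range[1] & year <= forcing$year_range[2]),
          sprintf("year outside supported range [%d, %d]",
                  forcing$year_range[1], forcing$year_range[2]),
          "invalid_input")
  if (!anthropogenic) return(rep(forcing$preindustrial_rate, length(year)))
  ay <- forcing$anchor_years
  ar <- forcing$anchor_rates
  out <- numeric(length(year))
  pre <- year <= ay[1]
  out[pre] <- forcing$preindustrial_rate
  if (any(!pre)) {
    # piecewise linear through (1850, 1950, 2000, 2030)
    out[!pre] <- approx(ay, ar, xout = pmin(year[!pre], ay[length(ay)]),
                        rule = 2)$y
  }
  out
}

#' Deposition time series with cumulative deposited mass
#'
#' @inheritParams deposition_rate
#' @param years sorted vector of calendar years.
#' @return data frame with `year`, `rate` (Tg N yr^-1) and `cumulative`
#'   (Tg N, trapezoidal integral from the first year).
#' @export
deposition_timeseries <- function(years, forcing, anthropogenic = TRUE) {
  .assert(!is.unsorted(years), "years must be sorted", "invalid_input")
  rate <- deposition_rate(years, forcing, anthropogenic)
  data.frame(year = years, rate = rate,
             cumulative = .cum_trapz(years, rate))
}

#' Atlantic inflow scenario
#'
#' Describes the Atlantic Water entering the Barents Sea: volume transport,
#' inflow nitrate concentration, and the evolving mixture of subpolar and
#' subtropical source waters whose delta15N_NO3 endmembers differ. Ramps are
#' linear from `ramp_start` (values are held constant before it, emulating
#' the recent-decades onset of Atlantification).
#'
#' Default endmember values (5.0 permil subpolar, 3.5 permil subtropical) are
#' literature-based configuration defaults, not measured inputs.
#'
#' @param q0 transport at `ramp_start` (Sv, default 2.0).
#' @param q_trend transport trend (Sv yr^-1, default 0.009, i.e. +0.09 Sv
#'   per decade).
#' @param no3_in0 inflow nitrate concentration (mmol m^-3, default 11).
#' @param no3_trend nitrate concentration trend (mmol m^-3 yr^-1, default 0).
#' @param f_subtropical0 subtropical fraction at `ramp_start` (default 0.25).
#' @param f_subtropical_trend change per year (default 0.004).
#' @param delta_subpolar,delta_subtropical endmember delta15N_NO3 (permil).
#' @param conc_subpolar,conc_subtropical endmember nitrate concentrations
#'   used for concentration-weighted mixing (equal by default).
#' @param ramp_start year the linear ramps begin (default 1970).
#' @return object of class `inflow_scenario`.
#' @export
inflow_scenario <- function(q0 = 2.0, q_trend = 0.009,
                            no3_in0 = 11, no3_trend = 0,
                            f_subtropical0 = 0.25, f_subtropical_trend = 0.004,
                            delta_subpolar = 5.0, delta_subtropical = 3.5,
                            conc_subpolar = 1, conc_subtropical = 1,
                            ramp_start = 1970) {
  .assert(q0 > 0, "q0 must be positive")
  .assert(no3_in0 > 0, "no3_in0 must be positive")
  .assert(f_subtropical0 >= 0 && f_subtropical0 <= 1,
          "f_subtropical0 must be in [0, 1]")
  .assert(delta_subtropical < delta_subpolar,
          "subtropical endmember must be lighter than subpolar")
  structure(list(q0 = q0, q_trend = q_trend, no3_in0 = no3_in0,
                 no3_trend = no3_trend, f_subtropical0 = f_subtropical0,
                 f_subtropical_trend = f_subtropical_trend,
                 delta_subpolar = delta_subpolar,
                 delta_subtropical = delta_subtropical,
                 conc_subpolar = conc_subpolar,
                 conc_subtropical = conc_subtropical,
                 ramp_start = ramp_start),
            class = "inflow_scenario")
}

.ramp_years <- function(year, scenario) pmax(0, year - scenario$ramp_start)

#' Scenario transport, nitrate and subtropical fraction at a given year
#'
#' @param scenario an [inflow_scenario()].
#' @param year calendar year(s).
#' @return numeric vector.
#' @export
scenario_q <- function(scenario, year) {
  pmax(1e-6, scenario$q0 + scenario$q_trend * .ramp_years(year, scenario))
}

#' @rdname scenario_q
#' @export
scenario_no3 <- function(scenario, year) {
  pmax(0, scenario$no3_in0 + scenario$no3_trend * .ramp_years(year, scenario))
}

#' @rdname scenario_q
#' @export
scenario_f_subtropical <- function(scenario, year) {
  pmin(1, pmax(0, scenario$f_subtropical0 +
                 scenario$f_subtropical_trend * .ramp_years(year, scenario)))
}

#' Endmember delta15N_NO3 of the Atlantic inflow
#'
#' Nitrate-concentration-weighted mixture of the subpolar and subtropical
#' endmembers; with equal endmember concentrations (the default) this reduces
#' to the linear mix `(1 - f) * delta_sp + f * delta_st`.
#'
#' @param year calendar year(s).
#' @param scenario an [inflow_scenario()].
#' @return delta15N_NO3 of the inflow endmember mixture (permil).
#' @export
#' @examples
#' sc <- inflow_scenario(f_subtropical0 = 0.4, f_subtropical_trend = 0)
#' endmember_delta(1970, sc)  # 5.0 - 0.4 * 1.5 = 4.4
endmember_delta <- function(year, scenario) {
  .assert(inherits(scenario, "inflow_scenario"),
          "scenario must be an inflow_scenario", "invalid_input")
  f <- scenario_f_subtropical(scenario, year)
  .assert(all(f >= 0 & f <= 1), "subtropical fraction outside [0, 1]")
  w_sp <- (1 - f) * scenario$conc_subpolar
  w_st <- f * scenario$conc_subtropical
  (w_sp * scenario$delta_subpolar + w_st * scenario$delta_subtropical) /
    (w_sp + w_st)
}
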