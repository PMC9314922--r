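# Internal helpers shared across modules.

# mean Julian year; all annual fluxes use this conversion
.SECONDS_PER_YEAR <- 365.25 * 86400
.EARTH_RADIUS_KM <- 6371.0088
.N_MOLAR_MASS <- 14.0067   # g mol^-1
.C_MOLAR_MASS <- 12.011    # g mol^-1

#' Convert a volume transport in Sverdrups to cubic metres per year
#'
#' 1 Sv = 1e6 m^3 s^-1.
#'
#' @param q_sv transport in Sv.
#' @return volume flux in m^3 yr^-1.
#' @export
sv_to_m3_per_year <- function(q_sv) q_sv * 1e6 * .SECONDS_PER_YEAR

#' Convert a nitrogen mass in teragrams to moles of N
#'
#' @param tg mass in Tg N.
#' @return amount in mol N.
#' @export
tg_to_mol_n <- function(tg) tg * 1e12 / .N_MOLAR_MASS

.assert <- function(cond, msg, class = "invalid_parameter") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "barentsiso_error", "error", "condition")))
  }
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# cumulative trapezoidal integral of y over x, same length as x
.cum_trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

# closed-form OLS slope via normal equations; used by generators so that
# recorded truths do not depend on the lm-based analysis path
.ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

# evaluate code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so generators are pure functions of (params, seed)
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
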