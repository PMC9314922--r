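# Corrected, QC'd, year-anchored d15N_Phe records from replicate
# amino-acid measurements, and their multi-decadal trend.

#' Correct replicate amino-acid delta values against the nearest standard
#'
#' Compound-specific amino-acid delta15N measurements drift with the response
#' of each amino acid to the chromatographic column. The reported value is the
#' replicate mean minus the offset between the measured and certified value of
#' the same amino acid in the nearest-run mixed standard:
#' \deqn{\delta_{reported} = \overline{\delta_{sample}} -
#'       (\delta_{std,measured} - \delta_{std,known})}
#'
#' @param sample_replicates numeric vector of replicate delta15N values (permil).
#' @param standard_measured measured delta15N of the amino acid in the nearest
#'   mixed standard (permil).
#' @param standard_known certified delta15N of that standard (permil).
#' @return corrected delta15N (permil).
#' @export
#' @examples
#' correct_delta(c(12.4, 11.6), 10.5, 10.0)  # 11.5
correct_delta <- function(sample_replicates, standard_measured, standard_known) {
  .assert(length(sample_replicates) >= 1L, "at least one replicate required",
          "invalid_input")
  .assert(all(is.finite(sample_replicates)), "replicates must be finite",
          "invalid_input")
  .assert(.is_number(standard_measured) && .is_number(standard_known),
          "standard values must be finite scalars", "invalid_input")
  mean(sample_replicates) - (standard_measured - standard_known)
}

#' Assign each sample injection to its nearest standard injection
#'
#' Mixed standards are interleaved with samples during a run (one standard
#' every few injections); each sample is corrected against the standard whose
#' injection position is closest. Ties go to the earlier standard.
#'
#' @param sample_positions numeric vector of sample injection positions.
#' @param standard_positions numeric vector of standard injection positions.
#' @return integer vector: index into `standard_positions` for each sample.
#' @export
nearest_standard <- function(sample_positions, standard_positions) {
  .assert(length(standard_positions) >= 1L, "need at least one standard",
          "invalid_input")
  vapply(sample_positions, function(p) {
    which.min(abs(standard_positions - p))
  }, integer(1))
}

#' Quality control of replicate measurements
#'
#' Duplicate measurements whose spread exceeds the expected measurement error
#' trigger a third replicate; duplicates that disagree and were never
#' triplicated fail QC and are excluded from trend fitting by default.
#'
#' @param replicates numeric vector of (corrected) replicate values (permil).
#' @param tolerance maximum acceptable replicate range (permil, default 1.0).
#' @return list with `final_value` (mean of replicates) and `qc_flag`, one of
#'   `"pass"`, `"triplicated"`, `"fail"`.
#' @export
qc_replicates <- function(replicates, tolerance = 1.0) {
  .assert(length(replicates) >= 2L, "at least two replicates required",
          "invalid_input")
  .assert(all(is.finite(replicates)), "replicates must be finite", "invalid_input")
  rng <- max(replicates) - min(replicates)
  flag <- if (rng <= tolerance) "pass"
          else if (length(replicates) >= 3L) "triplicated"
          else "fail"
  list(final_value = mean(replicates), qc_flag = flag)
}

#' Growth-layer-group window for one seal
#'
#' Each growth layer group (GLG) in dentine records one year of life; the
#' second and third GLGs of seals aged at least five at catch are combined, so
#' one measurement integrates calendar years `birth_year + 1` and
#' `birth_year + 2` with `birth_year = catch_year - age_years`.
#'
#' @param catch_year calendar year the animal was caught.
#' @param age_years age (GLG count) at catch; must be at least `min_age`.
#' @param min_age minimum admissible age (default 5).
#' @param archive_range plausible catch-year range, used as a sanity bound.
#' @param on_young `"error"` (default) to reject under-age animals, or
#'   `"flag"` to return the window with `qc_flag = "fail"`.
#' @return list with `window` (c(start, end)), `midpoint` and `qc_flag`.
#' @export
#' @examples
#' assign_glg_years(1957, 6)  # window 1952-1953, midpoint 1952.5
assign_glg_years <- function(catch_year, age_years, min_age = 5,
                             archive_range = c(1900, 2100),
                             on_young = c("error", "flag")) {
  on_young <- match.arg(on_young)
  .assert(.is_number(catch_year) && .is_number(age_years),
          "catch_year and age_years must be finite scalars", "invalid_input")
  .assert(age_years == round(age_years) && age_years >= 1,
          "age_years must be a positive integer", "invalid_input")
  .assert(catch_year >= archive_range[1] && catch_year <= archive_range[2],
          sprintf("catch_year %s outside plausible archive range [%s, %s]",
                  catch_year, archive_range[1], archive_range[2]),
          "invalid_input")
  flag <- "pass"
  if (age_years < min_age) {
    if (on_young == "error") {
      .assert(FALSE, sprintf("age %s below minimum age %s", age_years, min_age),
              "qc_exclusion")
    }
    flag <- "fail"
  }
  birth_year <- catch_year - age_years
  window <- c(birth_year + 1, birth_year + 2)
  list(window = window, midpoint = mean(window), qc_flag = flag)
}

#' Build per-seal records from a raw measurement table
#'
#' Applies the nearest-standard correction to every replicate, the replicate
#' QC rule, and the GLG chronology, producing one row per seal ready for
#' trend fitting.
#'
#' @param measurements data frame with columns `seal_id`, `amino_acid`,
#'   `replicate_index`, `d15n_measured`, `standard_measured`,
#'   `standard_known`, `catch_year`, `age_years` (the measurement CSV schema).
#' @param amino_acid which amino acid to extract (default `"phenylalanine"`).
#' @param qc_tolerance replicate-range tolerance passed to [qc_replicates()].
#' @param min_age minimum age at catch (default 5).
#' @param abscissa year assigned to each record for regression: GLG-window
#'   `"midpoint"` (default), `"start"`, or `"catch"` year.
#' @return data frame with one row per seal: `seal_id`, `catch_year`,
#'   `age_years`, `glg_start`, `glg_end`, `year` (regression abscissa),
#'   `d15n_phe`, `qc_flag`.
#' @export
build_seal_records <- function(measurements, amino_acid = "phenylalanine",
                               qc_tolerance = 1.0, min_age = 5,
                               abscissa = c("midpoint", "start", "catch")) {
  abscissa <- match.arg(abscissa)
  required <- c("seal_id", "amino_acid", "replicate_index", "d15n_measured",
                "standard_measured", "standard_known", "catch_year", "age_years")
  missing_cols <- setdiff(required, names(measurements))
  .assert(length(missing_cols) == 0L,
          paste("measurement table missing columns:",
                paste(missing_cols, collapse = ", ")), "schema_error")
  m <- measurements[measurements$amino_acid == amino_acid, , drop = FALSE]
  .assert(nrow(m) > 0L, paste("no rows for amino acid", amino_acid),
          "invalid_input")
  out <- lapply(split(m, m$seal_id), function(rows) {
    # correct each replicate by its own nearest-standard offset, then QC
    corrected <- rows$d15n_measured - (rows$standard_measured - rows$standard_known)
    qc <- qc_replicates(corrected, tolerance = qc_tolerance)
    glg <- assign_glg_years(rows$catch_year[1], rows$age_years[1],
                            min_age = min_age, on_young = "flag")
    flag <- if (glg$qc_flag == "fail") "fail" else qc$qc_flag
    yr <- switch(abscissa,
                 midpoint = glg$midpoint,
                 start = glg$window[1],
                 catch = rows$catch_year[1])
    data.frame(seal_id = rows$seal_id[1],
               catch_year = rows$catch_year[1],
               age_years = rows$age_years[1],
               glg_start = glg$window[1],
               glg_end = glg$window[2],
               year = yr,
               d15n_phe = qc$final_value,
               qc_flag = flag,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records
}

#' Fit the multi-decadal linear trend of a seal record
#'
#' Ordinary least squares of reported d15N_Phe on the record's year axis
#' (Gaussian errors, no transformation). Records flagged `"fail"` are excluded
#' unless `exclude_failed = FALSE`.
#'
#' @param records data frame from [build_seal_records()] (needs columns
#'   `year`, `d15n_phe` and optionally `qc_flag`).
#' @param exclude_failed drop records with `qc_flag == "fail"` (default TRUE).
#' @return object of class `trend_fit`: slope per year and per decade with
#'   standard errors, intercept, R-squared (fraction and percent),
#'   F-statistic, residual degrees of freedom, n, p-value, residuals, fitted
#'   values, and the underlying `lm` fit.
#' @export
fit_trend <- function(records, exclude_failed = TRUE) {
  .assert(all(c("year", "d15n_phe") %in% names(records)),
          "records need columns year and d15n_phe", "schema_error")
  r <- records
  if (exclude_failed && "qc_flag" %in% names(r)) {
    r <- r[r$qc_flag != "fail", , drop = FALSE]
  }
  .assert(nrow(r) >= 3L, "need at least 3 records passing QC", "invalid_input")
  .assert(length(unique(r$year)) >= 2L, "all records share one year",
          "singular_design")
  fit <- lm(d15n_phe ~ year, data = r)
  s <- suppressWarnings(summary(fit))
  # a constant response has zero total variance: report slope 0, R2 0, F 0
  if (var(r$d15n_phe) == 0 || is.nan(s$r.squared)) {
    s$r.squared <- 0
    s$fstatistic[1] <- 0
    s$coefficients[2, ] <- c(0, 0, 0, 1)
    fit$coefficients[] <- c(mean(r$d15n_phe), 0)
    fit$residuals[] <- 0
    fit$fitted.values[] <- mean(r$d15n_phe)
  }
  structure(list(
    slope_per_year = unname(coef(fit)[2]),
    slope_per_decade = 10 * unname(coef(fit)[2]),
    slope_se = unname(s$coefficients[2, 2]),
    slope_se_per_decade = 10 * unname(s$coefficients[2, 2]),
    intercept = unname(coef(fit)[1]),
    r_squared = unname(s$r.squared),
    r_squared_pct = 100 * unname(s$r.squared),
    f_statistic = unname(s$fstatistic[1]),
    df_resid = unname(s$fstatistic[3]),
    n = nrow(r),
    p_value = unname(s$coefficients[2, 4]),
    residuals = unname(residuals(fit)),
    fitted = unname(fitted(fit)),
    data = r,
    lm = fit
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Linear trend of d15N_Phe on year\n")
  cat(sprintf("  slope: %.3f permil/decade (se %.3f), intercept %.2f\n",
              x$slope_per_decade, x$slope_se_per_decade, x$intercept))
  cat(sprintf("  R2 = %.1f%%, F = %.1f on 1 and %d df, p = %.3g, n = %d\n",
              x$r_squared_pct, x$f_statistic, as.integer(x$df_resid),
              x$p_value, x$n))
  invisible(x)
}

#' Residual diagnostics for a fitted trend
#'
#' Numeric counterparts of the usual visual checks: residual-versus-fitted and
#' residual-versus-year series (homogeneity and independence), normal
#' quantile-quantile data, a Shapiro-Wilk normality statistic and a
#' Breusch-Pagan heteroscedasticity statistic, each with a pass/warn flag.
#'
#' @param fit a `trend_fit` from [fit_trend()].
#' @param alpha significance level for the flags (default 0.01).
#' @return list of data series and numeric summaries with `normality_flag`
#'   and `heteroscedasticity_flag` (`"pass"`/`"warn"`), plus `reliable`
#'   (FALSE with a warning when n < 8).
#' @export
residual_diagnostics <- function(fit, alpha = 0.01) {
  .assert(inherits(fit, "trend_fit"), "fit must be a trend_fit", "invalid_input")
  res <- fit$residuals
  n <- length(res)
  reliable <- n >= 8L
  if (!reliable) warning("fewer than 8 residuals; diagnostics unreliable")
  # residuals at floating-point noise level count as an exact fit
  if (sd(res) <= 1e-10 * max(1, sd(fit$fitted))) {
    # exact fit: nothing to test
    sw <- list(statistic = c(W = 1), p.value = 1)
    bp <- list(statistic = c(BP = 0), p.value = 1)
  } else {
    sw <- shapiro.test(res)
    bp <- lmtest::bptest(fit$lm)
  }
  qq <- qnorm(ppoints(n))
  list(
    residual_vs_fitted = data.frame(fitted = fit$fitted, residual = res),
    residual_vs_year = data.frame(year = fit$data$year, residual = res),
    qq = data.frame(theoretical = qq, sample = sort(res)),
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    breusch_pagan = unname(bp$statistic),
    breusch_pagan_p = bp$p.value,
    normality_flag = if (sw$p.value >= alpha) "pass" else "warn",
    heteroscedasticity_flag = if (bp$p.value >= alpha) "pass" else "warn",
    alpha = alpha,
    reliable = reliable
  )
}
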