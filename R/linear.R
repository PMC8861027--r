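# Standardized multiple regression of daily GPP anomalies on SWC, VPD,
# their interaction, temperature and radiation, with cross-site slope
# summaries and the with/without-extreme-year contrast.

#' Standardized multiple regression of GPP anomalies
#'
#' Ordinary least squares of standardized GPP on standardized SWC, VPD,
#' their product (formed after standardization, not re-standardized), Ta
#' and Rg. Raw coefficients are stored unmodified; the reported slopes
#' apply the field's sign conventions: the SWC slope is flipped to the
#' drying orientation (negative = GPP reduced when soil dries) while the
#' VPD slope keeps the increasing orientation (negative = GPP reduced when
#' VPD rises).
#'
#' @param days Daily table with standardized columns `gpp`, `swc`, `vpd`,
#'   `ta`, `rg` (use [zscore()] first).
#' @param response Response column (default "gpp_nt").
#' @return List of class `linfit`: `coef` (raw OLS), `reported`
#'   (drying/increase-oriented swc and vpd slopes), `se`, `sigma`, `n`,
#'   `model` (the `lm` fit).
#' @export
fit_standardized_regression <- function(days, response = "gpp_nt") {
  d <- days[stats::complete.cases(days[, c(response, "swc", "vpd", "ta",
                                           "rg")]), ]
  n <- nrow(d)
  if (n <= 7) stop("too few days for regression (n = ", n, ")")
  d$swc_x_vpd <- d$swc * d$vpd
  f <- stats::as.formula(paste(response, "~ swc + vpd + swc_x_vpd + ta + rg"))
  fit <- stats::lm(f, data = d)
  qrr <- fit$qr$rank
  if (qrr < 6) stop("collinearity error: design matrix is rank-deficient")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(
    coef = cf, se = se,
    reported = c(swc = -unname(cf["swc"]), vpd = unname(cf["vpd"])),
    sigma = stats::sigma(fit), n = n, model = fit
  ), class = "linfit")
}

#' @export
print.linfit <- function(x, ...) {
  cat("Standardized GPP regression (n =", x$n, ")\n")
  cat(sprintf("  reported slopes: SWC (drying) %.3f, VPD %.3f\n",
              x$reported["swc"], x$reported["vpd"]))
  cat(sprintf("  interaction %.3f, Ta %.3f, Rg %.3f, residual sd %.3f\n",
              x$coef["swc_x_vpd"], x$coef["ta"], x$coef["rg"], x$sigma))
  invisible(x)
}

#' Cross-site distribution of regression slopes
#'
#' Mean of per-site reported slopes with a normal 95% confidence interval
#' (mean +/- 1.96 SE across sites), per variable.
#'
#' @param fits List of `linfit` objects (>= 3 sites).
#' @return data.frame with one row per variable (`swc`, `vpd`): mean,
#'   ci_lo, ci_hi, se, n_sites, plus the raw slopes as an attribute.
#' @export
slope_distribution <- function(fits) {
  if (length(fits) < 3)
    stop("insufficient replication: need >= 3 sites, got ", length(fits))
  sl <- t(vapply(fits, function(f) f$reported, numeric(2)))
  out <- do.call(rbind, lapply(c("swc", "vpd"), function(v) {
    x <- sl[, v]
    se <- stats::sd(x) / sqrt(length(x))
    data.frame(variable = v, mean = mean(x),
               ci_lo = mean(x) - 1.96 * se, ci_hi = mean(x) + 1.96 * se,
               se = se, n_sites = length(x))
  }))
  attr(out, "slopes") <- sl
  out
}

#' Regression with and without one calendar year
#'
#' Refits the standardized regression on all years and on all-but-`year`,
#' re-standardizing within each subset so each fit's anomalies are defined
#' over its own analysis period.
#'
#' @param days Daily (unstandardized) table with a `year` column.
#' @param year Calendar year to exclude in the second fit.
#' @param response Response column.
#' @return List with elements `all` and `without` (both `linfit`).
#' @export
with_without_year <- function(days, year, response = "gpp_nt") {
  vars <- c(response, "swc", "vpd", "ta", "rg")
  fit_on <- function(d) {
    if (nrow(d) <= 7) stop("subset too small for regression")
    z <- zscore(d, vars)
    fit_standardized_regression(z$days, response)
  }
  list(all = fit_on(days),
       without = fit_on(days[days$year != year, , drop = FALSE]))
}
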