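# Windowed light-response-curve fits of the canopy CO2 flux, giving the
# maximum assimilation rate Amax per 2-14 day window.

#' Rectangular-hyperbola light response with a VPD-limited plateau
#'
#' Predicts the CO2 flux Fc (NEE sign convention: photosynthetic uptake
#' negative) as Fc = -alpha beta Rg / (alpha Rg + beta) + gamma_resp, where
#' the plateau beta decays exponentially above a VPD threshold:
#' beta = beta0 exp(-k (VPD - vpd0)) for VPD > vpd0, else beta0.
#'
#' @param rg Incoming shortwave radiation (W m-2).
#' @param vpd Vapor pressure deficit (kPa).
#' @param alpha Canopy quantum yield (umol CO2 per W).
#' @param beta0 Saturating uptake capacity at low VPD (umol m-2 s-1).
#' @param k_vpd Exponential VPD decay rate (kPa-1).
#' @param gamma_resp Ecosystem respiration offset (umol m-2 s-1).
#' @param vpd0 Decay onset (kPa), default 1.
#' @return Predicted Fc (umol m-2 s-1).
#' @export
lrc_predict <- function(rg, vpd, alpha, beta0, k_vpd, gamma_resp, vpd0 = 1) {
  beta <- beta0 * exp(-k_vpd * pmax(0, vpd - vpd0))
  -alpha * beta * rg / (alpha * rg + beta) + gamma_resp
}

#' Fit a light-response curve to one window of half-hourly CO2 flux
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the rectangular
#' hyperbola with VPD-limited plateau. When every VPD in the window is at
#' or below `vpd0` the decay rate is unidentifiable; it is fixed at 0 and
#' flagged.
#'
#' @param fc Half-hourly CO2 flux (umol m-2 s-1, uptake negative).
#' @param rg Incoming shortwave radiation (W m-2).
#' @param vpd Vapor pressure deficit (kPa).
#' @param vpd0 Plateau-decay onset (kPa).
#' @return List of class `lrc_fit`: `alpha`, `beta0`, `k_vpd`,
#'   `gamma_resp`, `rmse`, `n`, `converged`, `k_identifiable`,
#'   `at_bound`.
#' @export
fit_lrc_window <- function(fc, rg, vpd, vpd0 = 1) {
  ok <- !is.na(fc) & !is.na(rg) & !is.na(vpd)
  fc <- fc[ok]; rg <- rg[ok]; vpd <- vpd[ok]
  n <- length(fc)
  if (n < 10) stop("too few flux records in window (", n, ")")
  k_ident <- any(vpd > vpd0)
  # starting values from crude geometry of the cloud
  g0 <- stats::quantile(fc, 0.9, names = FALSE)
  b0 <- max(1, g0 - stats::quantile(fc, 0.05, names = FALSE))
  a0 <- max(0.005, b0 / max(rg))
  fit <- NULL
  if (k_ident) {
    fit <- tryCatch(minpack.lm::nlsLM(
      fc ~ lrc_predict(rg, vpd, alpha, beta0, k_vpd, gamma_resp, vpd0),
      start = list(alpha = a0, beta0 = b0, k_vpd = 0.2, gamma_resp = g0),
      lower = c(1e-4, 1e-3, 0, -50), upper = c(1, 200, 5, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      fc ~ lrc_predict(rg, vpd, alpha, beta0, 0, gamma_resp, vpd0),
      start = list(alpha = a0, beta0 = b0, gamma_resp = g0),
      lower = c(1e-4, 1e-3, -50), upper = c(1, 200, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    k_ident <- FALSE
  }
  if (is.null(fit)) {
    return(structure(list(alpha = NA_real_, beta0 = NA_real_,
                          k_vpd = NA_real_, gamma_resp = NA_real_,
                          rmse = NA_real_, n = n, converged = FALSE,
                          k_identifiable = k_ident, at_bound = FALSE),
                     class = "lrc_fit"))
  }
  cf <- stats::coef(fit)
  k_vpd <- if (k_ident) unname(cf["k_vpd"]) else 0
  at_bound <- unname(cf["beta0"]) >= 200 - 1e-6 || unname(cf["alpha"]) >= 1 - 1e-9
  structure(list(alpha = unname(cf["alpha"]), beta0 = unname(cf["beta0"]),
                 k_vpd = k_vpd, gamma_resp = unname(cf["gamma_resp"]),
                 rmse = sqrt(mean(stats::resid(fit)^2)), n = n,
                 converged = TRUE, k_identifiable = k_ident,
                 at_bound = at_bound),
            class = "lrc_fit")
}

#' @export
print.lrc_fit <- function(x, ...) {
  cat("Light-response fit (n =", x$n, ")\n")
  cat(sprintf("  alpha = %.4f, beta0 = %.2f, k_vpd = %.3f, gamma = %.2f, RMSE = %.3f\n",
              x$alpha, x$beta0, x$k_vpd, x$gamma_resp, x$rmse))
  if (!x$converged) cat("  ** did not converge **\n")
  invisible(x)
}

#' Daily Amax from moving-window light-response fits
#'
#' Splits a half-hourly record into consecutive windows of 2-14 days
#' (greedily extended from 2 days until at least `min_n` measured flux
#' half-hours with a usable radiation range are available), fits the
#' light-response curve per window, and assigns each day in the window the
#' same Amax = beta0, the VPD-uncorrected saturating capacity.
#'
#' @param dates Date vector, one per half-hour.
#' @param fc Half-hourly CO2 flux (umol m-2 s-1, uptake negative); pass
#'   only measured (non-gap-filled) values, NA elsewhere.
#' @param rg,vpd Drivers per half-hour.
#' @param min_n Minimum usable half-hours per window (default 30).
#' @param min_rg_ratio Required max/min daylight radiation ratio (default 5).
#' @param vpd0 Plateau-decay onset (kPa).
#' @return data.frame with one row per day: `date`, `amax`, `alpha`,
#'   `k_vpd`, `window_id`, `window_days`, `flagged`.
#' @export
fit_light_response <- function(dates, fc, rg, vpd, min_n = 30,
                               min_rg_ratio = 5, vpd0 = 1) {
  stopifnot(length(dates) == length(fc), length(fc) == length(rg),
            length(rg) == length(vpd))
  udays <- sort(unique(dates))
  out <- list()
  i <- 1L
  win_id <- 0L
  while (i <= length(udays)) {
    len <- 2L
    repeat {
      span <- udays[seq(i, min(i + len - 1L, length(udays)))]
      sel <- dates %in% span & !is.na(fc) & !is.na(rg) & !is.na(vpd) & rg > 0
      rgsel <- rg[sel]
      enough <- sum(sel) >= min_n && length(rgsel) > 0 &&
        max(rgsel) / max(min(rgsel), 1e-6) >= min_rg_ratio
      if (enough || len >= 14L || i + len - 1L >= length(udays)) break
      len <- len + 1L
    }
    win_id <- win_id + 1L
    span <- udays[seq(i, min(i + len - 1L, length(udays)))]
    sel <- dates %in% span & !is.na(fc) & !is.na(rg) & !is.na(vpd) & rg > 0
    if (sum(sel) >= min_n) {
      f <- fit_lrc_window(fc[sel], rg[sel], vpd[sel], vpd0 = vpd0)
      flagged <- !f$converged || f$at_bound
      amax <- if (f$converged && !f$at_bound) f$beta0 else NA_real_
      out[[win_id]] <- data.frame(date = span, amax = amax,
                                  alpha = f$alpha, k_vpd = f$k_vpd,
                                  window_id = win_id,
                                  window_days = length(span),
                                  flagged = flagged)
    } else {
      out[[win_id]] <- data.frame(date = span, amax = NA_real_,
                                  alpha = NA_real_, k_vpd = NA_real_,
                                  window_id = win_id,
                                  window_days = length(span),
                                  flagged = TRUE)
    }
    i <- i + length(span)
  }
  do.call(rbind, out)
}
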