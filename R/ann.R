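# Feed-forward neural-network sensitivity analysis: one-hidden-layer
# networks trained per site and response, one-standard-deviation
# perturbation sensitivities per day, medians on the 10 x 10 SWC/VPD
# percentile grid, repeat and cross-site aggregation with t-tests.

#' Training specification for the sensitivity networks
#'
#' @param hidden_nodes Hidden-layer size. The default (12) was chosen by
#'   sampling the 4-20 node grid and comparing held-out error and
#'   ground-truth recovery on synthetic networks.
#' @param repeats Number of independent train/perturb repeats whose cell
#'   medians are combined (default 5).
#' @param max_epochs Optimizer iteration cap (default 1000).
#' @param split Train/validation/test fractions (must sum to 1).
#' @param perf_threshold Minimum held-out correlation r between predicted
#'   and observed response; sites below it are excluded.
#' @param restarts Random restarts per repeat; the restart with the lowest
#'   validation MSE is kept (validation-based model selection).
#' @param max_fail Early-stopping patience: training stops when the
#'   validation error has not improved for this many iterations.
#' @return List of class `ann_spec`.
#' @export
ann_spec <- function(hidden_nodes = 12, repeats = 5, max_epochs = 1000,
                     split = c(0.6, 0.2, 0.2), perf_threshold = 0.5,
                     restarts = 6, max_fail = 6) {
  stopifnot(abs(sum(split) - 1) < 1e-9, repeats >= 1)
  structure(list(hidden_nodes = hidden_nodes, repeats = repeats,
                 max_epochs = max_epochs, split = split,
                 perf_threshold = perf_threshold, restarts = restarts,
                 max_fail = max_fail),
            class = "ann_spec")
}

#' Train one feed-forward network on standardized daily predictors
#'
#' Single hidden layer with sigmoidal activation and linear output,
#' trained by Levenberg-Marquardt least squares (see [mlp_train()]) with
#' early stopping on validation error. The data are split 60/20/20 into
#' training, validation and test portions from `seed`; `restarts`
#' networks are fitted from independent random initial weights and the one
#' with the lowest validation MSE is retained. Performance is reported as
#' correlation and RMSE on the untouched test portion.
#'
#' @param x Matrix or data.frame of standardized predictors (columns
#'   `ta`, `vpd`, `swc`, `rg`).
#' @param y Standardized response vector.
#' @param spec An [ann_spec()].
#' @param seed Integer seed controlling the split and initial weights;
#'   identical seeds give identical fits.
#' @return List of class `ann_fit`: `net` (the fitted `nnet`), `r_test`,
#'   `rmse_test`, `excluded`, `idx` (split membership), `converged`.
#' @export
train_ann <- function(x, y, spec = ann_spec(), seed = 1) {
  x <- as.matrix(x)
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(x)
  if (n < 100) stop("too few days to train (n = ", n, ", need >= 100)")
  set.seed(as.integer(seed %% .Machine$integer.max))
  perm <- sample.int(n)
  n_tr <- floor(spec$split[1] * n)
  n_va <- floor(spec$split[2] * n)
  i_tr <- perm[seq_len(n_tr)]
  i_va <- perm[n_tr + seq_len(n_va)]
  i_te <- perm[(n_tr + n_va + 1):n]

  best <- NULL
  for (r in seq_len(spec$restarts)) {
    net <- mlp_train(x, y, i_tr, i_va, hidden = spec$hidden_nodes,
                     max_epochs = spec$max_epochs,
                     max_fail = spec$max_fail)
    if (is.null(best) || net$val_mse < best$val_mse) best <- net
  }
  pred_te <- as.numeric(stats::predict(best, x[i_te, , drop = FALSE]))
  r_test <- suppressWarnings(stats::cor(pred_te, y[i_te]))
  if (is.na(r_test)) r_test <- 0
  structure(list(net = best, r_test = r_test,
                 rmse_test = sqrt(mean((pred_te - y[i_te])^2)),
                 excluded = r_test < spec$perf_threshold,
                 idx = list(train = i_tr, val = i_va, test = i_te),
                 converged = best$converged),
            class = "ann_fit")
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf("ANN fit: test r = %.3f, test RMSE = %.3f%s\n", x$r_test,
              x$rmse_test, if (x$excluded) " [excluded: r < threshold]" else ""))
  invisible(x)
}

#' Per-day perturbation sensitivity of a fitted network
#'
#' Perturbs one standardized predictor by `delta` standard deviations at
#' every day's observed covariate vector (other predictors held at their
#' observed values) and returns the prediction differences. With
#' standardized inputs the division by the predictor's SD is a division by
#' one. The conventional orientations are `delta = -1` for SWC (drying:
#' negative values mean the response falls as soil dries) and `delta = +1`
#' for VPD (increase).
#'
#' @param fit An `ann_fit` (or any object with a `predict` method over the
#'   same columns).
#' @param x Standardized predictor matrix/data.frame for the evaluation
#'   days.
#' @param variable Column name to perturb.
#' @param delta Perturbation in SD units (default +1).
#' @return Numeric vector of per-day sensitivities.
#' @export
perturbation_sensitivity <- function(fit, x, variable, delta = 1) {
  x <- as.matrix(x)
  if (!variable %in% colnames(x))
    stop("unknown predictor variable: ", variable)
  net <- if (inherits(fit, "ann_fit")) fit$net else fit
  xp <- x
  xp[, variable] <- xp[, variable] + delta
  (as.numeric(stats::predict(net, xp)) - as.numeric(stats::predict(net, x))) /
    abs(delta)
}

#' Median of per-day values within each percentile bin
#'
#' @param values Per-day numeric vector.
#' @param bins A `bin_grid` from [assign_bins()] (or integer vectors `i`,
#'   `j`).
#' @return 10 x 10 matrix of cell medians (rows: SWC decile, columns: VPD
#'   decile); empty cells are NA.
#' @export
cell_median <- function(values, bins) {
  i <- bins$i; j <- bins$j
  m <- matrix(NA_real_, 10, 10)
  ok <- !is.na(values) & !is.na(i) & !is.na(j)
  if (any(ok)) {
    agg <- tapply(values[ok], list(factor(i[ok], 1:10),
                                   factor(j[ok], 1:10)),
                  stats::median)
    m[] <- agg
  }
  m
}

#' Per-cell day counts on the 10 x 10 grid
#' @inheritParams cell_median
#' @export
cell_count <- function(bins) {
  tb <- table(factor(bins$i, 1:10), factor(bins$j, 1:10))
  matrix(as.integer(tb), 10, 10)
}

#' Aggregate repeat-level cell medians into a per-site grid
#'
#' Each repeat contributes a 10 x 10 matrix of cell medians; the site grid
#' is the cellwise median across repeats (median of medians).
#'
#' @param repeat_grids List of 10 x 10 matrices, one per repeat.
#' @return 10 x 10 matrix.
#' @export
bin_aggregate <- function(repeat_grids) {
  stopifnot(length(repeat_grids) >= 1)
  arr <- simplify2array(repeat_grids)
  apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
}

#' Sensitivity grids for one site and response
#'
#' Trains `spec$repeats` networks (repeat j of site s uses seed
#' `base_seed + 1000 s + j`), computes per-day drying-oriented SWC and
#' increasing-oriented VPD perturbation sensitivities, takes cell medians
#' per repeat, and combines repeats by the cellwise median.
#'
#' @param days Standardized daily table with columns `ta`, `vpd`, `swc`,
#'   `rg` and the response.
#' @param bins `bin_grid` of the same days.
#' @param response Response column name.
#' @param spec An [ann_spec()].
#' @param base_seed Base seed of the run.
#' @param site_index Site number entering the seed policy.
#' @param swc_delta Perturbation applied to SWC (default -1 SD, the drying
#'   orientation; set +1 for the literal printed direction).
#' @return List of class `site_grid`: `swc`, `vpd` (10 x 10 medians),
#'   `n_days` (cell counts), `r_test` (per repeat), `excluded`.
#' @export
site_sensitivities <- function(days, bins, response = "gpp_nt",
                               spec = ann_spec(), base_seed = 42,
                               site_index = 1, swc_delta = -1) {
  x <- as.matrix(days[, c("ta", "vpd", "swc", "rg")])
  y <- days[[response]]
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  bins <- list(i = bins$i[keep], j = bins$j[keep])
  g_swc <- vector("list", spec$repeats)
  g_vpd <- vector("list", spec$repeats)
  r_test <- numeric(spec$repeats)
  for (j in seq_len(spec$repeats)) {
    fit <- train_ann(x, y, spec, seed = base_seed + 1000 * site_index + j)
    r_test[j] <- fit$r_test
    s_swc <- perturbation_sensitivity(fit, x, "swc", delta = swc_delta)
    s_vpd <- perturbation_sensitivity(fit, x, "vpd", delta = 1)
    g_swc[[j]] <- cell_median(s_swc, bins)
    g_vpd[[j]] <- cell_median(s_vpd, bins)
  }
  structure(list(swc = bin_aggregate(g_swc), vpd = bin_aggregate(g_vpd),
                 n_days = cell_count(bins), r_test = r_test,
                 excluded = stats::median(r_test) < spec$perf_threshold,
                 response = response),
            class = "site_grid")
}

#' Combine per-site grids across sites
#'
#' Cellwise median across contributing sites, with standard errors
#' (sd / sqrt(n_sites), >= 2 sites) and two-sided one-sample t-tests of
#' mean sensitivity != 0 (>= 3 sites; degenerate all-equal nonzero cells
#' are reported as p = 0). Excluded sites (held-out r below threshold) are
#' dropped first.
#'
#' @param site_grids List of `site_grid` objects.
#' @param drop_excluded Drop sites flagged `excluded` (default TRUE).
#' @return List of class `sens_grid` with, per driver (`swc`, `vpd`):
#'   `median`, `mean`, `se`, `p`, plus `n_sites`, `n_days`, `response`.
#' @export
cross_site_grid <- function(site_grids, drop_excluded = TRUE) {
  if (drop_excluded)
    site_grids <- Filter(function(g) !isTRUE(g$excluded), site_grids)
  if (!length(site_grids)) stop("no non-excluded sites to aggregate")
  n_days <- Reduce(`+`, lapply(site_grids, `[[`, "n_days"))
  summarize <- function(which) {
    arr <- simplify2array(lapply(site_grids, `[[`, which))
    if (length(dim(arr)) == 2) arr <- array(arr, c(10, 10, 1))
    med <- apply(arr, c(1, 2), stats::median, na.rm = TRUE)
    mn <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    ns <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
    se <- apply(arr, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      n1 <- length(v)
      if (n1 < 2) return(NA_real_)
      sqrt(sum((v - mean(v))^2) / n1) / sqrt(n1)  # population-sd convention
    })
    p <- apply(arr, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 3) return(NA_real_)
      if (stats::sd(v) == 0) return(if (v[1] == 0) 1 else 0)
      stats::t.test(v)$p.value
    })
    med[ns == 0] <- NA_real_
    list(median = med, mean = mn, se = se, p = p, n_sites = ns)
  }
  structure(list(swc = summarize("swc"), vpd = summarize("vpd"),
                 n_days = n_days, n_sites = length(site_grids),
                 response = site_grids[[1]]$response),
            class = "sens_grid")
}

#' @export
print.sens_grid <- function(x, ...) {
  cat(sprintf("Cross-site sensitivity grid for %s (%d sites, %d days)\n",
              x$response, x$n_sites, sum(x$n_days)))
  cat(sprintf("  SWC sensitivity median over cells: %.3f (range %.3f to %.3f)\n",
              stats::median(x$swc$median, na.rm = TRUE),
              min(x$swc$median, na.rm = TRUE),
              max(x$swc$median, na.rm = TRUE)))
  cat(sprintf("  VPD sensitivity median over cells: %.3f (range %.3f to %.3f)\n",
              stats::median(x$vpd$median, na.rm = TRUE),
              min(x$vpd$median, na.rm = TRUE),
              max(x$vpd$median, na.rm = TRUE)))
  invisible(x)
}

#' Long-format table of a cross-site grid (for CSV output)
#' @param x A `sens_grid`.
#' @param ... Unused.
#' @export
as.data.frame.sens_grid <- function(x, ...) {
  ij <- expand.grid(i = 1:10, j = 1:10)
  do.call(rbind, lapply(c("swc", "vpd"), function(v) {
    g <- x[[v]]
    data.frame(variable = v, i = ij$i, j = ij$j,
               median = g$median[cbind(ij$i, ij$j)],
               mean = g$mean[cbind(ij$i, ij$j)],
               se = g$se[cbind(ij$i, ij$j)],
               p = g$p[cbind(ij$i, ij$j)],
               n_sites = g$n_sites[cbind(ij$i, ij$j)],
               n_days = x$n_days[cbind(ij$i, ij$j)],
               response = x$response)
  }))
}

#' Compare an estimated grid with the synthetic ground truth
#'
#' Cellwise estimated-minus-true error and the mean absolute error over
#' cells with at least `min_days` days.
#'
#' @param est 10 x 10 matrix of estimated sensitivities.
#' @param truth 10 x 10 matrix of oracle sensitivities on the same bins.
#' @param n_days 10 x 10 matrix of cell day counts.
#' @param min_days Minimum occupancy for a cell to enter the MAE.
#' @return List: `error` (est - truth), `mae`, `n_cells`.
#' @export
sensitivity_vs_truth <- function(est, truth, n_days, min_days = 30) {
  if (is.null(truth)) stop("ground truth absent: cannot score the grid")
  stopifnot(all(dim(est) == c(10, 10)), all(dim(truth) == c(10, 10)))
  err <- est - truth
  use <- n_days >= min_days & !is.na(err)
  list(error = err, mae = mean(abs(err[use])), n_cells = sum(use))
}

#' Oracle sensitivity grid from the generator's truth
#'
#' Evaluates the analytic z-scored sensitivities at every selected day's
#' observed drivers and takes cell medians, mirroring exactly the
#' aggregation applied to the network estimates.
#'
#' @param days_raw Unstandardized daily table (columns `swc`, `vpd`, `rg`).
#' @param bins `bin_grid` for the same days.
#' @param params The generating [truth_params()].
#' @param sd_swc,sd_vpd,sd_gpp Standardization SDs of the analysis set.
#' @param rg_scale Factor converting the daily daytime-mean radiation to
#'   the instantaneous level at which the oracle is evaluated (default 1).
#' @return List: `swc`, `vpd` 10 x 10 oracle matrices.
#' @export
true_sensitivity_grid <- function(days_raw, bins, params, sd_swc, sd_vpd,
                                  sd_gpp, rg_scale = 1) {
  ts <- true_sensitivities(params, days_raw$swc, days_raw$vpd,
                           days_raw$rg * rg_scale,
                           sd_swc = sd_swc, sd_vpd = sd_vpd,
                           sd_gpp = sd_gpp)
  list(swc = cell_median(ts$s_swc, bins), vpd = cell_median(ts$s_vpd, bins))
}
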