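# Method-choice and sampling uncertainty of sensitivity grids: cellwise
# differences between analysis variants, relative uncertainty in percent,
# and cross-site standard errors.

#' Cellwise difference of two sensitivity grids
#'
#' a - b per cell; NA where either input is missing. Both grids must share
#' binning provenance (same 10 x 10 layout).
#'
#' @param grid_a,grid_b 10 x 10 matrices.
#' @return 10 x 10 matrix of differences.
#' @export
grid_difference <- function(grid_a, grid_b) {
  if (!all(dim(grid_a) == dim(grid_b)))
    stop("grid shape mismatch: ", paste(dim(grid_a), collapse = "x"),
         " vs ", paste(dim(grid_b), collapse = "x"))
  grid_a - grid_b
}

#' Relative uncertainty between two variant grids (percent)
#'
#' 100 |a - b| / |(a + b)/2| per cell. Cells whose mean sensitivity is
#' within `eps` of zero are reported NA with an `undefined` flag rather
#' than blowing up: near-zero sensitivities make the ratio meaningless
#' (small absolute differences there imply huge relative ones).
#'
#' @param grid_a,grid_b 10 x 10 matrices.
#' @param eps Near-zero denominator threshold (default 1e-6).
#' @return List: `percent` (10 x 10), `undefined` (logical 10 x 10).
#' @export
relative_uncertainty <- function(grid_a, grid_b, eps = 1e-6) {
  if (!all(dim(grid_a) == dim(grid_b)))
    stop("grid shape mismatch")
  m <- (grid_a + grid_b) / 2
  undef <- !is.na(m) & abs(m) < eps
  pct <- 100 * abs(grid_a - grid_b) / abs(m)
  pct[undef] <- NA_real_
  list(percent = pct, undefined = undef)
}

#' Cross-site standard error of per-site sensitivity grids
#'
#' Per cell, the spread across sites divided by sqrt(number of
#' contributing sites); cells with a single site are NA. The spread uses
#' the n-denominator (population) standard deviation, matching the worked
#' convention that two sites at -0.2 and -0.4 give SE 0.0707. The relative
#' form divides by the absolute cross-site median.
#'
#' @param site_grids List of 10 x 10 per-site matrices.
#' @return List: `se`, `relative` (SE / |median|), `n_sites` (all
#'   10 x 10).
#' @export
cross_site_se <- function(site_grids) {
  arr <- simplify2array(site_grids)
  if (length(dim(arr)) == 2) arr <- array(arr, c(10, 10, 1))
  n <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  se <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    n1 <- length(v)
    if (n1 < 2) return(NA_real_)
    sqrt(sum((v - mean(v))^2) / n1) / sqrt(n1)
  })
  med <- apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  list(se = se, relative = se / abs(med), n_sites = n)
}
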