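#' Exceedance proportion of a set of co-expression levels
#'
#' `exceedance(v, c)` is the fraction of values greater than or equal to
#' `c`, i.e. the empirical survival function `Prob(X >= c)` of the
#' co-expression levels.  The strong/weak split at the disease-specific
#' cutoff point compares exactly these exceedance distributions between
#' the two groups.
#'
#' @param values Non-empty numeric vector of co-expression levels.
#' @param c Threshold(s) in \[0, 1\]; vectorized.
#' @return Proportion(s) in \[0, 1\].
#' @export
exceedance <- function(values, c) {
  if (!length(values)) stop("empty set of co-expression levels")
  if (anyNA(values) || anyNA(c)) stop("missing values are not allowed")
  if (any(c < 0 | c > 1)) stop("threshold must lie in [0, 1]")
  sv <- sort(values)
  # count of elements >= c, via the number of strictly smaller elements
  (length(sv) - findInterval(c, sv, left.open = TRUE)) / length(sv)
}

#' Maximum deviation between the two exceedance distributions
#'
#' Scans candidate thresholds for the largest absolute difference
#' `D = max_C |F_d(C) - F_n(C)|` between the disease and normal exceedance
#' functions, and reports the disease-specific cutoff point `C` where it is
#' attained.  The candidate grid is the sorted union of all observed
#' co-expression values: both exceedance functions are step functions with
#' jumps only at observed values, so the supremum over \[0, 1\] is attained
#' on this grid and the search is exact, not a discretization.  When
#' several thresholds attain `D`, the smallest is returned (deterministic
#' tie-break).
#'
#' @param tab Co-expression table from [pairwise_coexpression()] (columns
#'   `c_normal`, `c_disease`), non-empty.
#' @return List with elements `D`, `C`, and `grid_size` (number of
#'   candidate thresholds examined).
#' @export
max_deviation <- function(tab) {
  cn <- tab$c_normal
  cd <- tab$c_disease
  if (!length(cn) || !length(cd)) stop("empty co-expression table")
  sn <- sort(cn)
  sd_ <- sort(cd)
  grid <- sort(unique(c(sn, sd_)))
  f_n <- (length(sn) - findInterval(grid, sn, left.open = TRUE)) / length(sn)
  f_d <- (length(sd_) - findInterval(grid, sd_, left.open = TRUE)) / length(sd_)
  dev <- abs(f_d - f_n)
  i <- which.max(dev)   # first index = smallest threshold attaining the max
  list(D = dev[i], C = grid[i], grid_size = length(grid))
}

# Smirnov coefficients c(alpha) for the asymptotic two-sample critical value
smirnov_coefficients <- c(
  "0.1"   = 1.22,
  "0.05"  = 1.36,
  "0.025" = 1.48,
  "0.01"  = 1.63,
  "0.005" = 1.73,
  "0.001" = 1.95)

#' Critical deviation for the two-sample Kolmogorov-Smirnov test
#'
#' Asymptotic critical value `c(alpha) * sqrt((n1 + n2) / (n1 * n2))` with
#' the standard Smirnov coefficient table (`c(0.05) = 1.36`).  A maximum
#' deviation exceeding this value indicates that the two co-expression
#' distributions differ significantly at level `alpha` -- under the usual
#' caveat, stated in the run report, that gene pairs sharing a gene are not
#' independent observations.
#'
#' @param n1,n2 Number of observations (gene pairs) in each group.
#' @param alpha Significance level; one of 0.10, 0.05, 0.025, 0.01, 0.005,
#'   0.001.
#' @return The critical deviation (positive scalar).
#' @export
critical_deviation <- function(n1, n2, alpha = 0.05) {
  if (n1 < 1L || n2 < 1L) stop("n1 and n2 must be at least 1")
  i <- which(abs(as.numeric(names(smirnov_coefficients)) - alpha) < 1e-9)
  if (!length(i))
    stop("unsupported alpha; supported levels: ",
         paste(names(smirnov_coefficients), collapse = ", "))
  unname(smirnov_coefficients[i]) * sqrt((n1 + n2) / (n1 * n2))
}

#' Significance decision for the maximum deviation
#'
#' @param D Observed maximum deviation.
#' @param D_critical Critical deviation from [critical_deviation()].
#' @return `TRUE` iff `D > D_critical` (strictly).
#' @export
ks_decision <- function(D, D_critical) {
  if (D < 0 || D_critical < 0) stop("deviations must be non-negative")
  D > D_critical
}

#' Detect the disease-specific cutoff point
#'
#' Convenience wrapper running [max_deviation()], [critical_deviation()]
#' and [ks_decision()] on a co-expression table.
#'
#' @param tab Co-expression table from [pairwise_coexpression()].
#' @param alpha Significance level for the critical deviation.
#' @return Object of class `cutoff_result`: list with `D`, `C`,
#'   `D_critical`, `alpha`, `n_normal_pairs`, `n_disease_pairs`,
#'   `significant`, `grid_size`.
#' @export
detect_cutoff <- function(tab, alpha = 0.05) {
  md <- max_deviation(tab)
  dc <- critical_deviation(length(tab$c_normal), length(tab$c_disease), alpha)
  structure(list(
    D = md$D, C = md$C, D_critical = dc, alpha = alpha,
    n_normal_pairs = length(tab$c_normal),
    n_disease_pairs = length(tab$c_disease),
    significant = ks_decision(md$D, dc),
    grid_size = md$grid_size), class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Disease-specific cutoff detection\n",
    "  maximum deviation D : %.4f\n",
    "  cutoff point C      : %.4f\n",
    "  critical D (alpha=%g): %.4f\n",
    "  pairs (normal/disease): %d / %d\n",
    "  distributions differ : %s\n"),
    x$D, x$C, x$alpha, x$D_critical,
    x$n_normal_pairs, x$n_disease_pairs,
    if (x$significant) "yes (D > D_critical)" else "no"))
  invisible(x)
}
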