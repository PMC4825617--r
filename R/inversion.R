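#' Invert the noncentrality parameter of the F law of the case statistic
#'
#' `L_alpha` is the value of the noncentrality (on the `n * lambda` scale)
#' for which the observed `F0` is the `alpha`-quantile of the noncentral
#' `F(nu1, nu2, L)` distribution. The noncentral-F CDF at fixed `F0` is
#' strictly decreasing in the noncentrality, so `L_alpha` is found by a
#' bracketing root search; the upper bracket is doubled from an initial
#' guess until it encloses the root. When `F0` is at or below the
#' `alpha`-quantile of the central F distribution no positive root exists
#' and the standard truncation `L_alpha = 0` is returned, flagged via the
#' `"truncated"` attribute.
#'
#' `L_alpha` is non-increasing in `alpha` and non-decreasing in `F0`.
#'
#' @param F0 nonnegative scalar, transformed case statistic.
#' @param alpha probability in (0, 1).
#' @param dims an [mi_dims()] object.
#' @return Scalar `L >= 0` with attribute `"truncated"` (logical).
#' @export
invert_noncentrality <- function(F0, alpha, dims) {
  dims <- as_mi_dims(dims)
  if (length(F0) != 1L || !is.finite(F0) || F0 < 0)
    stop("'F0' must be a single nonnegative number", call. = FALSE)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1)", call. = FALSE)
  nu1 <- dims$nu1; nu2 <- dims$nu2
  # truncate within the CDF tolerance so the boundary F0 = central quantile
  # is not missed through rounding of pf/qf
  if (stats::pf(F0, nu1, nu2) <= alpha + 1e-10)
    return(structure(0, truncated = TRUE))
  # initial guess n*(lambda0 + nu1), doubled until the CDF drops below alpha
  upper <- max(1, dims$n * (lambda0_from_F0(F0, dims) + nu1))
  for (k in 1:80) {
    if (stats::pf(F0, nu1, nu2, ncp = upper) < alpha) break
    upper <- 2 * upper
    if (k == 80)
      stop("noncentrality bracketing failed: CDF at F0 = ", F0,
           " still above alpha = ", alpha, " at L = ", upper, call. = FALSE)
  }
  root <- stats::uniroot(function(L) stats::pf(F0, nu1, nu2, ncp = L) - alpha,
                         lower = 0, upper = upper, tol = 1e-10)
  structure(max(root$root, 0), truncated = FALSE)
}

# bare numeric version used in hot loops
invL <- function(F0, alpha, nu1, nu2, n) {
  if (stats::pf(F0, nu1, nu2) <= alpha + 1e-10) return(0)
  upper <- max(1, n * ((n - 1) * nu1 * F0 / (n * nu2) + nu1))
  while (stats::pf(F0, nu1, nu2, ncp = upper) >= alpha) upper <- 2 * upper
  stats::uniroot(function(L) stats::pf(F0, nu1, nu2, ncp = L) - alpha,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Exact confidence interval for the abnormality P
#'
#' An equal-tailed `100 * level` percent confidence interval for
#' `P = Pr(chisq_nu1 > lambda)` obtained by inverting the noncentral-F law
#' of the case statistic: with `alpha = 1 - level`, the limits are
#' `1 - G(L_{alpha/2} / n)` and `1 - G(L_{1 - alpha/2} / n)`, where `G` is
#' the chi-square CDF on `nu1` degrees of freedom. Coverage is exact up to
#' the truncation of negative noncentralities at zero; in particular the
#' upper limit equals 1 whenever `F0` falls below the upper central-F
#' quantile.
#'
#' @param lambda0 nonnegative sample Mahalanobis index.
#' @param dims an [mi_dims()] object.
#' @param level confidence level in (0, 1); default 0.95.
#' @return Object of class `"mi_interval"`: list with `level`, `lower`,
#'   `upper` and logical flags `lower_truncated`, `upper_truncated`.
#' @examples
#' confidence_interval(0.4, mi_dims(4, 20), 0.95)
#' @export
confidence_interval <- function(lambda0, dims, level = 0.95) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must lie strictly inside (0, 1)", call. = FALSE)
  F0 <- compute_F0(lambda0, dims)
  alpha <- 1 - level
  L_lo <- invert_noncentrality(F0, alpha / 2, dims)      # large L -> lower limit
  L_hi <- invert_noncentrality(F0, 1 - alpha / 2, dims)  # small L -> upper limit
  out <- list(level = level,
              lower = 1 - stats::pchisq(as.numeric(L_lo) / dims$n, dims$nu1),
              upper = 1 - stats::pchisq(as.numeric(L_hi) / dims$n, dims$nu1),
              lower_truncated = attr(L_lo, "truncated"),
              upper_truncated = attr(L_hi, "truncated"))
  class(out) <- "mi_interval"
  out
}

#' @export
print.mi_interval <- function(x, ...) {
  cat(sprintf("%g%% confidence interval for P: [%.2f%%, %.2f%%]\n",
              100 * x$level, 100 * x$lower, 100 * x$upper))
  if (x$upper_truncated)
    cat("  (upper limit truncated: F0 below the central-F quantile)\n")
  invisible(x)
}
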