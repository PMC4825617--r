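#' Unbiased estimator of the population Mahalanobis index
#'
#' The uniformly minimum variance unbiased estimator of the noncentrality,
#' on the `lambda` scale: `lambda_bar = [nu1 * (nu2 - 2) * F0 / nu2 - nu1] / n`.
#' It can be negative (whenever `F0 < nu2 / (nu2 - 2)`), which is what the
#' truncated and Taylor-corrected estimators repair.
#'
#' @param F0 nonnegative transformed case statistic (vectorised).
#' @param dims an [mi_dims()] object with `nu2 > 2`.
#' @return Real estimate(s) of `lambda`, possibly negative.
#' @export
lambda_bar <- function(F0, dims) {
  dims <- as_mi_dims(dims)
  if (dims$nu2 <= 2)
    stop("lambda_bar requires nu2 > 2 (mean of F0 must exist)", call. = FALSE)
  if (any(F0 < 0)) stop("'F0' must be nonnegative", call. = FALSE)
  (dims$nu1 * (dims$nu2 - 2) * F0 / dims$nu2 - dims$nu1) / dims$n
}

# unbiased estimator of Var(lambda_bar): u0 + u1*lb + u2*lb^2
varhat_lambda_bar <- function(lb, dims) {
  nu1 <- dims$nu1; nu2 <- dims$nu2; n <- dims$n
  u0 <- 2 * nu1 * (nu1 + nu2 - 2) / (n^2 * (nu2 - 2))
  u1 <- 4 * (nu1 + nu2 - 2) / (n * (nu2 - 2))
  u2 <- 2 / (nu2 - 2)
  u0 + u1 * lb + u2 * lb^2
}

#' Moment-based and Taylor-corrected estimators of P
#'
#' Three estimators built from point estimates of the noncentrality
#' `lambda`, each mapped through the chi-square survival function
#' `1 - G` on `nu1` degrees of freedom:
#'
#' * `estimate_PM`: truncated unbiased estimator,
#'   `PM = 1 - G(max(lambda_bar, 0))` (requires `nu2 > 2`).
#' * `estimate_PR`: admissible estimator
#'   `PR = 1 - G(nu1 * (nu2 - 4) * F0 / (n * nu2))` (requires `nu2 > 4`).
#' * `estimate_PT`: second-order Taylor correction for the bias incurred by
#'   plugging `lambda_bar` into a nonlinear function,
#'   `lambda_star = lambda_bar - Varhat(lambda_bar)/2 * ((nu1/2 - 1)/lambda_bar - 1/2)`
#'   with the unbiased variance estimate
#'   `Varhat = u0 + u1*lambda_bar + u2*lambda_bar^2`,
#'   `u0 = 2*nu1*(nu1 + nu2 - 2)/(n^2*(nu2 - 2))`,
#'   `u1 = 4*(nu1 + nu2 - 2)/(n*(nu2 - 2))`, `u2 = 2/(nu2 - 2)`;
#'   `PT = 1 - G(max(lambda_star, 0))`. The correction divides by
#'   `lambda_bar`, so for `lambda_bar <= 1e-8` (including all negative
#'   values) the estimator falls back to the truncated form `PM`, which is
#'   continuous with it; requires `nu2 > 4` so the variance being estimated
#'   exists. For `nu1 = 2` the `1/lambda_bar` term has a zero coefficient
#'   and the correction reduces to `lambda_bar + Varhat/4`.
#'
#' All three equal 1 at `lambda0 = 0` and always lie inside \[0, 1\].
#'
#' @param lambda0 nonnegative sample Mahalanobis index.
#' @param dims an [mi_dims()] object.
#' @return An `mi_estimate`.
#' @examples
#' estimate_PM(1, mi_dims(2, 20))
#' estimate_PT(1, mi_dims(2, 20))
#' @export
estimate_PM <- function(lambda0, dims) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  mi_estimate("PM", pM_value(lambda0, dims))
}

#' @rdname estimate_PM
#' @export
estimate_PR <- function(lambda0, dims) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  if (dims$nu2 <= 4)
    stop("the admissible estimator requires nu2 > 4", call. = FALSE)
  mi_estimate("PR", pR_value(lambda0, dims))
}

#' @rdname estimate_PM
#' @export
estimate_PT <- function(lambda0, dims) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  if (dims$nu2 <= 4)
    stop("the Taylor-corrected estimator requires nu2 > 4", call. = FALSE)
  lb <- lambda_bar(compute_F0(lambda0, dims), dims)
  notes <- character()
  if (lb <= 1e-8) notes <- "lambda_bar near or below 0: truncated fallback"
  else {
    ls <- lb - varhat_lambda_bar(lb, dims) / 2 * ((dims$nu1 / 2 - 1) / lb - 0.5)
    if (ls < 0) notes <- "lambda_star clamped at 0"
  }
  mi_estimate("PT", pT_value(lambda0, dims), notes = notes)
}

# vectorised kernels
pM_value <- function(lambda0, dims) {
  lb <- lambda_bar(compute_F0(lambda0, dims), dims)
  1 - stats::pchisq(pmax(lb, 0), dims$nu1)
}

pR_value <- function(lambda0, dims) {
  F0 <- compute_F0(lambda0, dims)
  lt <- dims$nu1 * (dims$nu2 - 4) * F0 / (dims$n * dims$nu2)
  1 - stats::pchisq(lt, dims$nu1)
}

pT_value <- function(lambda0, dims) {
  lb <- lambda_bar(compute_F0(lambda0, dims), dims)
  ls <- ifelse(lb <= 1e-8,
               pmax(lb, 0),
               pmax(lb - varhat_lambda_bar(lb, dims) / 2 *
                      ((dims$nu1 / 2 - 1) / lb - 0.5), 0))
  1 - stats::pchisq(ls, dims$nu1)
}
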