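#' Plug-in maximum-likelihood estimators of P
#'
#' Two p-value style estimators obtained by substituting maximum-likelihood
#' estimates for the unknown population parameters.
#'
#' `estimate_PF` is the p-value of the one-sample Hotelling T-squared test
#' of the case belonging to the control population:
#' `PF = Pr(F_{nu1,nu2} > nu2 * T2 / ((n - 1) * nu1))` with
#' `T2 = n * lambda0 / (n + 1)` Hotelling's statistic. `estimate_Pchi2`
#' replaces only the case's index by its sample value inside the population
#' chi-square law: `Pchi2 = Pr(chisq_nu1 > n * lambda0 / (n - 1))`.
#'
#' Both map `lambda0 = 0` to 1, decrease strictly in `lambda0`, and always
#' lie inside \[0, 1\]. In simulations `PF` overestimates P while `Pchi2`
#' underestimates it, increasingly so at large P.
#'
#' @param lambda0 nonnegative sample Mahalanobis index.
#' @param dims an [mi_dims()] object.
#' @return An `mi_estimate` (list with `method`, `value`, `in_range`,
#'   `notes`); `estimate_PF` additionally carries the Hotelling statistic
#'   in its notes.
#' @examples
#' estimate_PF(1, mi_dims(2, 10))
#' estimate_Pchi2(1, mi_dims(2, 10))
#' @export
estimate_PF <- function(lambda0, dims) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  T2 <- dims$n * lambda0 / (dims$n + 1)
  mi_estimate("PF", pF_value(lambda0, dims),
              notes = sprintf("Hotelling T2 = %.6g", T2))
}

#' @rdname estimate_PF
#' @export
estimate_Pchi2 <- function(lambda0, dims) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  mi_estimate("Pchi2", pchi2_value(lambda0, dims))
}

# vectorised kernels (used by the simulation harness)
pF_value <- function(lambda0, dims) {
  # multiplier assembled in one expression: n*nu2/((n+1)(n-1)nu1)
  x <- dims$n * dims$nu2 * lambda0 / ((dims$n + 1) * (dims$n - 1) * dims$nu1)
  stats::pf(x, dims$nu1, dims$nu2, lower.tail = FALSE)
}

pchi2_value <- function(lambda0, dims) {
  stats::pchisq(dims$n * lambda0 / (dims$n - 1), dims$nu1, lower.tail = FALSE)
}
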