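#' Degrees of freedom of the case-versus-controls problem
#'
#' A case profile of `nu1` scores is compared with a control sample of
#' `n = nu1 + nu2` individuals. `nu1` and `nu2` are the numerator and
#' denominator degrees of freedom of the F law of the sample Mahalanobis
#' index (see [compute_F0()]).
#'
#' @param nu1 integer, number of scores per profile (>= 1).
#' @param nu2 integer, residual degrees of freedom `n - nu1` (>= 1).
#' @return An object of class `"mi_dims"`: a list with elements `nu1`,
#'   `nu2` and `n = nu1 + nu2`.
#' @examples
#' mi_dims(4, 20)
#' @export
mi_dims <- function(nu1, nu2) {
  if (length(nu1) != 1L || length(nu2) != 1L ||
      !is.finite(nu1) || !is.finite(nu2))
    stop("'nu1' and 'nu2' must be single finite numbers", call. = FALSE)
  if (nu1 != round(nu1) || nu2 != round(nu2))
    stop("'nu1' and 'nu2' must be integers", call. = FALSE)
  if (nu1 < 1 || nu2 < 1)
    stop("'nu1' and 'nu2' must both be >= 1", call. = FALSE)
  structure(list(nu1 = as.integer(nu1), nu2 = as.integer(nu2),
                 n = as.integer(nu1 + nu2)),
            class = "mi_dims")
}

#' @export
print.mi_dims <- function(x, ...) {
  cat(sprintf("Mahalanobis index dims: nu1 = %d, nu2 = %d (n = %d controls)\n",
              x$nu1, x$nu2, x$n))
  invisible(x)
}

as_mi_dims <- function(dims) {
  if (inherits(dims, "mi_dims")) return(dims)
  if (is.numeric(dims) && length(dims) == 2L) return(mi_dims(dims[1], dims[2]))
  stop("'dims' must be an mi_dims object or a (nu1, nu2) pair", call. = FALSE)
}

check_lambda0 <- function(lambda0) {
  if (!is.numeric(lambda0) || anyNA(lambda0) || any(lambda0 < 0))
    stop("'lambda0' must be nonnegative", call. = FALSE)
  lambda0
}

#' Transformed case statistic F0
#'
#' The sample Mahalanobis index `lambda0` of a fixed case profile against a
#' control sample has, after rescaling, an exact noncentral F sampling
#' distribution:
#' `F0 = n * nu2 * lambda0 / ((n - 1) * nu1) ~ F(nu1, nu2, ncp = n * lambda)`,
#' where `lambda` is the population Mahalanobis index of the case. All
#' interval and point estimators in this package work through `F0`.
#'
#' @param lambda0 nonnegative sample Mahalanobis index (vectorised).
#' @param dims an [mi_dims()] object (or a `c(nu1, nu2)` pair).
#' @return `F0`, same length as `lambda0`.
#' @examples
#' compute_F0(0.4, mi_dims(4, 20))  # 2.086957, printed as 2.09
#' @export
compute_F0 <- function(lambda0, dims) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  dims$n * dims$nu2 * lambda0 / ((dims$n - 1) * dims$nu1)
}

#' Inverse of [compute_F0()]
#'
#' @param F0 nonnegative transformed statistic (vectorised).
#' @param dims an [mi_dims()] object.
#' @return The sample index `lambda0 = (n - 1) * nu1 * F0 / (n * nu2)`.
#' @export
lambda0_from_F0 <- function(F0, dims) {
  dims <- as_mi_dims(dims)
  if (any(F0 < 0)) stop("'F0' must be nonnegative", call. = FALSE)
  (dims$n - 1) * dims$nu1 * F0 / (dims$n * dims$nu2)
}
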