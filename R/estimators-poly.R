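# Moment-matched polynomial estimators of P.
#
# P = Pr(chisq_nu1 > lambda) is approximated on a data-driven interval
# [a, b] by a polynomial sum(a_i * lambda^i) of degree r (Bernstein or
# quadrature construction). Since each raw moment E(F0^i) is itself a
# polynomial of degree i in lambda, coefficients b_i with
# sum(b_i * E(F0^i)) = sum(a_i * lambda^i) exist and are found by a
# triangular solve; the estimator sum(b_i * F0^i) is then (approximately)
# unbiased for P wherever the polynomial approximation is accurate. Its
# value may leave [0, 1] at extreme lambda0.

# product of two polynomials given as coefficient vectors (index 1 = x^0)
poly_mul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p))
    r[i:(i + length(q) - 1L)] <- r[i:(i + length(q) - 1L)] + p[i] * q
  r
}

# (c0 + c1*x)^k as a coefficient vector, exact binomial expansion
affine_pow <- function(c0, c1, k) {
  if (k == 0) return(1)
  choose(k, 0:k) * c0^(k:0) * c1^(0:k)
}

pad_to <- function(p, len) c(p, numeric(len - length(p)))

#' Raw moments of a noncentral chi-square as polynomials in the noncentrality
#'
#' Coefficients of `delta^0, ..., delta^i` in `E[(chisq_nu(delta))^i]`,
#' obtained from the cumulants `kappa_j = 2^(j-1) * (j-1)! * (nu + j*delta)`
#' via the standard recursive cumulant-to-moment conversion. All
#' intermediate quantities are integers (exactly representable in doubles
#' for the orders used here), so the coefficients are exact.
#'
#' @param i moment order, integer >= 0.
#' @param nu degrees of freedom.
#' @return Numeric vector of length `i + 1`.
#' @examples
#' ncx2_moment_poly(1, 4)  # c(4, 1): E = nu + delta
#' @export
ncx2_moment_poly <- function(i, nu) {
  if (length(i) != 1L || i < 0 || i != round(i))
    stop("'i' must be a nonnegative integer", call. = FALSE)
  if (i == 0) return(1)
  kap <- lapply(1:i, function(j) {
    s <- 2^(j - 1) * factorial(j - 1)
    c(s * nu, s * j)
  })
  mom <- vector("list", i + 1L)
  mom[[1L]] <- 1
  for (m in 1:i) {
    acc <- numeric(m + 1L)
    for (k in 0:(m - 1)) {
      term <- choose(m - 1, k) * poly_mul(kap[[k + 1L]], mom[[m - k]])
      acc <- acc + pad_to(term, m + 1L)
    }
    mom[[m + 1L]] <- acc
  }
  mom[[i + 1L]]
}

#' Raw moments of the case statistic F0 as polynomials in lambda
#'
#' The i-th raw moment of the noncentral `F(nu1, nu2, n * lambda)` law of
#' `F0` equals the i-th noncentral chi-square moment (with noncentrality
#' `delta = n * lambda`) rescaled by
#' `nu2^i * Gamma(nu2/2 - i) / ((2 * nu1)^i * Gamma(nu2/2))`, and is a
#' polynomial of degree i in `lambda`. It exists only for `nu2 > 2 * i`,
#' which is what limits the usable polynomial degree to
#' `r < (n - nu1) / 2`.
#'
#' @param i moment order.
#' @param dims an [mi_dims()] object with `nu2 > 2 * i`.
#' @return Numeric vector: coefficients of `lambda^0, ..., lambda^i` in
#'   `E(F0^i)`.
#' @examples
#' f0_moment_poly(1, mi_dims(4, 20))  # E(F0) = (nu1 + n*lambda)*nu2/(nu1*(nu2-2))
#' @export
f0_moment_poly <- function(i, dims) {
  dims <- as_mi_dims(dims)
  if (length(i) != 1L || i < 0 || i != round(i))
    stop("'i' must be a nonnegative integer", call. = FALSE)
  if (dims$nu2 <= 2 * i)
    stop("moment of order ", i, " does not exist: requires nu2 > 2i, i.e. ",
         "degree r < (n - nu1)/2 = ", (dims$n - dims$nu1) / 2, call. = FALSE)
  cf <- ncx2_moment_poly(i, dims$nu1)
  cf <- cf * dims$n^(0:i)  # substitute delta = n * lambda
  if (i >= 1)
    cf <- cf * dims$nu2^i / (dims$nu1^i * prod(dims$nu2 - 2 * (1:i)))
  cf
}

# cache of moment matrices and Vandermonde inverses; keyed per configuration
.poly_cache <- new.env(parent = emptyenv())

moment_matrix <- function(dims, r) {
  key <- sprintf("C.%d.%d.%d", dims$nu1, dims$nu2, r)
  if (!is.null(.poly_cache[[key]])) return(.poly_cache[[key]])
  C <- matrix(0, r + 1L, r + 1L)  # C[j+1, i+1] = coeff of lambda^j in E(F0^i)
  for (i in 0:r) C[1:(i + 1L), i + 1L] <- f0_moment_poly(i, dims)
  .poly_cache[[key]] <- C
  C
}

vandermonde_inv <- function(r) {
  key <- sprintf("V.%d", r)
  if (!is.null(.poly_cache[[key]])) return(.poly_cache[[key]])
  xs <- (0:(r - 1)) / (r - 1)
  V <- solve(outer(xs, 0:(r - 1), `^`))
  .poly_cache[[key]] <- V
  V
}

#' Data-driven endpoints for the polynomial approximation interval
#'
#' The approximation interval `[a, b]` brackets the plausible values of the
#' unknown noncentrality given the observed `F0`: `b = L_0.001 / n` (upper
#' inverted-noncentrality quantile). The lower endpoint is
#' `a = 0.99 * L_0.5 / n` when that median value exceeds the chi-square
#' mode `max(nu1 - 2, 0)` (placing `a` just below the sample median
#' markedly improves polynomial accuracy), and `a = L_0.999 / n`
#' otherwise. If the bracket degenerates (`b <= a`, e.g. `F0 = 0`
#' truncating every quantile to zero), the fallback interval
#' `[0, qchisq(0.999, nu1)]` is used and flagged.
#'
#' @param F0 nonnegative transformed case statistic.
#' @param dims an [mi_dims()] object.
#' @return `c(a, b)` with attribute `"fallback"` (logical).
#' @export
select_endpoints <- function(F0, dims) {
  dims <- as_mi_dims(dims)
  if (length(F0) != 1L || !is.finite(F0) || F0 < 0)
    stop("'F0' must be a single nonnegative number", call. = FALSE)
  nu1 <- dims$nu1; nu2 <- dims$nu2; n <- dims$n
  b <- invL(F0, 0.001, nu1, nu2, n) / n
  med <- invL(F0, 0.5, nu1, nu2, n) / n
  a <- if (med > max(nu1 - 2, 0)) 0.99 * med else invL(F0, 0.999, nu1, nu2, n) / n
  if (b <= a)
    return(structure(c(a = 0, b = stats::qchisq(0.999, nu1)), fallback = TRUE))
  structure(c(a = a, b = b), fallback = FALSE)
}

#' Target polynomial coefficients for the survival function of a chi-square
#'
#' Both constructions return the coefficients of
#' `lambda^0, ..., lambda^r` of a degree-r polynomial approximating
#' `P(lambda) = 1 - G(lambda)` on `[a, b]`, where `G` is the chi-square
#' CDF on `nu1` degrees of freedom.
#'
#' `bernstein_target_coeffs` expands the Bernstein polynomial of `G` on
#' `[a, b]`:
#' `B_r = 1 - sum_i C(r,i) ((lambda-a)/(b-a))^i ((b-lambda)/(b-a))^(r-i) G(a + (b-a) i/r)`.
#' It reproduces `1 - G` exactly at both endpoints and converges uniformly
#' (slowly, at rate 1/r) on the interval.
#'
#' `quadrature_target_coeffs` instead approximates the chi-square *density*
#' on `[a, b]` (transformed to `[0, 1]`) by its Lagrange interpolant at the
#' `r` equally spaced nodes `i/(r - 1), i = 0, ..., r - 1` — a degree-(r-1)
#' polynomial — and integrates it exactly, giving
#' `1 - G(a) - integral` as a degree-r polynomial in `lambda`. For smooth
#' densities this interpolatory (Newton-Cotes type) construction is much
#' more accurate than the Bernstein operator at equal degree, though it can
#' oscillate near the endpoints.
#'
#' @param a,b interval endpoints, `a < b` (see [select_endpoints()]).
#' @param r polynomial degree (`r >= 1` for Bernstein, `r >= 2` for
#'   quadrature).
#' @param nu1 chi-square degrees of freedom.
#' @return Numeric vector of length `r + 1`.
#' @export
bernstein_target_coeffs <- function(a, b, r, nu1) {
  if (!(a < b)) stop("'a' must be strictly below 'b'", call. = FALSE)
  if (r < 1 || r != round(r)) stop("'r' must be an integer >= 1", call. = FALSE)
  d <- b - a
  acc <- numeric(r + 1L)
  for (i in 0:r) {
    term <- poly_mul(affine_pow(-a / d, 1 / d, i),
                     affine_pow(b / d, -1 / d, r - i)) *
      choose(r, i) * stats::pchisq(a + d * i / r, nu1)
    acc <- acc + term[1:(r + 1L)]
  }
  tgt <- -acc
  tgt[1L] <- tgt[1L] + 1
  tgt
}

#' @rdname bernstein_target_coeffs
#' @export
quadrature_target_coeffs <- function(a, b, r, nu1) {
  if (!(a < b)) stop("'a' must be strictly below 'b'", call. = FALSE)
  if (r < 2 || r != round(r)) stop("'r' must be an integer >= 2", call. = FALSE)
  d <- b - a
  nodes <- (0:(r - 1)) / (r - 1)
  fv <- d * stats::dchisq(a + d * nodes, nu1)     # transformed density at nodes
  qc <- as.numeric(vandermonde_inv(r) %*% fv)     # interpolant, x^0..x^(r-1)
  acc <- numeric(r + 1L)
  for (k in 0:(r - 1)) {                          # term-wise exact integral
    sub <- affine_pow(-a / d, 1 / d, k + 1L) / (k + 1L) * qc[k + 1L]
    acc <- acc + pad_to(sub, r + 1L)
  }
  tgt <- -acc
  tgt[1L] <- tgt[1L] + 1 - stats::pchisq(a, nu1)
  tgt
}

#' Match estimator coefficients to a target polynomial in lambda
#'
#' Solves `sum_i b_i * E(F0^i) = sum_j a_j * lambda^j` for the estimator
#' coefficients `b_i` by equating coefficients of like powers of `lambda`.
#' Because `E(F0^i)` has degree exactly i with a positive leading
#' coefficient, the system is triangular and solved by back-substitution
#' from `b_r = a_r / c_{r,r}`. The coefficient identity is re-checked and a
#' warning (with a condition-number estimate) is issued if the relative
#' residual exceeds 1e-6.
#'
#' @param target coefficients `a_0, ..., a_r` of the lambda-side polynomial.
#' @param moments list of length `r + 1`; element `i + 1` holds the
#'   coefficients of `E(F0^i)` as returned by [f0_moment_poly()].
#' @return Coefficients `b_0, ..., b_r`.
#' @export
solve_matched_coeffs <- function(target, moments) {
  r <- length(target) - 1L
  if (length(moments) != r + 1L)
    stop("'moments' must hold orders 0..r = 0..", r, call. = FALSE)
  C <- matrix(0, r + 1L, r + 1L)
  for (i in 0:r) C[1:(i + 1L), i + 1L] <- pad_to(moments[[i + 1L]], i + 1L)[1:(i + 1L)]
  b <- numeric(r + 1L)
  for (j in r:0) {
    s <- if (j < r) sum(C[j + 1L, (j + 2L):(r + 1L)] * b[(j + 2L):(r + 1L)]) else 0
    b[j + 1L] <- (target[j + 1L] - s) / C[j + 1L, j + 1L]
  }
  recon <- as.numeric(C %*% b)
  rel <- max(abs(recon - target) / pmax(abs(target), 1))
  if (rel > 1e-6)
    warning(sprintf(paste0("matched-coefficient solve is ill-conditioned: ",
                           "relative residual %.3g (condition estimate %.3g)"),
                    rel, kappa(C)), call. = FALSE)
  b
}

#' Polynomial (moment-matched, approximately unbiased) estimators of P
#'
#' Evaluates `sum(b_i * F0^i)` (Horner form) with `b_i` matched to the
#' Bernstein or quadrature target of the requested degree on the
#' data-driven interval from [select_endpoints()]. Requires
#' `nu2 > 2 * degree`, i.e. `degree < (n - nu1) / 2`, so that all moments
#' used in the matching exist. The estimate can leave \[0, 1\] for very
#' small or very large `lambda0`; by default it is reported unclipped with
#' `in_range = FALSE`, and `clip = TRUE` constrains it to \[0, 1\].
#'
#' @param lambda0 nonnegative sample Mahalanobis index.
#' @param dims an [mi_dims()] object.
#' @param degree polynomial degree r; 4, 7 and 10 are the tabulated
#'   choices, any `r < (n - nu1)/2` works.
#' @param family `"quadrature"` (marginally less biased; the recommended
#'   family) or `"bernstein"`.
#' @param clip clip the value into \[0, 1\]? Default `FALSE`.
#' @return An `mi_estimate`.
#' @examples
#' estimate_PP(2, mi_dims(4, 20), degree = 7, family = "quadrature")
#' @export
estimate_PP <- function(lambda0, dims, degree,
                        family = c("quadrature", "bernstein"), clip = FALSE) {
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  family <- match.arg(family)
  if (length(degree) != 1L || degree < 1 || degree != round(degree))
    stop("'degree' must be a positive integer", call. = FALSE)
  if (dims$nu2 <= 2 * degree)
    stop("degree ", degree, " unavailable at nu2 = ", dims$nu2,
         ": the polynomial degree r must be strictly less than (n - nu1)/2 = ",
         (dims$n - dims$nu1) / 2, call. = FALSE)
  value <- pP_value(lambda0, dims, degree, family)
  notes <- sprintf("%s, degree %d", family, degree)
  if (clip) {
    if (value < 0 || value > 1)
      notes <- c(notes, sprintf("clipped from %.4f", value))
    value <- min(max(value, 0), 1)
  }
  est <- mi_estimate(sprintf("P%s%d", if (family == "bernstein") "B" else "Q",
                             degree),
                     value, notes = notes)
  est
}

# vectorised kernel; endpoints and coefficients are per-observation,
# moment matrix is cached per (dims, degree)
pP_value <- function(lambda0, dims, degree, family) {
  C <- moment_matrix(dims, degree)  # warm the cache
  vapply(lambda0, function(l) {
    F0 <- compute_F0(l, dims)
    ab <- select_endpoints(F0, dims)
    tgt <- if (family == "bernstein")
      bernstein_target_coeffs(ab[1L], ab[2L], degree, dims$nu1)
    else
      quadrature_target_coeffs(ab[1L], ab[2L], degree, dims$nu1)
    b <- numeric(degree + 1L)
    for (j in degree:0) {
      s <- if (j < degree)
        sum(C[j + 1L, (j + 2L):(degree + 1L)] * b[(j + 2L):(degree + 1L)])
      else 0
      b[j + 1L] <- (tgt[j + 1L] - s) / C[j + 1L, j + 1L]
    }
    v <- 0
    for (cf in rev(b)) v <- v * F0 + cf  # Horner
    v
  }, numeric(1))
}
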