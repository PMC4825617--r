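# Registry of the fourteen estimators. Each entry supplies a vectorised
# kernel over lambda0, a constraint check on the dims, and whether the
# estimator is expensive per replicate (root-find ladders / numerical
# integration), which the simulation harness uses for its budget.
estimator_registry <- function() {
  poly_entry <- function(family, degree) {
    list(kernel = function(lambda0, dims, clip = FALSE) {
      v <- pP_value(lambda0, dims, degree, family)
      if (clip) v <- pmin(pmax(v, 0), 1)
      v
    },
    check = function(dims)
      if (dims$nu2 <= 2 * degree)
        sprintf("requires nu2 > %d (degree r < (n - nu1)/2)", 2 * degree),
    expensive = FALSE, bounded = FALSE)
  }
  list(
    PF    = list(kernel = function(lambda0, dims, clip = FALSE) pF_value(lambda0, dims),
                 check = function(dims) NULL, expensive = FALSE, bounded = TRUE),
    Pchi2 = list(kernel = function(lambda0, dims, clip = FALSE) pchi2_value(lambda0, dims),
                 check = function(dims) NULL, expensive = FALSE, bounded = TRUE),
    PD    = list(kernel = function(lambda0, dims, clip = FALSE) pD_value(lambda0, dims),
                 check = function(dims) NULL, expensive = FALSE, bounded = TRUE),
    PMD   = list(kernel = function(lambda0, dims, clip = FALSE) pMD_value(lambda0, dims),
                 check = function(dims) NULL, expensive = TRUE, bounded = TRUE),
    PBY   = list(kernel = function(lambda0, dims, clip = FALSE) pBY_value(lambda0, dims),
                 check = function(dims) NULL, expensive = TRUE, bounded = TRUE),
    PM    = list(kernel = function(lambda0, dims, clip = FALSE) pM_value(lambda0, dims),
                 check = function(dims)
                   if (dims$nu2 <= 2) "requires nu2 > 2", expensive = FALSE,
                 bounded = TRUE),
    PR    = list(kernel = function(lambda0, dims, clip = FALSE) pR_value(lambda0, dims),
                 check = function(dims)
                   if (dims$nu2 <= 4) "requires nu2 > 4", expensive = FALSE,
                 bounded = TRUE),
    PT    = list(kernel = function(lambda0, dims, clip = FALSE) pT_value(lambda0, dims),
                 check = function(dims)
                   if (dims$nu2 <= 4) "requires nu2 > 4", expensive = FALSE,
                 bounded = TRUE),
    PB4  = poly_entry("bernstein", 4),
    PB7  = poly_entry("bernstein", 7),
    PB10 = poly_entry("bernstein", 10),
    PQ4  = poly_entry("quadrature", 4),
    PQ7  = poly_entry("quadrature", 7),
    PQ10 = poly_entry("quadrature", 10)
  )
}

#' Names of the available estimators of P
#' @return Character vector of the fourteen estimator names.
#' @export
estimator_names <- function() names(estimator_registry())

check_estimators <- function(methods, dims) {
  reg <- estimator_registry()
  bad <- setdiff(methods, names(reg))
  if (length(bad))
    stop("unknown estimator(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  for (m in methods) {
    msg <- reg[[m]]$check(dims)
    if (!is.null(msg))
      stop("estimator ", m, " unavailable at nu1 = ", dims$nu1,
           ", nu2 = ", dims$nu2, ": ", msg, call. = FALSE)
  }
  invisible(reg[methods])
}

#' Estimate the abnormality of a case's Mahalanobis index
#'
#' One-stop interface: given either the sample Mahalanobis index `lambda0`
#' (with `dims`) or a raw control sample plus case profile, computes any
#' subset of the fourteen point estimators of P together with the exact
#' confidence interval. The default methods follow the practical
#' recommendations: the modified median estimator `PMD` as the descriptive
#' estimate, and the quadrature polynomial of degree 4 (`nu2 < 20`) or 7
#' (`nu2 >= 20`) when low bias matters.
#'
#' @param lambda0 nonnegative sample Mahalanobis index (omit when
#'   `controls` is given).
#' @param dims an [mi_dims()] object (omit when `controls` is given).
#' @param controls optional n x nu1 numeric matrix of control profiles.
#' @param case_profile optional length-nu1 case profile (required with
#'   `controls`).
#' @param methods character vector of estimator names (see
#'   [estimator_names()]); `NULL` selects the recommended default set.
#' @param level confidence level of the interval (default 0.95).
#' @param clip clip polynomial estimates into \[0, 1\]? Default `FALSE`.
#' @return Object of class `"mi_abnormality"`: list with `lambda0`, `F0`,
#'   `dims`, `estimates` (a data.frame with columns `method`, `value`,
#'   `in_range`, `notes`) and `interval` (an `"mi_interval"`).
#' @examples
#' estimate_abnormality(0.4, mi_dims(4, 20), methods = c("PD", "PMD"))
#' @export
estimate_abnormality <- function(lambda0 = NULL, dims = NULL,
                                 controls = NULL, case_profile = NULL,
                                 methods = NULL, level = 0.95, clip = FALSE) {
  if (!is.null(controls)) {
    if (is.null(case_profile))
      stop("'case_profile' is required with 'controls'", call. = FALSE)
    got <- compute_lambda0_from_data(controls, case_profile)
    lambda0 <- got$lambda0
    dims <- got$dims
  }
  if (is.null(lambda0) || is.null(dims))
    stop("supply either lambda0 + dims, or controls + case_profile",
         call. = FALSE)
  dims <- as_mi_dims(dims)
  check_lambda0(lambda0)
  if (is.null(methods))
    methods <- c("PMD", "PD", if (dims$nu2 < 20) "PQ4" else "PQ7")
  reg <- check_estimators(methods, dims)
  rows <- lapply(methods, function(m) {
    v <- reg[[m]]$kernel(lambda0, dims, clip = clip)
    est <- mi_estimate(m, v)
    if (clip && !reg[[m]]$bounded) est$notes <- "clipped to [0, 1] if needed"
    as.data.frame(est)
  })
  out <- list(lambda0 = lambda0,
              F0 = compute_F0(lambda0, dims),
              dims = dims,
              estimates = do.call(rbind, rows),
              interval = confidence_interval(lambda0, dims, level))
  class(out) <- "mi_abnormality"
  out
}

#' @export
print.mi_abnormality <- function(x, ...) {
  cat(sprintf("Abnormality of a Mahalanobis index (nu1 = %d, nu2 = %d, n = %d)\n",
              x$dims$nu1, x$dims$nu2, x$dims$n))
  cat(sprintf("  lambda0 = %.4f, F0 = %.4f\n\n", x$lambda0, x$F0))
  for (i in seq_len(nrow(x$estimates))) {
    e <- x$estimates[i, ]
    cat(sprintf("  %-6s %7.2f%%%s\n", e$method, 100 * e$value,
                if (!e$in_range) "  [outside 0-100%]" else ""))
  }
  cat("\n")
  print(x$interval)
  invisible(x)
}
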