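#' Sample Mahalanobis index of a case against a control sample
#'
#' Computes `lambda0 = (x* - xbar)' S^{-1} (x* - xbar)` from a control
#' matrix (rows = individuals, columns = scores) and a case profile, with
#' `xbar` the sample mean and `S` the unbiased (divisor `n - 1`) sample
#' covariance. The index is invariant under any invertible affine
#' transformation applied to controls and case together.
#'
#' @param controls numeric n x nu1 matrix (or data.frame) of control
#'   profiles; needs `n > nu1 + 1` so that `S` is invertible with at least
#'   one residual degree of freedom.
#' @param case_profile numeric vector of length nu1.
#' @return List with `lambda0` and `dims` (an [mi_dims()] with
#'   `nu2 = n - nu1`).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' compute_lambda0_from_data(X, c(1, 1, 1))
#' @export
compute_lambda0_from_data <- function(controls, case_profile) {
  controls <- as.matrix(controls)
  if (!is.numeric(controls) || anyNA(controls))
    stop("'controls' must be a complete numeric matrix", call. = FALSE)
  n <- nrow(controls); nu1 <- ncol(controls)
  if (length(case_profile) != nu1)
    stop("'case_profile' must have one value per control score column (",
         nu1, ")", call. = FALSE)
  if (n <= nu1 + 1)
    stop("need n > nu1 + 1 controls (got n = ", n, ", nu1 = ", nu1,
         "): nu2 = n - nu1 must be >= 1 and S must be invertible",
         call. = FALSE)
  S <- stats::cov(controls)
  cond <- kappa(S, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12)
    stop("sample covariance is singular or ill-conditioned ",
         "(condition number ", format(cond, digits = 3),
         "); check for collinear or constant score columns", call. = FALSE)
  lambda0 <- as.numeric(stats::mahalanobis(case_profile, colMeans(controls), S))
  list(lambda0 = lambda0, dims = mi_dims(nu1, n - nu1))
}

read_matrix_file <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]])))
  as.matrix(utils::read.table(path, header = has_header, sep = sep))
}

simsummary_to_json <- function(summary, path, config) {
  payload <- list(
    config = list(nu1 = config$dims$nu1, nu2 = config$dims$nu2,
                  true_P = config$true_P, N = config$N, seed = config$seed,
                  sampling_mode = config$sampling_mode,
                  estimators = config$estimators,
                  clip_polynomials = config$clip_polynomials,
                  N_expensive = config$N_expensive),
    results = as.data.frame(summary))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
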