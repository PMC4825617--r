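# Monte-Carlo study harness: draws sample Mahalanobis indices for a case
# with known true abnormality P, evaluates estimators, and summarises
# bias, RMSE, median error and average absolute error in percentage
# points.

#' True noncentrality corresponding to an abnormality P
#'
#' Since `P = Pr(chisq_nu1 > lambda)`, the population index giving true
#' abnormality P is the `(1 - P)`-quantile of the chi-square on `nu1`
#' degrees of freedom.
#'
#' @param P probability in (0, 1) (vectorised).
#' @param nu1 degrees of freedom.
#' @return Nonnegative `lambda`.
#' @examples
#' true_lambda_from_P(0.5, 2)  # 2 log 2
#' @export
true_lambda_from_P <- function(P, nu1) {
  if (any(P <= 0) || any(P >= 1))
    stop("'P' must lie strictly inside (0, 1)", call. = FALSE)
  stats::qchisq(1 - P, nu1)
}

#' Case profile with a prescribed population Mahalanobis index
#'
#' For the standardised population (`mu = 0`, `Sigma = I`), an
#' equal-elements profile with each score `sqrt(lambda / nu1)` has
#' Mahalanobis index exactly `lambda`. (Unequal-element profiles with the
#' same index behave identically since every estimator depends on the data
#' only through `lambda0`.)
#'
#' @param lambda nonnegative target index.
#' @param nu1 profile length.
#' @return Numeric vector of length `nu1`.
#' @export
make_case_profile <- function(lambda, nu1) {
  if (length(lambda) != 1L || lambda < 0)
    stop("'lambda' must be a single nonnegative number", call. = FALSE)
  rep(sqrt(lambda / nu1), nu1)
}

#' Draw sample Mahalanobis indices for a fixed case
#'
#' Two exactly equivalent sampling routes for the sample index `lambda0`
#' of a case with population index `lambda`:
#'
#' * `"ncf_direct"` draws `F0 ~ F(nu1, nu2, ncp = n * lambda)` and maps it
#'   back through [lambda0_from_F0()] — the exact sampling law of
#'   `lambda0`, and roughly two orders of magnitude faster;
#' * `"mvn_full"` draws `n` control profiles from `MVN(0, I)`, computes
#'   the sample mean and covariance, and evaluates the quadratic form for
#'   the equal-elements case profile of index `lambda` — the full
#'   data-generating story.
#'
#' @param lambda nonnegative true population index of the case.
#' @param dims an [mi_dims()] object.
#' @param nsim number of draws.
#' @param mode `"ncf_direct"` (default) or `"mvn_full"`.
#' @return Numeric vector of `nsim` nonnegative sample indices.
#' @export
simulate_lambda0 <- function(lambda, dims, nsim,
                             mode = c("ncf_direct", "mvn_full")) {
  dims <- as_mi_dims(dims)
  mode <- match.arg(mode)
  if (lambda < 0) stop("'lambda' must be nonnegative", call. = FALSE)
  if (mode == "ncf_direct") {
    F0 <- stats::rf(nsim, dims$nu1, dims$nu2, ncp = dims$n * lambda)
    return(lambda0_from_F0(F0, dims))
  }
  xstar <- make_case_profile(lambda, dims$nu1)
  vapply(seq_len(nsim), function(i) {
    X <- matrix(stats::rnorm(dims$n * dims$nu1), dims$n, dims$nu1)
    S <- stats::cov(X)
    d2 <- try(stats::mahalanobis(xstar, colMeans(X), S), silent = TRUE)
    while (inherits(d2, "try-error")) {  # singular S: probability-zero event
      warning("singular sample covariance encountered; resampling",
              call. = FALSE)
      X <- matrix(stats::rnorm(dims$n * dims$nu1), dims$n, dims$nu1)
      d2 <- try(stats::mahalanobis(xstar, colMeans(X), stats::cov(X)),
                silent = TRUE)
    }
    d2
  }, numeric(1))
}

#' Configuration of a Monte-Carlo estimator study
#'
#' @param nu1,nu2 degrees of freedom of each study cell.
#' @param true_P true abnormalities examined; default the tabulated grid
#'   1%, 2.5%, 5%, 10%, 20%, 40%.
#' @param N replicates per cell; the reference design uses 100,000.
#' @param seed root seed; each `(true_P)` cell uses an independent
#'   derived substream so adding estimators or cells leaves existing cells
#'   unchanged.
#' @param sampling_mode passed to [simulate_lambda0()].
#' @param estimators estimator names; default all estimators valid at
#'   these dims.
#' @param clip_polynomials clip polynomial estimates into \[0, 1\] before
#'   summarising? Default `FALSE` (the low tabulated biases are only
#'   reproduced unclipped).
#' @param N_expensive replicate cap for the expensive estimators `PMD` and
#'   `PBY` (posterior integration / 499 root-finds per replicate);
#'   default 5000. A warning reports the reduction when it bites.
#' @return A list of class `"mi_sim_config"`.
#' @export
sim_config <- function(nu1, nu2,
                       true_P = c(0.01, 0.025, 0.05, 0.10, 0.20, 0.40),
                       N = 100000, seed = 1,
                       sampling_mode = c("ncf_direct", "mvn_full"),
                       estimators = NULL, clip_polynomials = FALSE,
                       N_expensive = 5000) {
  dims <- mi_dims(nu1, nu2)
  sampling_mode <- match.arg(sampling_mode)
  if (any(true_P <= 0) || any(true_P >= 1))
    stop("'true_P' values must lie strictly inside (0, 1)", call. = FALSE)
  if (N < 1) stop("'N' must be >= 1", call. = FALSE)
  if (is.null(estimators)) {
    reg <- estimator_registry()
    estimators <- names(reg)[vapply(reg, function(e) is.null(e$check(dims)),
                                    logical(1))]
  }
  check_estimators(estimators, dims)
  structure(list(dims = dims, true_P = true_P, N = as.integer(N),
                 seed = as.integer(seed), sampling_mode = sampling_mode,
                 estimators = estimators,
                 clip_polynomials = isTRUE(clip_polynomials),
                 N_expensive = as.integer(N_expensive)),
            class = "mi_sim_config")
}

#' Run a Monte-Carlo estimator study
#'
#' For each true abnormality in the configuration, draws `N` sample
#' indices for a case with that abnormality, evaluates every requested
#' estimator on each draw, and summarises the errors `estimate - P` as
#' average bias, root mean square error, median error and average
#' absolute error, all in percentage points, together with the
#' Monte-Carlo standard error of the bias. Deterministic for a fixed
#' configuration (including seed).
#'
#' @param config an [sim_config()] object.
#' @return Object of class `"mi_simsummary"`: a data.frame with columns
#'   `nu1`, `nu2`, `true_P`, `estimator`, `bias_pp`, `rmse_pp`, `me_pp`,
#'   `aae_pp`, `mc_se_pp`, `N`, `seed`.
#' @examples
#' cfg <- sim_config(2, 10, true_P = 0.05, N = 200, estimators = "Pchi2")
#' run_study(cfg)
#' @export
run_study <- function(config) {
  if (!inherits(config, "mi_sim_config"))
    stop("'config' must come from sim_config()", call. = FALSE)
  dims <- config$dims
  reg <- check_estimators(config$estimators, dims)
  warned <- FALSE
  rows <- list()
  for (ip in seq_along(config$true_P)) {
    P <- config$true_P[ip]
    set.seed((config$seed + 7919L * ip) %% .Machine$integer.max)
    lambda <- true_lambda_from_P(P, dims$nu1)
    lam0 <- simulate_lambda0(lambda, dims, config$N, config$sampling_mode)
    for (m in config$estimators) {
      Ne <- config$N
      if (reg[[m]]$expensive && Ne > config$N_expensive) {
        Ne <- config$N_expensive
        if (!warned) {
          warning("expensive estimator(s) evaluated on the first ",
                  config$N_expensive, " of ", config$N,
                  " replicates; see 'N_expensive'", call. = FALSE)
          warned <- TRUE
        }
      }
      vals <- reg[[m]]$kernel(lam0[seq_len(Ne)], dims,
                              clip = config$clip_polynomials)
      err <- vals - P
      rows[[length(rows) + 1L]] <- data.frame(
        nu1 = dims$nu1, nu2 = dims$nu2, true_P = P, estimator = m,
        bias_pp = 100 * mean(err),
        rmse_pp = 100 * sqrt(mean(err^2)),
        me_pp   = 100 * stats::median(err),
        aae_pp  = 100 * mean(abs(err)),
        mc_se_pp = 100 * stats::sd(err) / sqrt(Ne),
        N = Ne, seed = config$seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mi_simsummary", "data.frame")
  out
}

#' @export
print.mi_simsummary <- function(x, ...) {
  cat(sprintf("Monte-Carlo estimator study (nu1 = %d, nu2 = %d)\n",
              x$nu1[1], x$nu2[1]))
  df <- as.data.frame(x)
  df$true_P <- sprintf("%g%%", 100 * df$true_P)
  for (col in c("bias_pp", "rmse_pp", "me_pp", "aae_pp"))
    df[[col]] <- sprintf("%.1f", df[[col]])
  df$mc_se_pp <- sprintf("%.2f", df$mc_se_pp)
  print(df[, c("true_P", "estimator", "bias_pp", "rmse_pp", "me_pp",
               "aae_pp", "mc_se_pp", "N")], row.names = FALSE)
  invisible(x)
}

#' Sweep estimators over a grid of observed indices
#'
#' Evaluates each estimator at fixed observed values `lambda0` (no
#' randomness) and reports range, monotonicity violations and where the
#' estimate leaves \[0, 1\]. The bounded estimators never leave the range;
#' the polynomial families can exceed 1 at small `lambda0` and drop below
#' 0 at large `lambda0`.
#'
#' @param dims an [mi_dims()] object.
#' @param lambda0_grid nonnegative, increasing grid of observed indices.
#' @param estimators estimator names; default all valid at `dims`.
#' @return A data.frame with one row per estimator: `min`, `max`,
#'   `n_above_1`, `n_below_0`, `n_nonmonotone` (count of increases of the
#'   value along the increasing grid), `out_of_range_at` (compact list of
#'   offending grid values). The full value matrix is attached as
#'   attribute `"values"`.
#' @export
estimator_profile <- function(dims, lambda0_grid, estimators = NULL) {
  dims <- as_mi_dims(dims)
  if (length(lambda0_grid) == 0)
    return(data.frame(estimator = character(), min = numeric(),
                      max = numeric(), n_above_1 = integer(),
                      n_below_0 = integer(), n_nonmonotone = integer(),
                      out_of_range_at = character(),
                      stringsAsFactors = FALSE))
  check_lambda0(lambda0_grid)
  if (is.unsorted(lambda0_grid))
    stop("'lambda0_grid' must be increasing", call. = FALSE)
  if (is.null(estimators)) {
    reg0 <- estimator_registry()
    estimators <- names(reg0)[vapply(reg0, function(e) is.null(e$check(dims)),
                                     logical(1))]
  }
  reg <- check_estimators(estimators, dims)
  vals <- sapply(estimators, function(m) reg[[m]]$kernel(lambda0_grid, dims))
  vals <- matrix(vals, nrow = length(lambda0_grid),
                 dimnames = list(NULL, estimators))
  rows <- lapply(estimators, function(m) {
    v <- vals[, m]
    oor <- lambda0_grid[v < 0 | v > 1]
    data.frame(estimator = m, min = min(v), max = max(v),
               n_above_1 = sum(v > 1), n_below_0 = sum(v < 0),
               n_nonmonotone = sum(diff(v) > 0),
               out_of_range_at = paste(signif(oor, 4), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "values") <- vals
  out
}
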