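---
title: "Estimating the abnormality of a Mahalanobis index: models, estimators and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the abnormality of a Mahalanobis index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A single case — in the motivating application, a neuropsychology patient —
provides a profile `x*` of `nu1` test scores. A normative population is
modelled as multivariate normal with mean `mu` and covariance `Sigma`, and
the case's population Mahalanobis index is
`lambda = (x* - mu)' Sigma^{-1} (x* - mu)`. Because the index of a random
member of the population follows a central chi-square distribution on
`nu1` degrees of freedom, the natural measure of how unusual the case is,
its *abnormality*, is

    P = Pr(chisq_nu1 > lambda) = 1 - G(lambda),

with `G` the chi-square CDF. `P` near 0 means almost nobody is more extreme
than the case; `P` near 1 means the case sits at the centre of the
population.

Only a control sample of `n` profiles is available, so `lambda` is observed
through the sample index `lambda0` computed with the sample mean and
(unbiased, divisor `n - 1`) covariance. Everything in this package rests on
the exact sampling law of the rescaled index: with `nu2 = n - nu1`,

    F0 = n * nu2 * lambda0 / ((n - 1) * nu1)  ~  F(nu1, nu2, ncp = n * lambda).

Assumptions worth stating plainly: the population is multivariate normal;
the case profile is treated as fixed (no distributional assumption about
where `x*` comes from); the controls are an i.i.d. sample from the
population; and `n > nu1` so the sample covariance is invertible. The
package refuses singular or nearly singular covariances rather than
regularising them.

## Interval estimation and the inversion primitive

Define `L_alpha` as the noncentrality (on the `n * lambda` scale) at which
the observed `F0` is the `alpha`-quantile of `F(nu1, nu2, L)`. Since that
CDF is strictly decreasing in `L`, `L_alpha` exists, is unique, and an
equal-tailed `100(1 - alpha)%` confidence interval for P is
`[1 - G(L_{alpha/2}/n), 1 - G(L_{1-alpha/2}/n)]`, with exact coverage up to
the standard truncation: when `F0` falls below the relevant central-F
quantile there is no positive root and `L` is set to 0 (so the upper limit
becomes exactly 1). `invert_noncentrality()` implements this with a
bracketing solver (`uniroot`) on `[0, U]`, doubling `U` from the initial
guess `n * (lambda0 + nu1)` until the bracket encloses the root, with
tolerance `1e-10` — far below the two-decimal precision at which
percentages are reported. Truncation is applied within the same `1e-10`
tolerance on the CDF scale so that boundary inputs are not missed to
floating-point rounding. All probability arithmetic is done on the CDF
scale (not log scale); the quantities involved never reach tails extreme
enough to underflow.

## The fourteen point estimators

**Plug-in (`PF`, `Pchi2`).** Replace unknown parameters by maximum
likelihood estimates inside the defining probability. `PF` is the p-value
of the one-sample Hotelling test (central F survival function at the
scaled statistic); `Pchi2` keeps the population chi-square law but plugs in
the sample index. Both are biased: `PF` upward everywhere, `Pchi2` downward
and badly so at large P. The Hotelling multiplier
`n * nu2 / ((n + 1)(n - 1) nu1)` is assembled in a single expression since
tabulated comparisons are sensitive at the 0.05-point level.

**Median family (`PD`, `PMD`).** `PD = 1 - G(L_0.5 / n)` has median error
essentially zero by construction but hits exactly 100% whenever `F0` is
below the central median — an incredible value whenever the case differs
from the population mean at all. `PMD = min(PD, 1 - G(M_lambda))` caps it:
`M_lambda` is the posterior median of the index of a *randomly chosen
control*, whose abnormality is uniform on (0, 1) a priori, implying a
chi-square prior on its index; the likelihood is the noncentral-F law of
`F0`. The two coincide except at small `lambda0`.

**Probability matching (`PBY`).** Treat the one-sided confidence limits at
quantiles `r/R` as posterior quantiles of P and average them. The defining
average runs `r = 1..R`, but the quantile `r/R = 1` has no finite limit;
with the default `R = 500` the package averages the 499 limits at
quantiles 0.002 … 0.998 (`ladder = "exclusive"`). The alternative reading —
dividing the same 499-term sum by 500 — is available as
`ladder = "inclusive-truncated"`; the two differ by at most `1/R`. `PBY`
has good interval pedigree but is a noticeably biased point estimator,
which is an instructive negative result.

**Moment family (`PM`, `PR`, `PT`).** `lambda_bar`, a linear function of
`F0`, is the minimum-variance unbiased estimator of `lambda` but can go
negative; truncating at zero gives `PM = 1 - G(max(lambda_bar, 0))`
(needs `nu2 > 2`). The admissible alternative scales `F0` by
`nu1 (nu2 - 4) / (n nu2)` and gives `PR` (needs `nu2 > 4`). `PT` corrects
the second-order bias of pushing `lambda_bar` through the nonlinear `G`: a
Taylor expansion yields the corrected point
`lambda* = lambda_bar - Varhat/2 * ((nu1/2 - 1)/lambda_bar - 1/2)`, with
`Varhat = u0 + u1 lambda_bar + u2 lambda_bar^2` the (exactly) unbiased
estimate of `Var(lambda_bar)`; coefficients carry `nu2 - 2` divisors so
that their expectation reproduces the true variance polynomial, whose
divisors are `nu2 - 4`.

*Design choice (degenerate Taylor branch).* The correction divides by
`lambda_bar`, and the source construction only covers the case where
`lambda_bar` exceeds the chi-square mode, noting the other case "can be
treated similarly" without a formula. For `lambda_bar <= 1e-8` (including
all negative values) this package falls back to the truncated form
`PT = PM`, which is continuous with the corrected branch and only affects
near-zero `lambda0`. For `nu1 = 2` the `1/lambda_bar` term has a zero
coefficient and the simplified expression `lambda_bar + Varhat/4` is used
directly.

**Polynomial family (`PB4/7/10`, `PQ4/7/10`).** The only estimators that
are approximately unbiased *uniformly* in P. Approximate
`P(lambda) = 1 - G(lambda)` on an interval `[a, b]` by a polynomial
`sum a_i lambda^i` of degree `r`; since each `E(F0^i)` is a degree-`i`
polynomial in `lambda`, coefficients `b_i` solving
`sum b_i E(F0^i) = sum a_i lambda^i` exist, and `sum b_i F0^i` then has
expectation equal to the polynomial approximation of P — unbiased wherever
the approximation is good. The moments exist only for `nu2 > 2i`, so the
degree is constrained by `r < (n - nu1)/2`: degree 10 needs `nu2 > 20`,
degree 7 needs `nu2 > 14`, degree 4 needs `nu2 > 8`.

Three numerical sub-problems, and the choices made:

* *Moments.* `E[(chisq_nu(delta))^i]` is built from the cumulants
  `kappa_j = 2^(j-1) (j-1)! (nu + j delta)` by the recursive
  cumulant-to-moment conversion, entirely in integer arithmetic (exact in
  doubles at these orders: the largest coefficients are ~1e12, far inside
  the 2^53 integer range); the F0 moment follows by substituting
  `delta = n lambda` and one gamma-ratio scale factor, computed as a
  product of small factors rather than a ratio of gammas. A computer
  algebra system is deliberately *not* required; exactness is guarded by a
  round-trip test (residual <= 1e-9 over every supported configuration).
* *Endpoints.* `[a, b]` should cover the plausible range of `lambda` given
  the data: `b = L_0.001 / n`, and `a = 0.99 * L_0.5 / n` when that median
  point exceeds the chi-square mode `max(nu1 - 2, 0)` (placing `a` just
  below the median greatly improves accuracy), else `a = L_0.999 / n`.
  If the bracket degenerates (e.g. `F0 = 0` truncates every quantile to
  zero) the fixed fallback `[0, qchisq(0.999, nu1)]` is used and flagged.
* *Targets.* The Bernstein target expands
  `1 - sum C(r,i) x^i (1-x)^(r-i) G(node_i)` in powers of `lambda`
  (binomial convolution with exact integer binomials before any floating
  cast); it reproduces `1 - G` exactly at both endpoints and converges
  uniformly but slowly. The quadrature target approximates the chi-square
  *density* (affinely mapped to [0, 1]) by its Lagrange interpolant at the
  `r` equally spaced nodes `i/(r-1)` — a classical interpolatory
  (Newton–Cotes type) quadrature — and integrates it exactly. For a smooth
  density this is far more accurate than the Bernstein operator at equal
  degree (on `[4, 30]` with `nu1 = 4`, `r = 7`: sup error ~0.007 versus
  ~0.08), at the price of possible oscillation near the endpoints; that
  trade-off is visible in the estimators, with the quadrature family
  slightly less biased overall and both families capable of leaving
  `[0, 1]` at extreme `lambda0`. The interpolation solve uses a cached
  inverse Vandermonde on the fixed [0, 1] nodes.
* *Matching.* Strict triangularity (each `E(F0^i)` has degree exactly `i`
  with positive leading coefficient) makes the matching a back-substitution
  from `b_r`; a residual check warns (with a condition estimate) if the
  identity degrades, which does not occur for the supported degrees.
  Evaluation uses Horner form for stability at degree 10.

Out-of-range values are reported as-is with an `in_range` flag; clipping to
`[0, 1]` is an explicit option. The default is unclipped because the
near-zero biases the family is chosen for are a property of the unclipped
estimator; clipping reintroduces bias at extreme P.

## The posterior median: numerics

The posterior for the modified median estimator is proportional to
`dchisq(lambda, nu1) * df(F0, nu1, nu2, ncp = n * lambda)`. It is smooth
and unimodal-to-monotone, so the package integrates it by the trapezoid
rule on a grid over `[0, Q]`, `Q = qchisq(1 - 1e-6, nu1) + 5 L_0.001 / n`,
mixing 25% log-spaced nodes (resolving the near-origin region, where the
prior can be steep) with 75% linear nodes — 4000 nodes by default, at
which the median is stable to ~2.5e-5 under 10x refinement (the package's
stated accuracy target is 1e-4; 2000 nodes sat exactly at that boundary,
so the default was doubled). The median is read from the normalised
cumulative by monotone linear interpolation.

One boundary subtlety: for `nu1 > 2` the noncentral-F density vanishes at
`F0 = 0`, so prior times likelihood is identically zero there. The
posterior is still well defined as a limit — the leading term of the
Poisson-mixture representation gives likelihood ratio `exp(-n lambda / 2)`
— and the implementation switches to that kernel when every density value
underflows, keeping the posterior median finite and positive for all
inputs.

## The simulation harness and what a green test establishes

The generator fixes `mu = 0`, `Sigma = I` — without loss of generality,
since every estimator depends on the data only through `lambda0` and the
Mahalanobis index is affine invariant (a property the tests verify rather
than assume). A true abnormality P maps to `lambda = qchisq(1 - P, nu1)`,
realised as the equal-elements profile `rep(sqrt(lambda/nu1), nu1)`;
unequal profiles with the same index are supported and behave identically,
which is why only the equal-elements default is exercised. The reference
design examines `nu1 in {2, 4, 8}`, `nu2 in {10, 20, 80}`,
`P in {1, 2.5, 5, 10, 20, 40}%` with 100,000 replicates per cell.

Two sampling routes are provided: `mvn_full` draws the `n x nu1` control
matrix and recomputes mean, covariance and quadratic form — the full
data-generating story; `ncf_direct` draws `F0` from its exact noncentral-F
law and back-transforms, which is distributionally identical (a
Kolmogorov–Smirnov test in the suite checks this) and roughly two orders
of magnitude faster, so it is the default. Each true-P cell runs on an
independent substream derived from the root seed, so adding estimators or
cells never perturbs existing results. The expensive estimators (`PBY`,
~500 root-finds per replicate; `PMD`, one posterior integration per
replicate) are capped at `N_expensive = 5000` replicates by default, with
a warning and with their Monte-Carlo standard errors reported so the
implied tolerance is explicit.

What the green simulation tests do establish: estimator bias/median-error
behaviour under the exactly-specified multivariate normal world, at
Monte-Carlo tolerances tied to the tabulated RMSE
(`max(3 * RMSE / sqrt(N), 0.1)` percentage points, the 0.1 covering table
rounding). What they do not establish: behaviour under non-normal
populations, missing data, or estimated (rather than fixed) case profiles
— none of which the model covers. Known limitations: no support for
singular covariances or `nu2 < 1`; the polynomial estimators are undefined
when `nu2 <= 2r`; `Pchi2`'s good RMSE at small P does not transfer to its
bias at large P; and with `nu1 > 8` the Mahalanobis framework itself
becomes questionable.

## Numerical summary of defaults

| quantity | default | why |
|---|---|---|
| inversion tolerance | 1e-10 (CDF scale) | far below 2-dp reporting precision |
| truncation guard | 1e-10 | boundary inputs robust to qf/pf rounding |
| posterior grid | 4000 nodes, 25% log-spaced, `Q = qchisq(1-1e-6) + 5 L_0.001/n` | median stable to ~2.5e-5 under refinement |
| `PBY` ladder | `R = 500`, exclusive (499 terms) | quantile 1 undefined; alternatives differ by < 1/R |
| Taylor fallback threshold | `lambda_bar <= 1e-8` | continuity with truncated estimator |
| polynomial degrees | 4, 7, 10 (others available) | tabulated reference choices; `r < (n - nu1)/2` enforced |
| polynomial clipping | off | unbiasedness is a property of the unclipped value |
| simulation mode | `ncf_direct` | exact by the sampling law; ~100x faster |
| `N_expensive` | 5000 | desk-scale runtime; MC-SE reported |
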