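Package: mahabn
Title: Point Estimation of the Abnormality of a Mahalanobis Index
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates P, the proportion of a multivariate-normal normative
    population whose squared Mahalanobis distance from the population mean
    exceeds that of a single case, from a case profile and a control sample
    of size n. Implements fourteen point estimators: the two plug-in
    maximum-likelihood p-values (central F and chi-square), median and
    modified-median estimators obtained by inverting the noncentrality
    parameter of the exact noncentral-F sampling law of the sample index, a
    probability-matching posterior mean, truncated-unbiased and admissible
    moment estimators, a Taylor-expansion bias correction, and
    approximately unbiased moment-matched polynomial estimators of degrees
    4, 7 and 10 built from Bernstein and quadrature approximations of the
    chi-square distribution function. Also provides exact confidence
    intervals for P and a Monte-Carlo harness that measures bias, root mean
    square error, median error and average absolute error of every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
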