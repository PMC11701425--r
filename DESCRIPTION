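Package: maxppc
Title: Maximal Point-Polyserial Correlation and Discrete Approximations
    of Continuous Distributions
Version: 0.1.0
Authors@R:
    person("maxppc", "developers", email = "maxppc@example.org",
           role = c("aut", "cre"))
Description: Tools for the attainable and maximal Pearson correlation
    between a continuous random variable and an ordinal variable with k
    categories. Provides closed-form partial moments for the normal,
    uniform, exponential, Pareto, logistic, power and lognormal families;
    the maximal point-polyserial correlation under comonotonicity for any
    discretization; constrained maximization over category probabilities
    with consecutive integer scores (CIS) and over free support values
    (OPT, equivalent to optimal quantization / principal points via
    Lloyd's algorithm); equal-probability closed forms and their limits as
    k grows; a copula experiment relating point-polyserial and polyserial
    correlations under Gauss, Frank, Clayton and Gumbel dependence; and
    k-point discrete approximations by maximal correlation, principal
    points and Golub-Welsch moment matching, with side-by-side comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
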