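#' Equal-probability maximal point-polyserial correlation, closed form
#'
#' Evaluates the family-specific closed form of the maximal correlation
#' between \code{model} and a k-category equal-probability ordinal variable
#' scored 1..k. Agrees with
#' \code{max_point_polyserial(model, equal_prob_discretization(k))} to
#' machine precision but stays cheap for very large k (the finite sums are
#' evaluated directly; R's long-double accumulator keeps them accurate up
#' to the k = 1e6 used for the limit checks).
#'
#' @param model a \code{ppc_dist} with finite variance.
#' @param k number of categories (>= 2).
#' @return the correlation, a scalar in (0, 1).
#' @examples
#' equalprob_maxcorr(make_distribution("normal"), 5)       # .9423
#' equalprob_maxcorr(make_distribution("exponential"), 10) # .8550
#' @export
equalprob_maxcorr <- function(model, k) {
  stopifnot(inherits(model, "ppc_dist"), k >= 2)
  dist_var(model)
  k <- as.numeric(k)
  sdV <- sqrt((k^2 - 1) / 12)         # sd of the discrete uniform on 1..k
  switch(model$family,
    normal = sum(stats::dnorm(stats::qnorm(seq_len(k - 1) / k))) / sdV,
    uniform = sqrt(1 - 1 / k^2),
    exponential = {
      i <- seq_len(k)[-1]
      mm <- (k * (k + 1) * (1 + log(k)) / 2 - sum(i * log(i))) / k
      (mm - (k + 1) / 2) / sdV
    },
    pareto = {
      alpha <- model$params$alpha
      i <- seq_len(k - 1)
      ec <- alpha / (alpha - 1) * (1 + sum(((k - i) / k)^((alpha - 1) / alpha)))
      (ec - alpha / (alpha - 1) * (k + 1) / 2) / (sqrt(dist_var(model)) * sdV)
    },
    logistic = {
      i <- seq_len(k - 1)
      num <- (k - 1) * log(k) - sum(i / k * log(i) + (1 - i / k) * log(k - i))
      num / (pi / sqrt(3) * sdV)
    },
    power = {
      alpha <- model$params$alpha
      i <- seq_len(k - 1)
      (k / 2 - 1 / 2 - sum((i / k)^((alpha + 1) / alpha))) *
        sqrt(alpha * (alpha + 2)) / sdV
    },
    # no special structure catalogued: fall back to the generic machinery
    max_point_polyserial(model, equal_prob_discretization(k))$rho)
}

#' Large-k limit of the equal-probability maximal correlation
#'
#' Closed-form limit, as the number of equal-probability categories grows,
#' of [equalprob_maxcorr()]:
#' uniform 1; normal \eqn{\sqrt{3/\pi}}; exponential \eqn{\sqrt{3}/2};
#' Pareto \eqn{\sqrt{3\alpha(\alpha-2)}/(2\alpha-1)} (needs alpha > 2);
#' logistic \eqn{3/\pi}; power \eqn{\sqrt{3\alpha(\alpha+2)}/(2\alpha+1)}.
#' The limit equals 1 only for the uniform (equivalently power with
#' alpha = 1): discretizing into many equal-probability cells cannot
#' resemble a non-uniform density.
#'
#' @param model a \code{ppc_dist} with finite variance.
#' @return the limit, a scalar in (0, 1].
#' @examples
#' limit_equalprob(make_distribution("normal"))          # 0.977205
#' limit_equalprob(make_distribution("pareto", alpha = 3)) # 0.6
#' @export
limit_equalprob <- function(model) {
  stopifnot(inherits(model, "ppc_dist"))
  dist_var(model)
  switch(model$family,
    uniform = 1,
    normal = sqrt(3 / pi),
    exponential = sqrt(3) / 2,
    pareto = {
      alpha <- model$params$alpha
      sqrt(3 * alpha * (alpha - 2)) / (2 * alpha - 1)
    },
    logistic = 3 / pi,
    power = {
      alpha <- model$params$alpha
      sqrt(3 * alpha * (alpha + 2)) / (2 * alpha + 1)
    },
    stop("no closed-form limit catalogued for family '", model$family, "'"))
}
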