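#' Specification of a synthetic bivariate continuous/ordinal sample
#'
#' Describes a reproducible paired sample: a continuous column drawn from
#' \code{model} and an ordinal column (category indices 1..k) obtained by
#' cutting a uniform driver at the cumulative probabilities of \code{disc}.
#' The coupling is comonotone (one shared uniform driver),
#' countermonotone (reflected driver), or linked by a parametric copula.
#' Same spec, same sample.
#'
#' @param model a \code{ppc_dist}.
#' @param disc a \code{ppc_disc} giving the ordinal category probabilities.
#' @param dependence \code{"comonotone"}, \code{"countermonotone"} or
#'   \code{"copula"}.
#' @param n sample size (>= 2).
#' @param seed integer seed.
#' @param copula a \code{ppc_copula}, required when
#'   \code{dependence = "copula"}.
#' @return list of class \code{"ppc_fixture_spec"}.
#' @export
fixture_spec <- function(model, disc, dependence = c("comonotone",
                         "countermonotone", "copula"), n, seed = 1L,
                         copula = NULL) {
  dependence <- match.arg(dependence)
  stopifnot(inherits(model, "ppc_dist"), inherits(disc, "ppc_disc"), n >= 2)
  if (dependence == "copula" && !inherits(copula, "ppc_copula"))
    stop("dependence = 'copula' needs a ppc_copula in 'copula'")
  structure(list(model = model, disc = disc, dependence = dependence,
                 n = as.integer(n), seed = as.integer(seed),
                 copula = copula),
            class = "ppc_fixture_spec")
}

# conditional-inversion / frailty samplers for the four copula families
copula_sample <- function(cop, n) {
  th <- cop$theta
  u1 <- stats::runif(n)
  switch(cop$family,
    gauss = {
      z1 <- stats::qnorm(u1)
      z2 <- th * z1 + sqrt(1 - th^2) * stats::rnorm(n)
      cbind(u1, stats::pnorm(z2))
    },
    frank = {
      w <- stats::runif(n)
      # solve h(v | u) = w in closed form
      ev <- w * expm1(-th) / (exp(-th * u1) - w * expm1(-th * u1))
      cbind(u1, -log1p(ev) / th)
    },
    clayton = {
      w <- stats::runif(n)
      cbind(u1, ((w^(-th / (1 + th)) - 1) * u1^(-th) + 1)^(-1 / th))
    },
    gumbel = {
      # positive stable frailty (Chambers-Mallows-Stuck), alpha = 1/theta
      a <- 1 / th
      if (th == 1) return(cbind(u1, stats::runif(n)))
      theta0 <- stats::runif(n, 0, pi)
      Ez <- stats::rexp(n)
      A <- (sin(a * theta0)^a * sin((1 - a) * theta0)^(1 - a) /
              sin(theta0))^(1 / (1 - a))
      S <- (A / Ez)^((1 - a) / a)
      e1 <- stats::rexp(n); e2 <- stats::rexp(n)
      cbind(exp(-(e1 / S)^a), exp(-(e2 / S)^a))
    })
}

#' Generate the paired sample described by a fixture spec
#'
#' @param spec a [fixture_spec()].
#' @return list with \code{x} (continuous, numeric n) and \code{y}
#'   (ordinal category index, integer n).
#' @examples
#' sp <- fixture_spec(make_distribution("normal"),
#'                    equal_prob_discretization(4), "comonotone",
#'                    n = 1000, seed = 42)
#' s <- generate_pair(sp)
#' cor(s$x, s$y)
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "ppc_fixture_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  k <- spec$disc$k
  cut_pts <- spec$disc$cumprobs[-k]
  if (spec$dependence == "copula") {
    uv <- copula_sample(spec$copula, spec$n)
    u <- uv[, 1]; u2 <- uv[, 2]
  } else {
    u <- stats::runif(spec$n)
    u2 <- if (spec$dependence == "comonotone") u else 1 - u
  }
  list(x = spec$model$quantile(u),
       y = findInterval(u2, cut_pts) + 1L)
}
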