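#' Analytic continuous distribution families
#'
#' Constructs a continuous distribution model exposing the density, the CDF,
#' the quantile function, the first two moments and a closed-form partial
#' moment \eqn{\int_a^b x f(x)\,dx}. These are the building blocks of every
#' correlation formula in the package: the maximal point-polyserial
#' correlation only needs quantiles (thresholds) and partial moments
#' (cell-conditional means) of the continuous law.
#'
#' Supported families (standardized forms; Pearson correlation is invariant
#' under positive affine transformation, so location-scale variants add
#' nothing):
#' \describe{
#'   \item{normal}{standard normal, no parameters.}
#'   \item{uniform}{uniform on (0,1), no parameters.}
#'   \item{exponential}{rate \code{lambda > 0} (default 1); mean 1/lambda,
#'     variance 1/lambda^2.}
#'   \item{pareto}{one-parameter Pareto on (1, Inf) with shape
#'     \code{alpha > 0}: F(x) = 1 - x^(-alpha). The mean exists only for
#'     alpha > 1, the variance only for alpha > 2.}
#'   \item{logistic}{standard logistic; mean 0, variance pi^2/3.}
#'   \item{power}{F(x) = x^alpha on (0,1), \code{alpha > 0} (a Beta(alpha, 1)
#'     law); alpha = 1 recovers the uniform.}
#'   \item{lognormal}{parameters \code{mu} (real, default 0) and
#'     \code{sigma > 0} (default 1).}
#' }
#'
#' @param family character; one of \code{"normal"}, \code{"uniform"},
#'   \code{"exponential"}, \code{"pareto"}, \code{"logistic"},
#'   \code{"power"}, \code{"lognormal"}.
#' @param ... family parameters by name (\code{lambda}, \code{alpha},
#'   \code{mu}, \code{sigma}), see Details.
#' @return An object of class \code{"ppc_dist"}: a list with elements
#'   \code{family}, \code{params}, \code{support}, and functions
#'   \code{pdf}, \code{cdf}, \code{quantile}.
#' @examples
#' m <- make_distribution("exponential", lambda = 1)
#' dist_mean(m)            # 1
#' dist_var(m)             # 1
#' partial_moment(m, 0, Inf)  # total mean, 1
#' @seealso [partial_moment()], [max_point_polyserial()]
#' @export
make_distribution <- function(family, ...) {
  family <- match.arg(family,
    c("normal", "uniform", "exponential", "pareto", "logistic", "power",
      "lognormal"))
  p <- list(...)
  # single positional unnamed parameter is accepted for the one-parameter
  # families, e.g. make_distribution("pareto", 4)
  if (length(p) == 1L && is.null(names(p)))
    names(p) <- switch(family,
      exponential = "lambda", pareto = "alpha", power = "alpha",
      stop("unnamed parameter not allowed for family '", family, "'"))
  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a positive finite number")
    v
  }
  m <- switch(family,
    normal = list(
      params = list(),
      support = c(-Inf, Inf),
      pdf = stats::dnorm, cdf = stats::pnorm, quantile = stats::qnorm,
      mu = 0, sigma2 = 1,
      antideriv = function(x) ifelse(is.finite(x), -stats::dnorm(x), 0)),
    uniform = list(
      params = list(),
      support = c(0, 1),
      pdf = function(x) stats::dunif(x), cdf = function(x) stats::punif(x),
      quantile = function(u) u,
      mu = 0.5, sigma2 = 1 / 12,
      antideriv = function(x) x^2 / 2),
    exponential = {
      lambda <- chk_pos(if (is.null(p$lambda)) 1 else p$lambda, "lambda")
      list(
        params = list(lambda = lambda),
        support = c(0, Inf),
        pdf = function(x) stats::dexp(x, lambda),
        cdf = function(x) stats::pexp(x, lambda),
        quantile = function(u) stats::qexp(u, lambda),
        mu = 1 / lambda, sigma2 = 1 / lambda^2,
        antideriv = function(x)
          ifelse(is.infinite(x), 0, -(x + 1 / lambda) * exp(-lambda * x)))
    },
    pareto = {
      alpha <- chk_pos(p$alpha, "alpha")
      list(
        params = list(alpha = alpha),
        support = c(1, Inf),
        pdf = function(x) ifelse(x >= 1, alpha / x^(alpha + 1), 0),
        cdf = function(x) ifelse(x >= 1, 1 - x^(-alpha), 0),
        quantile = function(u) (1 - u)^(-1 / alpha),
        mu = if (alpha > 1) alpha / (alpha - 1) else NULL,
        sigma2 = if (alpha > 2) alpha / ((alpha - 1)^2 * (alpha - 2))
                 else NULL,
        # alpha/(1-alpha) x^(1-alpha); -> 0 at +Inf only when alpha > 1
        antideriv = function(x)
          ifelse(is.infinite(x),
                 if (alpha > 1) 0 else Inf,
                 alpha / (1 - alpha) * x^(1 - alpha)))
    },
    logistic = list(
      params = list(),
      support = c(-Inf, Inf),
      pdf = function(x) stats::dlogis(x),
      cdf = function(x) stats::plogis(x),
      quantile = function(u) stats::qlogis(u),
      mu = 0, sigma2 = pi^2 / 3,
      # x e^x/(1+e^x) - log(1+e^x); both tails -> 0. log1p form keeps
      # large |x| stable: log(1+e^x) = max(x,0) + log1p(e^{-|x|}).
      antideriv = function(x) {
        out <- x * stats::plogis(x) - (pmax(x, 0) + log1p(exp(-abs(x))))
        out[is.infinite(x)] <- 0
        out
      }),
    power = {
      alpha <- chk_pos(p$alpha, "alpha")
      list(
        params = list(alpha = alpha),
        support = c(0, 1),
        pdf = function(x) ifelse(x > 0 & x < 1, alpha * x^(alpha - 1), 0),
        cdf = function(x) pmin(pmax(x, 0), 1)^alpha,
        quantile = function(u) u^(1 / alpha),
        mu = alpha / (alpha + 1),
        sigma2 = alpha / ((alpha + 1)^2 * (alpha + 2)),
        antideriv = function(x) alpha * x^(alpha + 1) / (alpha + 1))
    },
    lognormal = {
      mu_p <- if (is.null(p$mu)) 0 else p$mu
      sigma <- chk_pos(if (is.null(p$sigma)) 1 else p$sigma, "sigma")
      if (!is.numeric(mu_p) || !is.finite(mu_p)) stop("invalid 'mu'")
      m1 <- exp(mu_p + sigma^2 / 2)
      list(
        params = list(mu = mu_p, sigma = sigma),
        support = c(0, Inf),
        pdf = function(x) stats::dlnorm(x, mu_p, sigma),
        cdf = function(x) stats::plnorm(x, mu_p, sigma),
        quantile = function(u) stats::qlnorm(u, mu_p, sigma),
        mu = m1,
        sigma2 = (exp(sigma^2) - 1) * exp(2 * mu_p + sigma^2),
        # int_0^x t f(t) dt = E(X) Phi((log x - mu - sigma^2)/sigma)
        antideriv = function(x)
          ifelse(x <= 0, 0,
            m1 * stats::pnorm((log(pmax(x, .Machine$double.xmin)) - mu_p -
                                 sigma^2) / sigma)))
    })
  m$family <- family
  class(m) <- "ppc_dist"
  m
}

#' Parse a "family:par=value" distribution string
#'
#' Convenience parser for command-line/config use, e.g. \code{"pareto:alpha=4"},
#' \code{"exponential:lambda=1"}, \code{"lognormal:mu=0,sigma=2"} or plain
#' \code{"normal"}.
#'
#' @param spec character scalar.
#' @return a \code{ppc_dist} model, as from [make_distribution()].
#' @export
parse_distribution <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  family <- parts[1]
  args <- list()
  if (length(parts) > 1L && nzchar(parts[2])) {
    for (kv in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      kvp <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(kvp) != 2L) stop("cannot parse parameter '", kv, "'")
      args[[trimws(kvp[1])]] <- as.numeric(kvp[2])
    }
  }
  # accept 'rate' as an alias for the exponential rate
  if (!is.null(args$rate) && family == "exponential") {
    args$lambda <- args$rate; args$rate <- NULL
  }
  do.call(make_distribution, c(list(family = family), args))
}

#' @export
print.ppc_dist <- function(x, ...) {
  ps <- if (length(x$params))
    paste0("(", paste(names(x$params), unlist(x$params), sep = " = ",
                      collapse = ", "), ")")
  else ""
  cat("<ppc_dist> ", x$family, ps, "  support [",
      x$support[1], ", ", x$support[2], "]\n", sep = "")
  mu <- tryCatch(dist_mean(x), error = function(e) NA_real_)
  s2 <- tryCatch(dist_var(x), error = function(e) NA_real_)
  cat("  mean = ", format(mu), ", variance = ", format(s2), "\n", sep = "")
  invisible(x)
}

#' Expectation of a continuous model
#'
#' @param model a \code{ppc_dist}.
#' @return \eqn{E(X)}; errors if the moment does not exist (Pareto with
#'   \code{alpha <= 1}).
#' @export
dist_mean <- function(model) {
  stopifnot(inherits(model, "ppc_dist"))
  if (is.null(model$mu))
    stop("E(X) does not exist for ", model$family,
         " with these parameters (needs alpha > 1)")
  model$mu
}

#' Variance of a continuous model
#'
#' @param model a \code{ppc_dist}.
#' @return \eqn{Var(X)}; errors if the moment does not exist (Pareto with
#'   \code{alpha <= 2}).
#' @export
dist_var <- function(model) {
  stopifnot(inherits(model, "ppc_dist"))
  if (is.null(model$sigma2))
    stop("Var(X) does not exist for ", model$family,
         " with these parameters (needs alpha > 2)")
  model$sigma2
}

#' Partial moment of a continuous model
#'
#' Computes \eqn{\int_{lower}^{upper} x f(x)\,dx} through the family's
#' closed-form antiderivative. Divided by the interval probability this is
#' the conditional mean of X on the interval -- the quantity that drives
#' both the comonotonic mixed moment and the optimal (OPT) scores.
#'
#' @param model a \code{ppc_dist}.
#' @param lower,upper interval endpoints; \code{-Inf}/\code{Inf} sentinels
#'   are clamped to the support. Must satisfy \code{lower <= upper} and
#'   intersect the support.
#' @return the partial moment, a scalar.
#' @examples
#' partial_moment(make_distribution("uniform"), 0, 0.5)  # 0.125
#' partial_moment(make_distribution("normal"), -Inf, 0)  # -1/sqrt(2*pi)
#' @export
partial_moment <- function(model, lower, upper) {
  stopifnot(inherits(model, "ppc_dist"),
            is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (is.na(lower) || is.na(upper) || lower > upper)
    stop("need lower <= upper")
  s <- model$support
  if (upper < s[1] || lower > s[2])
    stop("interval [", lower, ", ", upper, "] lies outside the support [",
         s[1], ", ", s[2], "]")
  lo <- max(lower, s[1]); hi <- min(upper, s[2])
  model$antideriv(hi) - model$antideriv(lo)
}

#' Numeric-quadrature partial moment (cross-validation fallback)
#'
#' Adaptive quadrature counterpart of [partial_moment()]; used only to
#' cross-check the closed forms, never on the hot path.
#'
#' @inheritParams partial_moment
#' @param abs.tol absolute tolerance passed to [stats::integrate()].
#' @return the partial moment, a scalar.
#' @export
partial_moment_numeric <- function(model, lower, upper, abs.tol = 1e-10) {
  stopifnot(inherits(model, "ppc_dist"))
  s <- model$support
  lo <- max(lower, s[1]); hi <- min(upper, s[2])
  if (lo >= hi) return(0)
  stats::integrate(function(x) x * model$pdf(x), lo, hi,
                   abs.tol = abs.tol, rel.tol = 1e-12,
                   subdivisions = 500L)$value
}
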