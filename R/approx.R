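#' Raw moment of a continuous model
#'
#' \eqn{E(X^n)} via closed form where the family has one (normal, uniform,
#' exponential, power, Pareto, logistic, lognormal); errors when the moment
#' does not exist.
#'
#' @param model a \code{ppc_dist}.
#' @param n nonnegative integer order.
#' @return the raw moment.
#' @export
dist_moment <- function(model, n) {
  stopifnot(inherits(model, "ppc_dist"), n >= 0, n == round(n))
  if (n == 0) return(1)
  switch(model$family,
    normal = if (n %% 2 == 1) 0 else prod(seq(1, n - 1, by = 2)),
    uniform = 1 / (n + 1),
    exponential = factorial(n) / model$params$lambda^n,
    power = model$params$alpha / (model$params$alpha + n),
    pareto = {
      alpha <- model$params$alpha
      if (n >= alpha)
        stop("E(X^", n, ") does not exist for Pareto alpha = ", alpha)
      alpha / (alpha - n)
    },
    logistic = {
      if (n %% 2 == 1) return(0)
      # E(X^{2m}) = (2^{2m} - 2) pi^{2m} |B_{2m}| (Bernoulli numbers)
      B <- c(1 / 6, 1 / 30, 1 / 42, 1 / 30, 5 / 66, 691 / 2730, 7 / 6,
             3617 / 510, 43867 / 798, 174611 / 330, 854513 / 138,
             236364091 / 2730)
      m <- n / 2
      if (m > length(B)) stop("logistic moments implemented up to order 24")
      (2^n - 2) * pi^n * B[m]
    },
    lognormal = exp(n * model$params$mu + n^2 * model$params$sigma^2 / 2))
}

# Chebyshev algorithm: recurrence coefficients (alpha_j, beta_j) of the
# monic orthogonal polynomials from raw moments m_0..m_{2k-1}. Returns the
# Jacobi matrix inputs for golub_welsch. Double precision: notoriously
# ill-conditioned, so breakdown (beta <= 0 or non-finite) is an error.
chebyshev_recurrence <- function(mom, k) {
  stopifnot(length(mom) >= 2 * k)
  alpha <- numeric(k); beta <- numeric(k)
  sig_prev <- rep(0, 2 * k + 1)            # sigma_{-1, l}
  sig <- mom[seq_len(2 * k)]               # sigma_{0, l} = m_l, l = 0..2k-1
  alpha[1] <- mom[2] / mom[1]
  beta[1] <- mom[1]
  if (k > 1) {
    for (j in seq_len(k - 1)) {            # build sigma_{j, l}
      ln <- j:(2 * k - j - 1)              # l indices (0-based) kept
      sig_new <- numeric(2 * k)
      for (l in ln) {
        sig_new[l + 1] <- sig[l + 2] - alpha[j] * sig[l + 1] -
          beta[j] * sig_prev[l + 1]
      }
      a <- sig_new[j + 2] / sig_new[j + 1] - sig[j + 1] / sig[j]
      b <- sig_new[j + 1] / sig[j]
      if (!is.finite(a) || !is.finite(b) || b <= 0)
        stop("moment-matrix breakdown in double precision; reduce k")
      alpha[j + 1] <- a; beta[j + 1] <- b
      sig_prev <- sig; sig <- sig_new
    }
  }
  list(a = alpha, b = sqrt(beta[-1]))
}

#' Moment-matching k-point approximation (Gaussian quadrature rule)
#'
#' The unique k-point discrete law matching the first 2k-1 raw moments of
#' \code{model}: the Gaussian quadrature rule with the model's density as
#' weight function, obtained by eigen-decomposition of the Jacobi matrix
#' (Golub-Welsch). Normal, uniform and exponential use their exact
#' closed-form recurrence coefficients (Hermite / shifted Legendre /
#' Laguerre); other families go through the Chebyshev algorithm on exact
#' raw moments, which in double precision is reliable only up to k = 12
#' (errors beyond, or on breakdown).
#'
#' @param model a \code{ppc_dist}; moments up to order 2k must exist
#'   (Pareto needs alpha > 2k).
#' @param k number of points (>= 1).
#' @return a [discretization()] with the quadrature nodes and weights.
#' @examples
#' moment_match(make_distribution("uniform"), 2)  # 1/2 -/+ 1/(2 sqrt(3))
#' @export
moment_match <- function(model, k) {
  stopifnot(inherits(model, "ppc_dist"), k >= 1, k == round(k))
  if (model$family == "pareto" && model$params$alpha <= 2 * k)
    stop("Pareto moments up to order ", 2 * k, " require alpha > ", 2 * k)
  rec <- switch(model$family,
    normal = list(a = rep(0, k), b = sqrt(seq_len(max(k - 1, 0)))),
    uniform = {
      j <- seq_len(max(k - 1, 0))
      list(a = rep(0.5, k), b = j / (2 * sqrt(4 * j^2 - 1)))
    },
    exponential = {
      lam <- model$params$lambda
      list(a = (2 * seq_len(k) - 1) / lam, b = seq_len(max(k - 1, 0)) / lam)
    },
    {
      if (k > 12)
        stop("moment matching via the Chebyshev algorithm is capped at ",
             "k = 12 (double-precision conditioning)")
      mom <- vapply(0:(2 * k - 1), function(n) dist_moment(model, n),
                    numeric(1))
      chebyshev_recurrence(c(1, mom[-1]), k)
    })
  gw <- golub_welsch(rec$a, rec$b)
  if (k == 1)
    return(structure(list(values = gw$nodes, probs = 1, cumprobs = 1, k = 1L),
                     class = "ppc_disc"))
  discretization(gw$nodes, gw$weights / sum(gw$weights))
}

#' Moment-standardized CIS maximal-correlation approximation
#'
#' Takes the CIS optimum of [maximize_cis()] and maps the scores 1..k
#' affinely so the discrete mean and variance equal those of \code{model};
#' the correlation with X is untouched (affine invariance) and the result
#' is usable as a k-point approximation of the continuous law.
#'
#' @inheritParams maximize_cis
#' @return a [discretization()] with matched first two moments.
#' @export
standardized_cis_approx <- function(model, k, settings = opt_settings()) {
  r <- maximize_cis(model, k, settings)
  p <- r$disc$probs
  E <- disc_mean(r$disc); V <- disc_var(r$disc)
  y <- dist_mean(model) + sqrt(dist_var(model)) * (seq_len(k) - E) / sqrt(V)
  discretization(y, p)
}

#' Side-by-side k-point approximations of a continuous law
#'
#' Assembles the three approximations discussed in this package --
#' moment-standardized CIS maximal correlation, principal points
#' (OPT/Lloyd), and Golub-Welsch moment matching -- with per-method
#' summaries (mean, variance, MSE, number of exactly matched moments) and
#' step-CDF coordinates for plotting against the continuous CDF.
#'
#' @inheritParams maximize_cis
#' @return object of class \code{"ppc_approx_table"}: list with
#'   \code{model}, \code{k}, \code{methods} (named list of
#'   discretizations), \code{summaries} (data.frame), \code{step_cdf}
#'   (named list of data.frames with columns x, F).
#' @export
compare_approximations <- function(model, k, settings = opt_settings()) {
  methods <- list(
    maxcorr_cis = standardized_cis_approx(model, k, settings),
    maxcorr_opt = maximize_opt(model, k, settings)$disc,
    moment_match = moment_match(model, k))
  summaries <- do.call(rbind, lapply(names(methods), function(nm) {
    d <- methods[[nm]]
    data.frame(method = nm, mean = disc_mean(d), variance = disc_var(d),
               mse = mse(model, d),
               moments_matched = switch(nm, maxcorr_cis = 2L,
                                        maxcorr_opt = 1L,
                                        moment_match = 2L * k - 1L))
  }))
  step_cdf <- lapply(methods, function(d)
    data.frame(x = d$values, F = d$cumprobs))
  structure(list(model = model, k = k, methods = methods,
                 summaries = summaries, step_cdf = step_cdf),
            class = "ppc_approx_table")
}

#' @export
print.ppc_approx_table <- function(x, ...) {
  cat("<ppc_approx_table>", x$model$family, " k =", x$k, "\n")
  tab <- data.frame(lapply(x$methods, function(d)
    c(rbind(round(d$values, 3), round(d$probs, 4)))))
  rn <- c(rbind(paste0("value_", seq_len(x$k)), paste0("prob_", seq_len(x$k))))
  rownames(tab) <- rn
  print(tab)
  cat("\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}
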