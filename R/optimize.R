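#' Optimization settings
#'
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap per optimizer stage.
#' @param multistart number of jittered restarts (>= 1) for the simplex
#'   search; the best objective wins.
#' @param seed integer seed for the multistart jitter (ignored when
#'   \code{multistart == 1}).
#' @return list of class \code{"ppc_opt_settings"}.
#' @export
opt_settings <- function(tol = 1e-10, max_iter = 10000L, multistart = 1L,
                         seed = 1L) {
  stopifnot(tol > 0, max_iter >= 1, multistart >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 multistart = as.integer(multistart),
                 seed = as.integer(seed)),
            class = "ppc_opt_settings")
}

# objective: maximal point-polyserial correlation on CIS scores for probs p.
# p entries below eps are clipped so quantiles stay finite.
cis_rho <- function(model, p) {
  p <- pmax(p, 0); p <- p / sum(p)
  d <- tryCatch(discretization(seq_along(p), pmax(p, 1e-12) / sum(pmax(p, 1e-12))),
                error = function(e) NULL)
  if (is.null(d)) return(NA_real_)
  max_point_polyserial(model, d)$rho
}

# probabilities induced by equally spaced cut points a + b*(i + 1/2)
ab_probs <- function(model, k, a, b) {
  cuts <- a + b * (seq_len(k - 1L) + 0.5)
  Fi <- model$cdf(cuts)
  diff(c(0, pmin(pmax(Fi, 0), 1), 1))
}

# stage-1 search over the Proposition-2 (shift, scale) parametrization
solve_ab <- function(model, k, settings) {
  qf <- model$quantile
  obj <- function(th) {
    p <- ab_probs(model, k, th[1], exp(th[2]))
    if (sum(p > 1e-9) < 2) return(0)  # degenerate: rho ~ 0
    -cis_rho(model, p)
  }
  # initialize by regressing equal-probability quantiles on cut indices
  eps <- 1e-9
  qs <- qf(pmin(pmax(seq_len(k - 1L) / k, eps), 1 - eps))
  idx <- seq_len(k - 1L) + 0.5
  b0 <- if (k > 2) stats::cov(qs, idx) / stats::var(idx)
        else max(diff(range(qs)), 0.1) + 0.5
  b0 <- max(b0, 1e-6)
  a0 <- mean(qs) - b0 * mean(idx)
  r1 <- stats::optim(c(a0, log(b0)), obj, method = "Nelder-Mead",
                     control = list(maxit = settings$max_iter,
                                    reltol = settings$tol * 1e-3))
  r2 <- stats::optim(r1$par, obj, method = "BFGS",
                     control = list(maxit = settings$max_iter,
                                    reltol = settings$tol * 1e-3))
  best <- if (r2$value <= r1$value) r2 else r1
  list(a = best$par[1], b = exp(best$par[2]), rho = -best$value,
       probs = ab_probs(model, k, best$par[1], exp(best$par[2])),
       iters = sum(r1$counts[1], r2$counts[1], na.rm = TRUE),
       converged = best$convergence == 0)
}

# stage-2 polish: BFGS on softmax(z), z in R^{k-1} (first logit pinned at 0)
polish_simplex <- function(model, p0, settings) {
  k <- length(p0)
  z0 <- log(pmax(p0, 1e-9))
  z0 <- (z0 - z0[1])[-1]
  obj <- function(z) {
    z <- pmin(pmax(z, -40), 40)
    p <- exp(c(0, z)); p <- p / sum(p)
    -cis_rho(model, p)
  }
  r <- stats::optim(z0, obj, method = "BFGS",
                    control = list(maxit = settings$max_iter,
                                   reltol = settings$tol * 1e-4))
  p <- exp(c(0, pmin(pmax(r$par, -40), 40)))
  list(probs = p / sum(p), rho = -r$value, iters = unname(r$counts[1]),
       converged = r$convergence == 0)
}

#' Maximum point-polyserial correlation over category probabilities (CIS)
#'
#' Solves the CIS problem: maximize the maximal point-polyserial
#' correlation between \code{model} and a k-category ordinal variable with
#' consecutive integer scores 1..k over the probability simplex. The search
#' runs in two stages: a 2-parameter shift/scale search over equally spaced
#' thresholds (exactly the structure the optimum must have -- see
#' [threshold_spacing()]), then a quasi-Newton polish over softmax-encoded
#' probabilities; optional jittered multistarts guard against local optima.
#'
#' @param model a \code{ppc_dist} with finite variance.
#' @param k number of categories (>= 2).
#' @param settings an [opt_settings()] list.
#' @return a \code{"ppc_maxcorr"} with the optimal probabilities on scores
#'   1..k and optimizer diagnostics.
#' @examples
#' maximize_cis(make_distribution("uniform"), 4)$rho  # sqrt(1 - 1/16)
#' @export
maximize_cis <- function(model, k, settings = opt_settings()) {
  stopifnot(inherits(model, "ppc_dist"), k >= 2)
  dist_var(model)
  s1 <- solve_ab(model, k, settings)
  cand <- list(polish_simplex(model, s1$probs, settings))
  if (settings$multistart > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(settings$seed)
    for (m in seq_len(settings$multistart - 1L)) {
      g <- stats::rexp(k)                       # Dirichlet(1) start
      cand[[m + 1L]] <- polish_simplex(model, g / sum(g), settings)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  best <- cand[[which.max(vapply(cand, `[[`, 0, "rho"))]]
  if (!best$converged && !s1$converged)
    stop("CIS optimization failed to converge after ", settings$max_iter,
         " iterations in every start")
  p <- pmax(best$probs, 1e-12); p <- p / sum(p)
  d <- discretization(seq_len(k), p)
  res <- max_point_polyserial(model, d)
  res$diagnostics <- list(method = "ab+softmax-bfgs", iterations = best$iters,
                          converged = best$converged,
                          starts = settings$multistart)
  res
}

#' CIS maximization in the two-variable shift/scale form
#'
#' Equivalent restatement of the CIS problem: the optimal thresholds are
#' equally spaced on the scale of X, so it suffices to search over a shift
#' a and a scale b > 0 defining cut points \eqn{c_i = a + b(i + 1/2)},
#' with probabilities \eqn{p_i = F(c_i) - F(c_{i-1})}. Agrees with
#' [maximize_cis()] on the objective and (to ~1e-4) on each probability.
#'
#' @inheritParams maximize_cis
#' @return a \code{"ppc_maxcorr"}; diagnostics carry the optimal
#'   \code{a} and \code{b}.
#' @export
maximize_cis_ab <- function(model, k, settings = opt_settings()) {
  stopifnot(inherits(model, "ppc_dist"), k >= 2)
  dist_var(model)
  s <- solve_ab(model, k, settings)
  if (!s$converged)
    stop("(a,b) optimization failed to converge after ", settings$max_iter,
         " iterations")
  p <- pmax(s$probs, 1e-12); p <- p / sum(p)
  d <- discretization(seq_len(k), p)
  res <- max_point_polyserial(model, d)
  res$diagnostics <- list(method = "ab", a = s$a, b = s$b,
                          iterations = s$iters, converged = s$converged)
  res
}

#' Spacing of the thresholds induced on the continuous scale
#'
#' Differences \eqn{F^{-1}(F_{i+1}) - F^{-1}(F_i)}, i = 1..k-2, of the
#' thresholds a discretization marks on X. At a CIS optimum with k >= 4
#' these are constant (equal to covariance/variance of the optimal
#' discrete law), the stationarity structure of the CIS problem.
#'
#' @param model a \code{ppc_dist}.
#' @param disc a \code{ppc_disc} with k >= 3.
#' @return numeric vector of k-2 spacings.
#' @export
threshold_spacing <- function(model, disc) {
  stopifnot(inherits(model, "ppc_dist"), inherits(disc, "ppc_disc"),
            disc$k >= 3)
  thr <- model$quantile(pmin(pmax(disc$cumprobs[-disc$k], 0), 1))
  diff(thr)
}

#' Principal points / optimal quantizer via Lloyd's algorithm (OPT)
#'
#' Solves the free-support problem: maximize the correlation over both
#' probabilities and support values. The fixed point alternates (i) support
#' values = conditional means of X over their cells and (ii) cut points =
#' midpoints of consecutive support values; this is Lloyd's algorithm and
#' its solution is the set of k principal points, minimizing the mean
#' squared quantization error. The achieved correlation is
#' \eqn{\sqrt{Var(X_d)}/\sigma = \sqrt{1 - MSE/\sigma^2}}.
#'
#' @inheritParams maximize_cis
#' @return a \code{"ppc_maxcorr"} whose discretization holds the principal
#'   points and their probabilities.
#' @examples
#' r <- maximize_opt(make_distribution("normal"), 7)
#' round(r$disc$values, 3)   # 0, +/-0.561, +/-1.188, +/-2.033
#' @export
maximize_opt <- function(model, k, settings = opt_settings()) {
  stopifnot(inherits(model, "ppc_dist"), k >= 2)
  s2 <- dist_var(model)
  x <- model$quantile((seq_len(k) - 0.5) / k)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    cuts <- (x[-1] + x[-k]) / 2
    lo <- c(model$support[1], cuts)
    hi <- c(cuts, model$support[2])
    p <- model$cdf(hi) - model$cdf(lo)
    xn <- vapply(seq_len(k), function(i)
      partial_moment(model, lo[i], hi[i]) / p[i], numeric(1))
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < 1e-12) break
    if (iters >= settings$max_iter)
      stop("Lloyd iteration did not converge after ", iters,
           " sweeps (last change ", format(delta), ")")
  }
  diag_list <- list(method = "lloyd", iterations = iters, converged = TRUE)
  if (min(p) < 1e-12)
    diag_list$warning <- "tail cell probability at numerical resolution"
  d <- discretization(x, p)
  res <- max_point_polyserial(model, d)
  res$diagnostics <- diag_list
  res
}

#' Mean squared quantization error of a discretization
#'
#' Expected squared distance between X and the nearest support value using
#' midpoint cut cells:
#' \eqn{\sum_i \int_{c_{i-1}}^{c_i} (x - x_i)^2 f(x) dx}, expanded as
#' \eqn{E(X^2) - 2\sum_i x_i m_i + \sum_i x_i^2 p_i} with cell partial
#' moments \eqn{m_i}. At a Lloyd fixed point
#' \eqn{Var(X_d) = \sigma^2 - MSE}.
#'
#' @param model a \code{ppc_dist} with finite variance.
#' @param disc a \code{ppc_disc} (its probabilities are ignored; the cells
#'   are rebuilt from midpoints of \code{disc$values}).
#' @return the MSE, a scalar >= 0.
#' @export
mse <- function(model, disc) {
  stopifnot(inherits(model, "ppc_dist"), inherits(disc, "ppc_disc"))
  x <- disc$values; k <- disc$k
  cuts <- (x[-1] + x[-k]) / 2
  lo <- c(model$support[1], cuts)
  hi <- c(cuts, model$support[2])
  p <- model$cdf(hi) - model$cdf(lo)
  m <- vapply(seq_len(k), function(i)
    partial_moment(model, lo[i], hi[i]), numeric(1))
  ex2 <- dist_var(model) + dist_mean(model)^2
  ex2 - 2 * sum(x * m) + sum(x^2 * p)
}
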