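#' Comonotonic mixed moment E_c(X * X_d)
#'
#' The mixed moment of a continuous variable X and a discretization X_d when
#' the two are comonotonic (coupled by the upper Frechet bound). Cell i of
#' X_d occupies the quantile band (F^{-1}(F_{i-1}), F^{-1}(F_i)] of X, so
#' \deqn{E_c(X X_d) = \sum_i x_i \int_{F^{-1}(F_{i-1})}^{F^{-1}(F_i)}
#'   x f(x) dx,}
#' evaluated with the family's closed-form partial moments. Cells with
#' probability below 1e-12 are skipped (the closed-form limit of 0 log 0).
#'
#' @param model a \code{ppc_dist} with existing mean.
#' @param disc a \code{ppc_disc}.
#' @return the mixed moment, a scalar.
#' @export
comonotonic_mixed_moment <- function(model, disc) {
  stopifnot(inherits(model, "ppc_dist"), inherits(disc, "ppc_disc"))
  dist_mean(model)  # errors early if E(X) does not exist
  Fi <- pmin(pmax(disc$cumprobs, 0), 1)
  Fi[disc$k] <- 1
  qs <- c(model$support[1], model$quantile(Fi[-disc$k]), model$support[2])
  keep <- disc$probs > 1e-12
  cells <- vapply(seq_len(disc$k), function(i) {
    if (!keep[i]) return(0)
    partial_moment(model, qs[i], qs[i + 1])
  }, numeric(1))
  sum(disc$values * cells)
}

ppc_maxcorr_result <- function(rho, disc, model, mixed_moment,
                               diagnostics = list()) {
  Fi <- disc$cumprobs
  thr <- model$quantile(pmin(pmax(Fi[-disc$k], 0), 1))
  structure(list(rho = rho, disc = disc, thresholds = thr,
                 mixed_moment = mixed_moment,
                 covariance = mixed_moment - dist_mean(model) * disc_mean(disc),
                 diagnostics = diagnostics),
            class = "ppc_maxcorr")
}

#' @export
print.ppc_maxcorr <- function(x, ...) {
  cat("<ppc_maxcorr> rho_PP,max =", format(x$rho, digits = 8), "\n")
  cat("  k =", x$disc$k, " values:", format(x$disc$values, digits = 4), "\n")
  cat("  probs:", format(round(x$disc$probs, 4), nsmall = 4), "\n")
  cat("  thresholds on X:", format(x$thresholds, digits = 4), "\n")
  if (length(x$diagnostics))
    cat("  diagnostics:", paste(names(x$diagnostics),
        vapply(x$diagnostics, function(d) paste(format(d), collapse = ","),
               ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Maximal point-polyserial correlation for a given discretization
#'
#' The largest Pearson correlation attainable between X and X_d over all
#' joint couplings with these margins -- attained under comonotonicity:
#' \deqn{\rho_{PP,max} = (E_c(X X_d) - \mu E(X_d)) / (\sigma \sqrt{V(X_d)}).}
#'
#' @param model a \code{ppc_dist} with finite variance.
#' @param disc a \code{ppc_disc} with positive variance.
#' @return a \code{"ppc_maxcorr"} object: \code{rho}, the discretization,
#'   the induced thresholds on the scale of X, the mixed moment and the
#'   covariance.
#' @examples
#' m <- make_distribution("normal")
#' max_point_polyserial(m, equal_prob_discretization(2))$rho  # 2*dnorm(0)
#' @export
max_point_polyserial <- function(model, disc) {
  stopifnot(inherits(model, "ppc_dist"), inherits(disc, "ppc_disc"))
  V <- disc_var(disc)
  if (V <= 0) stop("discretization has zero variance")
  s2 <- dist_var(model)
  mm <- comonotonic_mixed_moment(model, disc)
  rho <- (mm - dist_mean(model) * disc_mean(disc)) / (sqrt(s2) * sqrt(V))
  ppc_maxcorr_result(rho, disc, model, mm)
}

#' Optimal (OPT) scores for given category probabilities
#'
#' For fixed probabilities the support values maximizing the correlation
#' with X are the cell-conditional means
#' \eqn{x_i^* = \int_{F^{-1}(F_{i-1})}^{F^{-1}(F_i)} x f(x) dx / p_i}
#' (or any positive affine map of them). The resulting discrete variable
#' preserves E(X) but its variance is below Var(X).
#'
#' @param model a \code{ppc_dist}.
#' @param probs probability vector, all entries strictly positive.
#' @return numeric vector of k optimal scores (strictly increasing).
#' @examples
#' optimal_scores(make_distribution("uniform"), rep(0.2, 5)) # (2i-1)/10
#' @export
optimal_scores <- function(model, probs) {
  stopifnot(inherits(model, "ppc_dist"), is.numeric(probs), length(probs) >= 2)
  if (any(probs <= 0))
    stop("all probabilities must be positive (an empty cell has no ",
         "conditional mean)")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1")
  k <- length(probs)
  Fi <- cumsum(probs); Fi[k] <- 1
  qs <- c(model$support[1], model$quantile(Fi[-k]), model$support[2])
  vapply(seq_len(k), function(i)
    partial_moment(model, qs[i], qs[i + 1]) / probs[i], numeric(1))
}

#' Correlation achieved by the optimal scores
#'
#' With the optimal scores in place the maximal correlation collapses to
#' \eqn{\sqrt{Var(X_d)}/\sigma}; this route and
#' [max_point_polyserial()] on the optimal-score discretization agree to
#' machine precision, which the test-suite asserts.
#'
#' @inheritParams optimal_scores
#' @return the correlation, in (0, 1).
#' @export
corr_with_optimal_scores <- function(model, probs) {
  xs <- optimal_scores(model, probs)
  d <- discretization(xs, probs)
  sqrt(disc_var(d) / dist_var(model))
}

#' Normal biserial ratio (Pearson's dichotomization formula)
#'
#' Ratio of point-biserial to biserial correlation when a standard normal
#' variable is cut at \code{omega}:
#' \eqn{\phi(\omega)/\sqrt{p(\omega) q(\omega)}} with
#' \eqn{p(\omega) = 1 - \Phi(\omega)}. Symmetric in omega with maximum
#' \eqn{2\phi(0) \approx .7979} at 0; vanishes in the tails.
#'
#' @param omega cut point(s), finite numeric.
#' @return the ratio, vectorized over \code{omega}.
#' @export
biserial_ratio_normal <- function(omega) {
  stopifnot(is.numeric(omega), all(is.finite(omega)))
  p <- stats::pnorm(omega, lower.tail = FALSE)
  q <- 1 - p
  out <- stats::dnorm(omega) / sqrt(p * q)
  out[p * q == 0] <- 0
  out
}

#' Normal point-polyserial ratio for arbitrary category probabilities
#'
#' For a bivariate normal pair with one component discretized into k
#' categories with probabilities \code{probs} (consecutive integer scores),
#' the point-polyserial to polyserial ratio is
#' \deqn{\sum_i \phi(\Phi^{-1}(F_i)) / \sqrt{\sum i^2 p_i - (\sum i p_i)^2},}
#' which equals the maximal point-polyserial correlation of the standard
#' normal with that discretization.
#'
#' @param probs probability vector (nonnegative, sums to 1); needs at least
#'   two categories with positive mass.
#' @return the ratio, a scalar in (0, 1).
#' @examples
#' normal_ratio(rep(1/3, 3))   # .8906
#' @export
normal_ratio <- function(probs) {
  stopifnot(is.numeric(probs), length(probs) >= 2)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("invalid probability vector")
  k <- length(probs)
  i <- seq_len(k)
  V <- sum(i^2 * probs) - sum(i * probs)^2
  if (V <= 0) stop("degenerate probabilities: zero variance")
  Fi <- pmin(cumsum(probs)[-k], 1)
  sum(stats::dnorm(stats::qnorm(Fi))) / sqrt(V)
}

#' Attainable correlation bounds for two continuous laws
#'
#' The Frechet-Hoeffding bounds for Pearson's correlation given the two
#' margins: \eqn{\rho_{max} = cor(F_1^{-1}(U), F_2^{-1}(U))} (comonotonic)
#' and \eqn{\rho_{min} = cor(F_1^{-1}(U), F_2^{-1}(1-U))} (countermonotonic),
#' computed by 2048-node Gauss-Legendre quadrature on (0,1). A
#' lognormal-lognormal pair with mu1 = mu2 = 0 and sigma1 = 1 uses the
#' closed forms \eqn{(e^{\pm\sigma_2} - 1)/\sqrt{(e-1)(e^{\sigma_2^2}-1)}}.
#'
#' @param model1,model2 \code{ppc_dist} objects with finite variance.
#' @param nodes quadrature size (default 2048).
#' @return named numeric vector \code{c(rho_min, rho_max)}.
#' @examples
#' attainable_bounds(make_distribution("lognormal", sigma = 1),
#'                   make_distribution("lognormal", sigma = 2))
#' @export
attainable_bounds <- function(model1, model2, nodes = 2048L) {
  stopifnot(inherits(model1, "ppc_dist"), inherits(model2, "ppc_dist"))
  s1 <- dist_var(model1); s2 <- dist_var(model2)
  if (identical(model1$family, model2$family) &&
      identical(model1$params, model2$params)) {
    # same type: the comonotonic bound is exactly 1
    rho_max <- 1
    rho_min <- attainable_quad(model1, model2, nodes)["rho_min"]
    return(c(rho_min = unname(rho_min), rho_max = rho_max))
  }
  if (model1$family == "lognormal" && model2$family == "lognormal" &&
      model1$params$mu == 0 && model2$params$mu == 0 &&
      model1$params$sigma == 1) {
    sg <- model2$params$sigma
    den <- sqrt((exp(1) - 1) * (exp(sg^2) - 1))
    return(c(rho_min = (exp(-sg) - 1) / den, rho_max = (exp(sg) - 1) / den))
  }
  attainable_quad(model1, model2, nodes)
}

attainable_quad <- function(model1, model2, nodes) {
  g <- graded_gl_grid(nodes)      # on (0,1), tail-graded
  x <- model1$quantile(g$x)
  y <- model2$quantile(g$x)
  m1 <- dist_mean(model1); m2 <- dist_mean(model2)
  s1 <- sqrt(dist_var(model1)); s2 <- sqrt(dist_var(model2))
  rho_max <- (sum(g$w * x * y) - m1 * m2) / (s1 * s2)
  # countermonotone coupling: pair the u-quantile of X with the (1-u)-
  # quantile of Y; the product decays in both tails, so the loss of
  # relative precision in 1-u near 1 is harmless
  u_rev <- pmin(1 - g$x, 1 - 2^-53)   # keep strictly inside (0, 1)
  y_rev <- model2$quantile(u_rev)
  rho_min <- (sum(g$w * x * y_rev) - m1 * m2) / (s1 * s2)
  c(rho_min = min(rho_min, 1), rho_max = min(rho_max, 1))
}

#' Empirical maximal correlation by sorting (comonotonic rearrangement)
#'
#' Pearson correlation of the two samples sorted in ascending order -- the
#' sample analogue of the comonotonic coupling, and an upper bound for the
#' correlation of any reordering of the pairs (rearrangement inequality).
#'
#' @param sample_x,sample_y numeric vectors of equal length n >= 2, neither
#'   constant.
#' @return the sorted-sample Pearson correlation.
#' @export
empirical_max_corr <- function(sample_x, sample_y) {
  stopifnot(is.numeric(sample_x), is.numeric(sample_y),
            length(sample_x) == length(sample_y), length(sample_x) >= 2)
  if (stats::sd(sample_x) == 0 || stats::sd(sample_y) == 0)
    stop("correlation undefined for a constant sample")
  stats::cor(sort(sample_x, method = "radix"),
             sort(sample_y, method = "radix"))
}
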