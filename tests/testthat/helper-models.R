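# The six families the correlation tables cover, at the parameter values
# used throughout, plus a quadrature mixed-moment oracle independent of the
# closed-form partial moments.

six_families <- function() {
  list(
    normal = make_distribution("normal"),
    uniform = make_distribution("uniform"),
    exponential = make_distribution("exponential", lambda = 1),
    pareto = make_distribution("pareto", alpha = 4),
    logistic = make_distribution("logistic"),
    power = make_distribution("power", alpha = 2))
}

# oracle: E_c(X X_d) by per-cell adaptive quadrature of x f(x)
quad_mixed_moment <- function(model, disc) {
  Fi <- disc$cumprobs
  qs <- c(model$support[1], model$quantile(Fi[-disc$k]), model$support[2])
  sum(disc$values * vapply(seq_len(disc$k), function(i) {
    if (disc$probs[i] < 1e-12) return(0)
    partial_moment_numeric(model, qs[i], qs[i + 1])
  }, numeric(1)))
}

# oracle: maximal correlation from the quadrature mixed moment
quad_rho <- function(model, disc) {
  (quad_mixed_moment(model, disc) - dist_mean(model) * disc_mean(disc)) /
    sqrt(dist_var(model) * disc_var(disc))
}

random_probs <- function(k) {
  p <- stats::rexp(k)
  p / sum(p)
}
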