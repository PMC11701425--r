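test_that("comonotonic mixed moment: direct integrals and quadrature oracle", {
  un <- make_distribution("uniform")
  d2 <- equal_prob_discretization(2)
  # 1 * int_0^.5 x dx + 2 * int_.5^1 x dx
  expect_equal(comonotonic_mixed_moment(un, d2), 0.875)

  ex <- make_distribution("exponential")
  for (k in c(2, 4, 7)) {
    d <- equal_prob_discretization(k)
    i <- seq_len(k)[-1]
    closed <- (k * (k + 1) * (1 + log(k)) / 2 - sum(i * log(i))) / k
    expect_equal(comonotonic_mixed_moment(ex, d), closed, tolerance = 1e-12)
    expect_equal(comonotonic_mixed_moment(ex, d), quad_mixed_moment(ex, d),
                 tolerance = 1e-8)
  }

  no <- make_distribution("normal")
  # k = 2 halves: 1 * (-phi(0)) + 2 * phi(0) = phi(0)
  expect_equal(comonotonic_mixed_moment(no, d2), stats::dnorm(0))
})

test_that("maximal point-polyserial correlation matches the printed anchors", {
  expect_equal(round(max_point_polyserial(make_distribution("normal"),
                                          equal_prob_discretization(2))$rho,
                     4), 0.7979)
  expect_equal(max_point_polyserial(make_distribution("uniform"),
                                    equal_prob_discretization(10))$rho,
               sqrt(1 - 1 / 100), tolerance = 1e-12)
  expect_equal(round(max_point_polyserial(make_distribution("exponential"),
                                          equal_prob_discretization(2))$rho,
                     4), 0.6931)
})

test_that("maximal correlation result is internally consistent", {
  m <- make_distribution("logistic")
  d <- discretization(1:4, c(0.1, 0.4, 0.3, 0.2))
  r <- max_point_polyserial(m, d)
  expect_true(r$rho > 0 && r$rho < 1)
  expect_true(all(diff(r$thresholds) > 0))
  expect_equal(r$covariance,
               r$rho * sqrt(dist_var(m)) * sqrt(disc_var(d)),
               tolerance = 1e-8)
  expect_error(max_point_polyserial(
    make_distribution("pareto", alpha = 1.5), d), "does not exist")
})

test_that("rho in (0,1) and equals the quadrature oracle across families", {
  set.seed(31)
  for (m in six_families()) {
    for (k in c(2, 3, 6)) {
      d <- discretization(seq_len(k), random_probs(k))
      r <- max_point_polyserial(m, d)
      expect_true(r$rho > 0 && r$rho < 1, info = m$family)
      expect_equal(r$rho, quad_rho(m, d), tolerance = 1e-8, info = m$family)
    }
  }
})

test_that("optimal scores are the cell-conditional means", {
  expect_equal(optimal_scores(make_distribution("normal"), c(0.5, 0.5)),
               c(-1, 1) * stats::dnorm(0) / 0.5, tolerance = 1e-12)
  expect_equal(optimal_scores(make_distribution("uniform"), rep(0.2, 5)),
               c(0.1, 0.3, 0.5, 0.7, 0.9), tolerance = 1e-12)
  ex <- make_distribution("exponential")
  p <- rep(1 / 3, 3)
  qs <- c(0, stats::qexp(cumsum(p)[-3]), Inf)
  oracle <- vapply(1:3, function(i)
    partial_moment_numeric(ex, qs[i], qs[i + 1]) / p[i], numeric(1))
  expect_equal(optimal_scores(ex, p), oracle, tolerance = 1e-8)
  expect_error(optimal_scores(ex, c(0.5, 0, 0.5)), "positive")
})

test_that("optimal scores preserve the mean, shrink the variance, and
           dominate any fixed scoring", {
  set.seed(41)
  for (m in six_families()) {
    p <- random_probs(4)
    xs <- optimal_scores(m, p)
    d <- discretization(xs, p)
    expect_equal(disc_mean(d), dist_mean(m), tolerance = 1e-9,
                 info = m$family)
    expect_lt(disc_var(d), dist_var(m))
    r_opt <- corr_with_optimal_scores(m, p)
    # route agreement: sqrt(V)/sigma vs the generic comonotonic formula
    expect_equal(r_opt, max_point_polyserial(m, d)$rho, tolerance = 1e-10,
                 info = m$family)
    # optimal scores dominate consecutive integer scores
    r_cis <- max_point_polyserial(m, discretization(1:4, p))$rho
    expect_gte(r_opt, r_cis - 1e-12)
    expect_true(r_opt > 0 && r_opt < 1)
  }
})

test_that("normal biserial ratio: maximum, symmetry, tails, MC oracle", {
  expect_equal(biserial_ratio_normal(0), 2 * stats::dnorm(0))
  expect_equal(round(biserial_ratio_normal(0), 4), 0.7979)
  expect_equal(biserial_ratio_normal(1.3), biserial_ratio_normal(-1.3))
  expect_lt(biserial_ratio_normal(8), 1e-4)
  # k = 2 consistency with the general ratio
  for (w in c(-0.7, 0, 1)) {
    p <- stats::pnorm(w, lower.tail = FALSE)
    expect_equal(biserial_ratio_normal(w), normal_ratio(c(1 - p, p)),
                 tolerance = 1e-14)
  }
  # Monte-Carlo oracle: dichotomized comonotonic normal pair at omega = 1
  set.seed(51)
  z <- stats::rnorm(1e6)
  expect_equal(biserial_ratio_normal(1), stats::cor(z, as.numeric(z >= 1)),
               tolerance = 0.002)
})

test_that("normal point-polyserial ratio reproduces Table-1-style values", {
  expect_equal(round(normal_ratio(rep(1 / 3, 3)), 4), 0.8906)
  expect_equal(round(normal_ratio(rep(1 / 7, 7)), 4), 0.9581)
  expect_error(normal_ratio(c(1, 0, 0)), "zero variance")
})

test_that("attainable bounds: lognormal closed forms and generic quadrature", {
  l1 <- make_distribution("lognormal", mu = 0, sigma = 1)
  l2 <- make_distribution("lognormal", mu = 0, sigma = 2)
  b <- attainable_bounds(l1, l2)
  expect_equal(round(unname(b["rho_max"]), 3), 0.666)
  expect_equal(round(unname(b["rho_min"]), 3), -0.090)
  b11 <- attainable_bounds(l1, make_distribution("lognormal", sigma = 1))
  expect_equal(unname(b11["rho_max"]), 1)
  expect_equal(unname(b11["rho_min"]), -exp(-1), tolerance = 1e-4)
  # any model against itself attains +1; normal against itself also -1
  bn <- attainable_bounds(make_distribution("normal"),
                          make_distribution("normal"))
  expect_equal(unname(bn), c(-1, 1), tolerance = 1e-9)
  expect_error(attainable_bounds(l1, make_distribution("pareto", alpha = 2)),
               "does not exist")
})

test_that("empirical maximal correlation is the sorted-sample correlation", {
  set.seed(61)
  x <- stats::rnorm(500)
  expect_equal(empirical_max_corr(x, exp(x)),
               stats::cor(sort(x), sort(exp(x))))
  expect_equal(empirical_max_corr(c(1, 2, 3), c(10, 20, 30)), 1)
  # already-comonotone monotone transform: sorting leaves pairing intact
  expect_equal(empirical_max_corr(x, 3 * x + 2), 1)
  expect_error(empirical_max_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  # large-sample check against the analytic k = 6 equal-probability value
  u <- stats::runif(1e6)
  y <- findInterval(u, (1:5) / 6) + 1
  expect_equal(empirical_max_corr(stats::qnorm(u), y),
               equalprob_maxcorr(make_distribution("normal"), 6),
               tolerance = 0.002)
})
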