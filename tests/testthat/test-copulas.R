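test_that("copula parameter domains are enforced", {
  expect_error(copula_model("gauss", 1.2), "domain")
  expect_error(copula_model("frank", 0), "domain")
  expect_error(copula_model("clayton", -0.5), "domain")
  expect_error(copula_model("gumbel", 0.8), "domain")
  expect_s3_class(copula_model("gumbel", 1), "ppc_copula")
})

test_that("densities: independence limits and finite-difference oracle", {
  u <- c(0.2, 0.5, 0.8)
  expect_equal(copula_density(copula_model("gauss", 1e-12), u, rev(u)),
               rep(1, 3), tolerance = 1e-9)
  expect_equal(copula_density(copula_model("frank", 1e-8), u, rev(u)),
               rep(1, 3), tolerance = 1e-6)
  # mixed partial derivative of the CDF as an independent oracle
  fd_density <- function(cop, u, v, h = 1e-4) {
    (copula_cdf(cop, u + h, v + h) - copula_cdf(cop, u - h, v + h) -
       copula_cdf(cop, u + h, v - h) + copula_cdf(cop, u - h, v - h)) /
      (4 * h^2)
  }
  for (cop in list(copula_model("clayton", 2), copula_model("frank", 4),
                   copula_model("gumbel", 1.7))) {
    for (pt in list(c(0.5, 0.5), c(0.3, 0.7))) {
      expect_equal(copula_density(cop, pt[1], pt[2]),
                   fd_density(cop, pt[1], pt[2]),
                   tolerance = 1e-4, info = cop$family)
    }
  }
  expect_error(copula_density(copula_model("clayton", 2), 0, 0.5),
               "strictly inside")
})

test_that("densities are symmetric, nonnegative and carry the CDF's mass", {
  n <- 96
  g <- maxppc:::gauss_legendre(n)
  U <- matrix(g$x, n, n)
  W <- outer(g$w, g$w)
  # smooth interior box where tensor quadrature is sharp: the density must
  # reproduce the rectangle mass of the CDF (inclusion-exclusion) to 1e-6
  eps <- 0.05
  Ub <- matrix(eps + (1 - 2 * eps) * g$x, n, n)
  Wb <- outer(g$w, g$w) * (1 - 2 * eps)^2
  for (cop in list(copula_model("gauss", 0.6), copula_model("frank", 5),
                   copula_model("clayton", 2), copula_model("gumbel", 2))) {
    dens <- copula_density(cop, U, t(U))
    expect_true(all(dens >= 0), info = cop$family)
    expect_equal(dens, t(dens), tolerance = 1e-10, info = cop$family)
    # full-square integral approaches 1; corner singularities limit the
    # fixed tensor grid to ~1e-4 for Clayton/Gumbel
    expect_equal(sum(W * dens), 1, tolerance = 5e-4, info = cop$family)
    box <- copula_cdf(cop, 1 - eps, 1 - eps) -
      copula_cdf(cop, eps, 1 - eps) - copula_cdf(cop, 1 - eps, eps) +
      copula_cdf(cop, eps, eps)
    expect_equal(sum(Wb * copula_density(cop, Ub, t(Ub))), box,
                 tolerance = 1e-6, info = cop$family)
  }
})

test_that("conditional distribution is the u-derivative of the CDF", {
  for (cop in list(copula_model("gauss", 0.5), copula_model("frank", -3),
                   copula_model("clayton", 1.5), copula_model("gumbel", 2.5))) {
    h <- 1e-5
    for (pt in list(c(0.4, 0.6), c(0.7, 0.2))) {
      fd <- (copula_cdf(cop, pt[1] + h, pt[2]) -
               copula_cdf(cop, pt[1] - h, pt[2])) / (2 * h)
      expect_equal(copula_conditional(cop, pt[1], pt[2]), fd,
                   tolerance = 1e-6, info = cop$family)
    }
  }
})

test_that("Spearman calibration round-trips for every family", {
  expect_equal(calibrate_theta("gauss", 0), 0)
  expect_equal(calibrate_theta("gauss", 0.5), 2 * sin(pi / 12))
  expect_error(calibrate_theta("clayton", -0.3), "positive dependence")
  expect_error(calibrate_theta("gumbel", -0.1), "positive dependence")
  for (f in c("gauss", "frank", "clayton", "gumbel")) {
    for (rs in c(0.2, 0.7)) {
      th <- calibrate_theta(f, rs)
      expect_equal(spearman_rho(copula_model(f, th)), rs,
                   tolerance = 1e-6, info = f)
    }
  }
  # comprehensive families reach negative dependence too
  th <- calibrate_theta("frank", -0.4)
  expect_equal(spearman_rho(copula_model("frank", th)), -0.4,
               tolerance = 1e-6)
})

test_that("point-polyserial correlation under a copula: limits and 2-D
           tensor-quadrature oracle", {
  expect_equal(point_polyserial_under_copula(copula_model("gauss", 1e-9), 2),
               0, tolerance = 1e-7)
  # near-comonotone Gauss approaches the uniform equal-probability bound
  expect_equal(point_polyserial_under_copula(copula_model("gauss", 0.9999), 2),
               0.8660, tolerance = 5e-3)
  expect_equal(point_polyserial_under_copula(copula_model("gauss", 0.9999), 3),
               0.9428, tolerance = 5e-3)

  # oracle: band-wise 2-D tensor Gauss-Legendre over the copula density
  # n = 256 keeps the (1,1)-corner discretization error of the tensor grid
  # below ~5e-5 for the Gumbel (checked by grid refinement)
  oracle_rho <- function(cop, k) {
    n <- 256
    g <- maxppc:::gauss_legendre(n)
    mixed <- 0
    for (i in seq_len(k)) {
      lo <- (i - 1) / k
      v <- lo + g$x / k
      U <- matrix(g$x, n, n)
      V <- matrix(v, n, n, byrow = TRUE)
      W <- outer(g$w, g$w) / k
      mixed <- mixed + i * sum(W * U * copula_density(cop, U, V))
    }
    (mixed - 0.5 * (k + 1) / 2) / sqrt((k^2 - 1) / 12 / 12)
  }
  for (cop in list(copula_model("gauss", 0.6), copula_model("frank", 5),
                   copula_model("clayton", 2), copula_model("gumbel", 2))) {
    for (k in 2:3) {
      expect_equal(point_polyserial_under_copula(cop, k),
                   oracle_rho(cop, k), tolerance = 1e-4,
                   info = paste(cop$family, k))
    }
  }
})

test_that("ratio curves: Gauss band, rho_pp bound, convergence to the
           uniform bound as rho -> 1", {
  bound2 <- sqrt(1 - 1 / 4)   # .8660
  bound3 <- sqrt(1 - 1 / 9)   # .9428
  rc <- ratio_curve("gauss", k = 2)
  expect_equal(nrow(rc), 19)
  expect_true(all(rc$ratio > 0.80 & rc$ratio <= bound2 + 1e-6))
  for (f in c("gauss", "frank", "clayton", "gumbel")) {
    rc3 <- ratio_curve(f, rho_grid = c(0.1, 0.5, 0.9), k = 3)
    expect_true(all(rc3$rho_pp <= bound3 + 1e-5), info = f)
    r99 <- ratio_curve(f, rho_grid = 0.99, k = 2)
    expect_equal(r99$ratio, bound2, tolerance = 0.01, info = f)
  }
  expect_error(ratio_curve("gauss", rho_grid = c(0, 0.5), k = 2))
})
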