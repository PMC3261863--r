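test_that("edge locations are the design-times-eta dot products", {
  d0 <- intercept_design(3)
  expect_equal(edge_locations(d0, 2.5), rep(2.5, 6))
  z <- edge_design(cbind(1, c(3, 3)), n = 2, names = c("(Intercept)", "z"))
  expect_equal(edge_locations(z, c(1, -2)), c(-5, -5))
  set.seed(5)
  Z <- cbind(1, matrix(rnorm(20 * 3), 20, 3))
  d <- edge_design(Z, n = 5)
  eta <- rnorm(4)
  naive <- vapply(1:20, function(r) sum(Z[r, ] * eta), numeric(1))
  expect_equal(edge_locations(d, eta), naive)
  expect_error(edge_locations(d, eta[1:2]), "length")
})

test_that("node attribute expansion matches the per-pair loop", {
  set.seed(6)
  attr_tab <- data.frame(u = rnorm(4))
  d <- node_design(attr_tab, list(u = c("sender", "receiver", "absdiff")))
  idx <- edge_index(4)
  for (e in seq_len(nrow(idx))) {
    i <- idx[e, 1]; j <- idx[e, 2]
    expect_equal(unname(d$covariates[e, ]),
                 c(1, attr_tab$u[i], attr_tab$u[j],
                   abs(attr_tab$u[i] - attr_tab$u[j])))
  }
})

test_that("CDF maps hit their documented reference points", {
  y1 <- valued_network(matrix(c(0, 0, 0, 0), 2, 2))
  cau <- marginal_model("cauchy", eta = 0, alpha = 1)
  expect_equal(unique(gergm:::edge_vector(to_restricted(y1, cau))), 0.5)

  iv <- marginal_model("interval", bounds = c(-1, 1))
  y2 <- valued_network(matrix(c(0, .5, .5, 0), 2, 2))
  expect_equal(unique(gergm:::edge_vector(to_restricted(y2, iv))), 0.75)
  expect_error(to_restricted(valued_network(matrix(c(0, 2, 0, 0), 2, 2)),
                             iv), "bounds")

  # gaussian CDF against a quadrature oracle of the normal density
  gau <- marginal_model("gaussian", eta = 0, alpha = 1)
  y3 <- valued_network(matrix(c(0, 1.959964, -0.5, 0), 2, 2, byrow = TRUE))
  x3 <- gergm:::edge_vector(to_restricted(y3, gau))
  quad <- function(b) stats::integrate(function(t) dnorm(t), -Inf, b,
                                       rel.tol = 1e-10)$value
  expect_equal(x3[1], quad(1.959964), tolerance = 1e-7)
  expect_equal(x3[1], 0.975, tolerance = 1e-6)
  expect_equal(x3[2], quad(-0.5), tolerance = 1e-7)
})

test_that("quantile maps invert the CDF maps (round trip, all families)", {
  cau <- marginal_model("cauchy", eta = 0, alpha = 1)
  x <- restricted_network(matrix(c(0, .75, .5, 0), 2, 2, byrow = TRUE))
  y <- to_observed(x, cau)
  expect_equal(y[1, 2], 1.0, tolerance = 1e-12)  # tan(pi/4)

  iv <- marginal_model("interval", bounds = c(-1, 1))
  expect_equal(to_observed(x, iv)[1, 2], 0.5)

  set.seed(8)
  n <- 24  # 552 edges; round trip over many random edges per family
  Z <- edge_design(cbind(1, rnorm(n * (n - 1))), n = n)
  for (fam in c("gaussian", "cauchy")) {
    mod <- marginal_model(fam, eta = c(0.3, -1.2), alpha = 1.7)
    x <- restricted_network(matrix(runif(n * n, .01, .99), n, n))
    y <- to_observed(x, mod, Z)
    back <- to_restricted(y, mod, Z)
    expect_equal(gergm:::edge_vector(back), gergm:::edge_vector(x),
                 tolerance = 1e-8)
  }
})

test_that("quantile functions are strictly increasing on a grid", {
  grid <- seq(.01, .99, by = .01)
  for (mod in list(marginal_model("gaussian", eta = 1, alpha = 2),
                   marginal_model("cauchy", eta = -1, alpha = .5),
                   marginal_model("interval", bounds = c(2, 5)))) {
    yv <- gergm:::marg_quantile(mod, grid,
                                rep(if (length(mod$eta)) mod$eta else 0,
                                    length(grid)))
    expect_true(all(diff(yv) > 0))
  }
})

test_that("log marginal density sums edgewise log densities", {
  cau <- marginal_model("cauchy", eta = 0, alpha = 1)
  y1 <- valued_network(matrix(0, 2, 2))
  expect_equal(log_marginal_density(y1, cau), 2 * (-log(pi)))

  iv <- marginal_model("interval", bounds = c(0, 1))
  yb <- valued_network(matrix(c(0, .2, .9, 0), 2, 2, byrow = TRUE))
  expect_equal(log_marginal_density(yb, iv), 0)

  # gaussian against quadrature-normalized density values
  set.seed(9)
  mus <- rnorm(100); ys <- rnorm(100, mus, 1.3)
  norm_const <- stats::integrate(function(t) exp(-t^2 / (2 * 1.3^2)),
                                 -Inf, Inf, rel.tol = 1e-12)$value
  oracle <- sum(-(ys - mus)^2 / (2 * 1.3^2) - log(norm_const))
  mod <- marginal_model("gaussian", eta = 0, alpha = 1.3)
  pkg <- gergm:::marg_logpdf(mod, ys, mus)
  expect_equal(sum(pkg), oracle, tolerance = 1e-9)
})

test_that("marginal model validation catches bad parameters", {
  expect_error(marginal_model("gaussian", alpha = -1), "positive")
  expect_error(marginal_model("interval"), "bounds")
  expect_error(marginal_model("interval", bounds = c(2, 1)), "bounds")
})
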