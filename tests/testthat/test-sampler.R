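test_that("conditional coefficients follow the edge deltas", {
  m <- matrix(c(0, .2, .4, 0), 2, 2, byrow = TRUE)
  expect_equal(conditional_coefficient(m, 0, "reciprocity", 1, 2), 0)
  expect_equal(conditional_coefficient(m, 2, "edge_sum", 1, 2), 2)
  expect_equal(conditional_coefficient(m, 2, "edge_sum", 2, 1), 2)
  expect_equal(conditional_coefficient(m, 1, "reciprocity", 1, 2), 0.4)
  expect_error(conditional_coefficient(m, c(1, 2), "edge_sum", 1, 2),
               "length")
})

test_that("draw_edge is the exact inverse CDF of the conditional", {
  expect_equal(draw_edge(0, 0.5), 0.5)
  # frozen value computed by bisection on the analytic CDF
  expect_equal(draw_edge(1, 0.5), bisect_trunc_exp(1, 0.5),
               tolerance = 1e-9)
  expect_equal(draw_edge(1, 0.5), 0.620115, tolerance = 1e-6)
  # matches bisection across signs and magnitudes, incl. overflow regime
  set.seed(21)
  for (a in c(-50, -5, -1, 1e-4, 1, 5, 50, 800)) {
    u <- runif(5, .05, .95)
    expect_equal(draw_edge(a, u),
                 vapply(u, function(ui) bisect_trunc_exp(a, ui),
                        numeric(1)),
                 tolerance = 1e-7)
  }
  # reflection symmetry of the truncated exponential
  a <- runif(50, -6, 6); u <- runif(50, .01, .99)
  expect_equal(draw_edge(a, u) + draw_edge(-a, 1 - u), rep(1, 50),
               tolerance = 1e-9)
  expect_error(draw_edge(1, 1.5), "strictly")
})

test_that("repeated conditional draws match the analytic density", {
  set.seed(22)
  for (a in c(-5, -1, 1, 5)) {
    u <- runif(20000)
    x <- draw_edge(a, u)
    breaks <- seq(0, 1, by = .1)
    obs <- table(cut(x, breaks))
    p <- diff(vapply(breaks, trunc_exp_cdf, numeric(1), a = a))
    expect_gt(stats::chisq.test(obs, p = p)$p.value, 1e-3)
  }
})

test_that("a sweep at theta = 0 yields iid uniforms; seeds reproduce", {
  set.seed(23)
  x0 <- rand_restricted(8)
  x1 <- gibbs_sweep(x0, 0, "reciprocity")
  expect_gt(stats::ks.test(gergm:::edge_vector(x1), "punif")$p.value, .01)
  set.seed(99)
  a <- gibbs_sweep(x0, c(1, -1), c("edge_sum", "reciprocity"))
  set.seed(99)
  b <- gibbs_sweep(x0, c(1, -1), c("edge_sum", "reciprocity"))
  expect_identical(a, b)
})

test_that("the chain's long-run mean matches the closed-form mean", {
  set.seed(24)
  sim <- simulate_restricted(3, "edge_sum", n = 8,
                             gibbs_config(sweeps = 1500, burnin = 100))
  # independent-edge model: mean of exp(3x) on (0,1) via quadrature
  oracle <- stats::integrate(function(x) x * exp(3 * x), 0, 1)$value /
    stats::integrate(function(x) exp(3 * x), 0, 1)$value
  expect_equal(mean(sim$draws), oracle, tolerance = 0.01)
  expect_equal(oracle, 1 / (1 - exp(-3)) - 1 / 3, tolerance = 1e-9)
})

test_that("simulation output has the right shape and traces", {
  set.seed(25)
  cfg <- gibbs_config(sweeps = 50, burnin = 10, thin = 4)
  sim <- simulate_restricted(c(0, 0), c("edge_sum", "reciprocity"), 5, cfg)
  expect_length(sim$networks, 10)          # (50 - 10) / 4
  expect_equal(dim(sim$draws), c(20, 10))  # m = 20 edges
  expect_length(sim$mean_trace, 50)
  expect_equal(dim(sim$stat_trace), c(50, 2))
  expect_true(all(sim$mean_trace > 0 & sim$mean_trace < 1))
  expect_error(simulate_restricted(0, "edge_sum", 1, cfg), "at least 2")
})

test_that("theta = 0 edges are uniform; transformed edges match family", {
  set.seed(26)
  cfg <- gibbs_config(sweeps = 120, burnin = 20, thin = 1)
  sim <- simulate_observed(0, "edge_sum",
                           marginal_model("gaussian", eta = 0, alpha = 1),
                           n = 6, config = cfg)
  pooled_x <- as.numeric(sim$draws)
  expect_gt(stats::ks.test(pooled_x, "punif")$p.value, .01)
  pooled_y <- unlist(lapply(sim$observed, gergm:::edge_vector))
  expect_gt(stats::ks.test(pooled_y, "pnorm")$p.value, .01)

  ivcfg <- gibbs_config(sweeps = 30, burnin = 10)
  sim2 <- simulate_observed(0, "edge_sum",
                            marginal_model("interval", bounds = c(-1, 1)),
                            n = 6, config = ivcfg)
  ys <- unlist(lapply(sim2$observed, gergm:::edge_vector))
  expect_true(all(ys >= -1 & ys <= 1))

  sim3 <- simulate_observed(0, "edge_sum",
                            marginal_model("cauchy", eta = 0, alpha = 1),
                            n = 6, config = cfg)
  yc <- unlist(lapply(sim3$observed, gergm:::edge_vector))
  kurt <- mean((yc - mean(yc))^4) / stats::var(yc)^2
  expect_gt(kurt, 20)  # heavy tails dwarf the normal kurtosis of 3
})

test_that("extreme dependence parameters drive the chain to full/empty", {
  set.seed(27)
  cfg <- gibbs_config(sweeps = 60, burnin = 20)
  hi <- simulate_restricted(40, "edge_sum", 6, cfg)
  lo <- simulate_restricted(-40, "edge_sum", 6, cfg)
  expect_gt(mean(hi$draws), 0.95)
  expect_lt(mean(lo$draws), 0.05)
})

test_that("dispersed initialization draws from a U-shaped start", {
  set.seed(28)
  m <- gergm:::init_network("dispersed", 30)
  v <- gergm:::edge_vector(m)
  # Beta(1/2,1/2) puts more than uniform mass near the endpoints
  expect_gt(mean(v < .1 | v > .9), 0.25)
})
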