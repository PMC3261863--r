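test_that("MPLE solves the conditional moment equations", {
  # edge_sum only: conditionals = marginals, so the MPLE matches the
  # moment equation mean(x) = E[x; theta] exactly
  half <- gergm:::edge_matrix(rep(.5, 12), 4, diag = 0)
  th <- mple(half, "edge_sum")
  expect_equal(as.numeric(th), 0, tolerance = 1e-6)

  # mean 0.719...: root of the truncated-exponential mean, computed by
  # numerical inversion of the quadrature mean function
  mean_fun <- function(a) stats::integrate(function(x) x * exp(a * x),
                                           0, 1)$value /
    stats::integrate(function(x) exp(a * x), 0, 1)$value
  target <- mean_fun(3)
  m3 <- gergm:::edge_matrix(rep(target, 12), 4, diag = 0)
  th3 <- mple(m3, "edge_sum")
  expect_equal(as.numeric(th3), 3, tolerance = 1e-5)

  # first-order condition at the maximizer
  set.seed(31)
  x <- rand_restricted(6)
  th2 <- mple(x, c("edge_sum", "reciprocity", "in_two_stars"))
  expect_lt(max(abs(attr(th2, "gradient"))), 1e-5)
})

test_that("with theta = 0 the marginal fit reduces to regression", {
  set.seed(32)
  n <- 10
  Z <- edge_design(cbind(1, rnorm(90), rnorm(90)), n = n)
  eta_true <- c(1, .5, -.25)
  yv <- drop(Z$covariates %*% eta_true) + rnorm(90, sd = .7)
  y <- valued_network(gergm:::edge_matrix(yv, n, diag = 0))

  # gaussian: closed-form least squares oracle via the normal equations
  fitg <- fit_beta(y, marginal_model("gaussian"), Z)
  ols <- solve(crossprod(Z$covariates), crossprod(Z$covariates, yv))
  expect_equal(fitg$eta, unname(drop(ols)), tolerance = 1e-6)
  expect_equal(fitg$alpha,
               sqrt(mean((yv - drop(Z$covariates %*% ols))^2)),
               tolerance = 1e-6)

  # intercept-only gaussian: location is the sample mean of the edges
  fit0 <- fit_beta(y, marginal_model("gaussian"), intercept_design(n))
  expect_equal(fit0$eta, mean(yv), tolerance = 1e-8, ignore_attr = TRUE)

  # cauchy: independent Cauchy-regression oracle by direct maximization
  # of the Cauchy log likelihood (different optimizer + parameterization)
  set.seed(33)
  yc <- drop(Z$covariates %*% eta_true) + rcauchy(90, scale = .5)
  ycn <- valued_network(gergm:::edge_matrix(yc, n, diag = 0))
  fitc <- fit_beta(ycn, marginal_model("cauchy"), Z)
  oracle_nll <- function(p)
    -sum(dcauchy(yc, drop(Z$covariates %*% p[1:3]), exp(p[4]), log = TRUE))
  orc <- stats::nlm(oracle_nll, c(stats::median(yc), 0, 0, 0),
                    gradtol = 1e-12, steptol = 1e-14, iterlim = 500)
  expect_equal(fitc$eta, orc$estimate[1:3], tolerance = 1e-4)
  expect_equal(log(fitc$alpha), orc$estimate[4], tolerance = 1e-4)
})

test_that("the importance-sampled constant ratio matches the closed form", {
  # independent-edge model: C(theta) = [(e^theta - 1)/theta]^m exactly
  set.seed(34)
  n <- 5; m <- 20; M <- 2000
  theta_t <- 0.5
  sim <- simulate_restricted(theta_t, "edge_sum", n,
                             gibbs_config(sweeps = M + 20, burnin = 20))
  H <- colSums(sim$draws)
  for (theta in c(1.2, -0.5)) {
    w <- (theta - theta_t) * H
    est <- log(mean(exp(w)))
    se <- stats::sd(exp(w)) / (mean(exp(w)) * sqrt(M))
    closed <- m * (log(expm1(theta) / theta) -
                   log(expm1(theta_t) / theta_t))
    expect_lt(abs(est - closed), 3.5 * se)
  }
})

test_that("update_theta is self-consistent and guards the convex hull", {
  set.seed(35)
  n <- 6
  spec <- stat_spec(c("edge_sum", "reciprocity"))
  truth <- c(-0.4, 0.8)
  sim <- simulate_restricted(truth, spec, n,
                             gibbs_config(sweeps = 2100, burnin = 100,
                                          thin = 1))
  H <- t(apply(sim$draws, 2, function(v)
    compute_stats(gergm:::edge_matrix(v, n, diag = 0), spec)))

  # self-consistency: with the expected statistics under the truth as the
  # observation, the update returns the truth up to Monte Carlo error
  h_obs <- colMeans(H)
  upd <- update_theta(h_obs, spec, truth, H)
  expect_lt(max(abs(upd - truth)), 0.15)
  expect_lt(max(abs(attr(upd, "gradient"))), 1e-3)

  # the attained objective equals the importance-sampling formula, whose
  # ratio term vanishes at theta = theta_tilde
  obj_manual <- sum(upd * h_obs) -
    log(mean(exp(drop(H %*% (upd - truth)))))
  expect_equal(attr(upd, "objective"), obj_manual, tolerance = 1e-8)

  # observed statistics outside the sampled hull raise the diagnostic
  h_out <- apply(H, 2, max) + 1
  expect_error(update_theta(h_out, spec, truth, H), "convex hull")
})

test_that("full fits recover generating parameters and reproduce", {
  sc <- make_scenario("gaussian_recovery", seed = 101)
  fit <- gergm(sc$network, sc$spec, family = "gaussian",
               design = sc$design, control = gergm_control(M = 400),
               seed = 5)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  truth <- c(sc$theta, sc$model$eta, 0)  # log(alpha = 1) = 0
  expect_true(all(abs(est - truth) < 3.5 * se))
  expect_true(all(diag(vcov(fit)) > 0))
  expect_equal(vcov(fit), t(vcov(fit)))

  # identical seed and configuration reproduce the fit exactly
  fit2 <- gergm(sc$network, sc$spec, family = "gaussian",
                design = sc$design, control = gergm_control(M = 400),
                seed = 5)
  expect_equal(coef(fit), coef(fit2))
  expect_equal(vcov(fit), vcov(fit2))
})

test_that("the beta covariance block matches least-squares theory", {
  # theta approximately 0 by construction: independent gaussian data
  set.seed(36)
  n <- 12
  Z <- edge_design(cbind(1, rnorm(n * (n - 1))), n = n)
  yv <- drop(Z$covariates %*% c(1, .5)) + rnorm(n * (n - 1), sd = .8)
  y <- valued_network(gergm:::edge_matrix(yv, n, diag = 0))
  fit <- gergm(y, "edge_sum", family = "gaussian", design = Z,
               control = gergm_control(M = 400), seed = 6)
  # blockwise: the beta block alone is the independent-regression
  # information; the joint covariance also carries the near-collinear
  # (edge_sum, intercept) direction
  Vb <- vcov_estimate(fit, blockwise = TRUE)
  V <- Vb[c("(Intercept)", "z1"), c("(Intercept)", "z1")]
  ols_V <- fit$model$alpha^2 * solve(crossprod(Z$covariates))
  expect_equal(unname(V), unname(ols_V), tolerance = 0.05)
  expect_true(all(diag(Vb) > 0))
})

test_that("Wald block tests obey their small-sample identities", {
  sc <- make_scenario("gaussian_recovery", seed = 102)
  fit <- gergm(sc$network, sc$spec, family = "gaussian",
               design = sc$design, control = gergm_control(M = 300),
               seed = 7)
  # single parameter: W = (estimate / SE)^2
  w1 <- wald_block_test(fit, "reciprocity")
  z <- coef(fit)["reciprocity"] / sqrt(vcov(fit)["reciprocity",
                                                 "reciprocity"])
  expect_equal(w1$statistic, unname(z^2), tolerance = 1e-10)
  expect_equal(w1$df, 1L)
  # a parameter forced to zero gives W = 0, p = 1
  fit0 <- fit
  fit0$theta["reciprocity"] <- 0
  w0 <- wald_block_test(fit0, "reciprocity")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)
  expect_error(wald_block_test(fit, "not_a_parameter"), "unknown")
})
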