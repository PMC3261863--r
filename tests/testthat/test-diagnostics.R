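test_that("Geweke z flags designed failures and rejects bad input", {
  expect_error(geweke_z(rnorm(50)), "too short")
  expect_error(geweke_z(rnorm(1000), first_frac = .5, last_frac = .6),
               "non-overlapping")
  expect_error(geweke_z(rep(1, 1000)), "degenerate")
  # a mean step-change at the midpoint must be flagged loudly
  set.seed(41)
  broken <- c(rnorm(2000), rnorm(2000, mean = 3))
  expect_gt(abs(geweke_z(broken)), 5)
  # a well-behaved iid chain is not flagged (one draw, fixed seed)
  expect_lt(abs(geweke_z(rnorm(5000))), 3)
})

test_that("Geweke z is approximately standard normal on iid chains", {
  set.seed(42)
  zs <- replicate(200, geweke_z(rnorm(2000)))
  # calibration: rejection rate near the nominal 5%
  expect_lt(abs(mean(abs(zs) > 1.96) - 0.05), 0.045)
  expect_gt(stats::ks.test(zs, "pnorm")$p.value, 0.01)
})

test_that("Gelman-Rubin follows its closed form and calibrates", {
  # identical nonconstant chains: B = 0 forces R = sqrt((n-1)/n)
  ch <- rnorm(100)
  expect_equal(gelman_rubin(list(ch, ch)), sqrt(99 / 100))
  # same-distribution chains converge to 1
  set.seed(43)
  chains <- replicate(3, rnorm(10000), simplify = FALSE)
  expect_lt(gelman_rubin(chains), 1.01)
  # chains at different levels blow up
  expect_gt(gelman_rubin(list(rnorm(500), rnorm(500) + 5)), 1.1)
  expect_error(gelman_rubin(list(rnorm(10))), "at least 2")
  expect_error(gelman_rubin(list(rnorm(10), rnorm(11))), "equal length")
  expect_error(gelman_rubin(list(rep(1, 50), rep(1, 50))), "zero within")
})

test_that("degeneracy is flagged by proximity of the mean to 0 or 1", {
  r <- degeneracy_report(list(rep(.02, 500) + rnorm(500, 0, .001)),
                         observed_mean = .5)
  expect_true(r$degenerate)
  expect_match(r$rhat_note, "single chain")
  r2 <- degeneracy_report(list(rep(.48, 500) + rnorm(500, 0, .01),
                               rep(.52, 500) + rnorm(500, 0, .01)),
                          observed_mean = .5)
  expect_false(r2$degenerate)
  expect_true(is.finite(r2$gelman_rubin))
  expect_error(degeneracy_report(list(rnorm(10)), observed_mean = 2),
               "observed_mean")
})

test_that("well-mixed uniform chains pass every diagnostic", {
  set.seed(44)
  sims <- lapply(1:2, function(k)
    simulate_restricted(0, "edge_sum", n = 5,
                        gibbs_config(sweeps = 2000, burnin = 100)))
  r <- degeneracy_report(sims, observed_mean = .5,
                         edge_series = lapply(sims, function(s) s$draws))
  expect_false(r$degenerate)
  expect_true(all(abs(r$geweke) < 4))
  expect_length(r$gelman_rubin, 20)  # per-edge, m = 20
  expect_equal(r$n_rhat_ge_1.1, 0)
})

test_that("goodness of fit separates right and wrong dependence models", {
  set.seed(45)
  # data with strong reciprocity
  spec <- stat_spec(c("edge_sum", "reciprocity"))
  sim <- simulate_restricted(c(0, 2), spec, n = 12,
                             gibbs_config(sweeps = 800, burnin = 799))
  x <- sim$networks[[1]]
  y <- to_observed(x, marginal_model("gaussian"))

  fit_right <- gergm(y, spec, family = "gaussian",
                     control = gergm_control(M = 300), seed = 46)
  g_right <- gof_dependence(fit_right, nsim = 200, seed = 1)
  expect_true(all(g_right$percentile > 0.01 & g_right$percentile < 0.99))

  # a null model must fail to reproduce the reciprocity statistic:
  # force theta to zero and keep the fitted marginal
  fit_null <- fit_right
  fit_null$theta[] <- 0
  g_null <- gof_dependence(fit_null, nsim = 200, seed = 1)
  expect_false(g_null$in_iqr["reciprocity"])
  expect_gt(g_right$observed["reciprocity"],
            max(stats::quantile(g_null$simulated[, "reciprocity"], .75)))

  expect_error(gof_dependence(fit_right, nsim = 0), "positive")
})
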