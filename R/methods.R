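#' @export
print.gergm <- function(x, ...) {
  cat("Generalized exponential random graph model\n")
  cat("  network: ", x$n, " vertices, ", n_edges(x$y), " directed edges\n",
      sep = "")
  cat("  marginal family: ", x$model$family, "\n", sep = "")
  cat("  dependence statistics: ", paste(x$spec$names, collapse = ", "),
      "\n", sep = "")
  cat("  converged: ", x$converged, " (", nrow(x$loglik_trace) - 1L,
      " outer iterations, M = ", x$control$M, ")\n\n", sep = "")
  print(coef(x), digits = 4)
  invisible(x)
}

#' Extract GERGM coefficients
#'
#' The dependence parameters \eqn{\theta} followed by the transformation
#' parameters \eqn{(\eta, \log\alpha)}.
#'
#' @param object a fitted `gergm`.
#' @param ... unused.
#' @export
coef.gergm <- function(object, ...) {
  c(object$theta, stats::setNames(beta_pack(object$model),
                                  beta_names(object$model, object$design)))
}

#' @export
vcov.gergm <- function(object, ...) object$vcov

#' @export
logLik.gergm <- function(object, ...) {
  ll <- object$loglik_trace$loglik[nrow(object$loglik_trace)]
  structure(ll, df = length(coef(object)), class = "logLik")
}

#' Summarize a GERGM fit
#'
#' Coefficient table (estimate, standard error, z, p) from the
#' Hessian-based covariance, plus the joint Wald test that all dependence
#' parameters are zero — the test of the nested independence regression.
#'
#' @param object a fitted `gergm`.
#' @param ... unused.
#' @export
summary.gergm <- function(object, ...) {
  est <- coef(object)
  se <- sqrt(diag(object$vcov))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  wald <- wald_block_test(object)
  structure(list(coefficients = tab, wald_dependence = wald,
                 converged = object$converged,
                 family = object$model$family,
                 statistics = object$spec$names, n = object$n,
                 iterations = nrow(object$loglik_trace) - 1L),
            class = "summary.gergm")
}

#' @export
print.summary.gergm <- function(x, ...) {
  cat("GERGM fit (", x$family, " marginal), ", x$n, " vertices\n\n",
      sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  w <- x$wald_dependence
  cat(sprintf("\nWald test of all dependence terms = 0: W = %.3f on %d df, p = %.4g\n",
              w$statistic, w$df, w$p.value))
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  invisible(x)
}

#' Simulate networks from a fitted GERGM
#'
#' Draws `nsim` observed networks from the fitted model: Gibbs sampling of
#' the restricted network at \eqn{\hat\theta} followed by the fitted
#' marginal transformation.
#'
#' @param object a fitted `gergm`.
#' @param nsim number of networks.
#' @param seed optional seed.
#' @param burnin,thin Gibbs settings; the chain starts at the fitted
#'   restricted network \eqn{\hat x}.
#' @param restricted if `TRUE`, return restricted networks instead of
#'   observed ones.
#' @param ... unused.
#' @return list of networks; attribute `sim` carries the full sampler
#'   output (traces included).
#' @export
simulate.gergm <- function(object, nsim = 100L, seed = NULL,
                           burnin = 100L, thin = 2L,
                           restricted = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- gibbs_config(sweeps = burnin + nsim * thin, burnin = burnin,
                      thin = thin, init = as_edge_matrix(object$x_hat))
  sim <- if (restricted)
    simulate_restricted(object$theta, object$spec, object$n, cfg)
  else
    simulate_observed(object$theta, object$spec, object$model,
                      object$design, object$n, cfg)
  out <- if (restricted) sim$networks else sim$observed
  attr(out, "sim") <- sim
  out
}

#' Fitted edge locations
#'
#' The marginal location \eqn{\mu_{ij} = z_{ij}'\hat\eta} per edge
#' (enumeration order of [edge_index()]); for the interval family, the
#' midpoint of the bounds.
#'
#' @param object a fitted `gergm`.
#' @param ... unused.
#' @export
predict.gergm <- function(object, ...) {
  if (object$model$family == "interval")
    return(rep(mean(object$model$bounds), n_edges(object$y)))
  edge_locations(object$design, object$model$eta)
}

#' Residuals of the marginal location model
#'
#' Observed edge values minus fitted locations, in edge enumeration
#' order.  Dependence lives in the restricted network, so these are
#' marginal (not whitened) residuals.
#'
#' @param object a fitted `gergm`.
#' @param ... unused.
#' @export
residuals.gergm <- function(object, ...) {
  edge_vector(object$y) - predict(object)
}

#' Plot simulation-based goodness of fit
#'
#' Boxplots of each dependence statistic over networks simulated from the
#' fitted model, with the observed value of the statistic on the
#' estimated restricted network overlaid — the fitted model is adequate
#' for a feature when the observed value falls well inside the simulated
#' distribution.
#'
#' @param x a fitted `gergm`.
#' @param nsim simulated networks.
#' @param seed optional seed.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.gergm <- function(x, nsim = 200L, seed = NULL, ...) {
  g <- gof_dependence(x, nsim = nsim, seed = seed)
  sims <- g$simulated
  graphics::boxplot(sims, names = colnames(sims),
                    ylab = "statistic on restricted network", ...)
  graphics::points(seq_along(g$observed), g$observed, col = "red",
                   pch = 19)
  invisible(g)
}
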