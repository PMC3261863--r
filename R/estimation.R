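#' Control parameters for GERGM estimation
#'
#' @param M networks per Monte Carlo sample used to approximate the
#'   normalizing-constant ratio (>= 100).
#' @param max_iter maximum outer alternating iterations.
#' @param tol convergence floor: iteration stops once every parameter
#'   changes by less than `max(tol, 2 * mc_se)`, where `mc_se` is the
#'   Monte Carlo standard error of the dependence-parameter update —
#'   changes smaller than the update's own sampling noise carry no
#'   information, so `tol` alone governs only in the large-`M` limit.
#' @param sim_burnin,sim_thin Gibbs burn-in sweeps and thinning used when
#'   simulating the Monte Carlo samples during estimation (chains start at
#'   the current estimate of the restricted network, so short burn-ins
#'   suffice).
#' @param hull_retries times a fresh, longer sample is drawn after a
#'   convex-hull failure before giving up.
#' @param optim_reltol relative tolerance handed to the inner optimizers.
#' @export
gergm_control <- function(M = 1000L, max_iter = 25L, tol = 1e-4,
                          sim_burnin = 100L, sim_thin = 2L,
                          hull_retries = 2L, optim_reltol = 1e-10) {
  stopifnot(M >= 100, max_iter >= 1, tol > 0)
  structure(list(M = as.integer(M), max_iter = as.integer(max_iter),
                 tol = tol, sim_burnin = as.integer(sim_burnin),
                 sim_thin = as.integer(sim_thin),
                 hull_retries = as.integer(hull_retries),
                 optim_reltol = optim_reltol),
            class = "gergm_control")
}

## delta matrix: m x q change scores of every statistic at every edge
delta_matrix <- function(x, spec) {
  idx <- edge_index(nrow(x))
  m <- as_edge_matrix(x)
  codes <- stat_codes(spec)
  D <- matrix(0, nrow(idx), length(codes))
  for (e in seq_len(nrow(idx)))
    D[e, ] <- cpp_edge_delta(m, codes, idx[e, 1L] - 1L, idx[e, 2L] - 1L)
  sweep(D, 2L, spec$scaling, "/")
}

#' Maximum pseudolikelihood estimate of the dependence parameters
#'
#' Maximizes the product of the exact truncated-exponential full
#' conditionals of all edges,
#' \deqn{\sum_{ij} \{a_{ij} x_{ij} - \log[(e^{a_{ij}} - 1)/a_{ij}]\},
#'   \quad a_{ij} = \theta' \Delta_{ij} h,}
#' the standard starting value for the Monte Carlo MLE.  For a model whose
#' only statistic is `edge_sum` the conditionals equal the marginals and
#' the MPLE is the exact MLE.
#'
#' @param x restricted network.
#' @param spec a [stat_spec()].
#' @param theta_init optional starting value (default 0).
#' @return named numeric vector \eqn{\hat\theta}; attributes `gradient`
#'   and `converged`.
#' @export
mple <- function(x, spec, theta_init = NULL) {
  spec <- as_stat_spec(spec)
  q <- length(spec$names)
  D <- delta_matrix(x, spec)
  xv <- edge_vector(x)
  negll <- function(th) {
    a <- drop(D %*% th)
    -sum(a * xv - log_trunc_exp_norm(a))
  }
  grad <- function(th) {
    a <- drop(D %*% th)
    -drop(crossprod(D, xv - trunc_exp_mean(a)))
  }
  th0 <- if (is.null(theta_init)) numeric(q) else as.numeric(theta_init)
  opt <- stats::optim(th0, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    warning("MPLE optimizer did not converge (code ", opt$convergence,
            ")", call. = FALSE)
  out <- opt$par
  names(out) <- spec$names
  attr(out, "gradient") <- -grad(opt$par)
  attr(out, "converged") <- opt$convergence == 0
  out
}

#' Maximum likelihood update of the transformation parameters
#'
#' With the dependence parameters held at `theta`, maximizes
#' \deqn{\theta'h(F(y \mid \beta)) + \sum_{ij} \log f(y_{ij} \mid \beta)}
#' over \eqn{\beta = (\eta, \log\alpha)} — the normalizing constant does
#' not involve \eqn{\beta}, so this is an ordinary smooth maximization.
#' With `theta = 0` and the Gaussian family the maximizer is exactly the
#' least-squares fit (computed in closed form); with `theta = 0` and the
#' Cauchy family it is the Cauchy regression (CRM) fit.
#'
#' @param y observed `valued_network`.
#' @param model a [marginal_model()] (its parameters are the start).
#' @param design an [edge_design()].
#' @param theta dependence parameters.
#' @param spec a [stat_spec()].
#' @return updated `marginal_model`; attribute `value` holds the attained
#'   objective.
#' @export
fit_beta <- function(y, model, design = NULL, theta = NULL, spec = NULL) {
  if (model$family == "interval") {
    attr(model, "value") <- log_marginal_density(y, model, design)
    return(model)
  }
  if (is.null(design)) design <- intercept_design(nrow(y))
  if (is.null(theta)) theta <- numeric(0)
  dep <- length(theta) > 0 && any(theta != 0)
  if (dep) spec <- as_stat_spec(spec)
  yv <- edge_vector(y)
  Z <- design$covariates

  if (!dep && model$family == "gaussian") {
    ## exact reduction to linear regression on the edges
    qr_fit <- qr(Z)
    eta <- qr.coef(qr_fit, yv)
    resid <- yv - drop(Z %*% eta)
    alpha <- sqrt(mean(resid^2))
    model$eta <- unname(eta); model$alpha <- alpha
    attr(model, "value") <- log_marginal_density(y, model, design)
    return(model)
  }

  objective <- function(beta) {
    mod <- beta_unpack(model, beta)
    val <- log_marginal_density(y, mod, design)
    if (dep) {
      x <- to_restricted(y, mod, design)
      val <- val + sum(theta * compute_stats(x, spec))
    }
    -val
  }
  start <- beta_pack(start_beta(model, yv, Z))
  opt <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0)
    warning("transformation-parameter optimizer did not converge (code ",
            opt$convergence, ")", call. = FALSE)
  out <- beta_unpack(model, opt$par)
  attr(out, "value") <- -opt$value
  out
}

## starting values for the marginal fit: least squares + residual spread
start_beta <- function(model, yv, Z) {
  eta <- tryCatch(qr.coef(qr(Z), yv), error = function(e) NULL)
  if (is.null(eta) || any(!is.finite(eta)))
    eta <- c(stats::median(yv), numeric(ncol(Z) - 1L))
  resid <- yv - drop(Z %*% eta)
  s <- if (model$family == "cauchy") stats::mad(resid) else
         sqrt(mean(resid^2))
  if (!is.finite(s) || s <= 0) s <- stats::sd(resid)
  if (!is.finite(s) || s <= 0) s <- 1
  model$eta <- unname(eta); model$alpha <- s
  model
}

#' Monte Carlo MLE update of the dependence parameters
#'
#' Given a sample of restricted networks simulated at the provisional
#' value \eqn{\tilde\theta}, maximizes the importance-sampling
#' approximation to the log likelihood ratio
#' \deqn{\theta'h(\hat x) - \log\Big[\frac1M \sum_m
#'   e^{(\theta - \tilde\theta)' h(x_m)}\Big],}
#' which estimates \eqn{\theta'h(\hat x) - \log C(\theta)/C(\tilde\theta)}.
#' A finite maximizer exists only when \eqn{h(\hat x)} lies inside the
#' convex hull of the sampled statistics; violations are detected (the
#' componentwise-range necessary condition plus optimizer divergence /
#' non-vanishing gradient) and raised as an error asking for a fresh,
#' larger sample at the current \eqn{\tilde\theta}.
#'
#' @param h_obs statistic vector of the current restricted network
#'   \eqn{h(\hat x)} (or the network itself).
#' @param spec a [stat_spec()].
#' @param theta_tilde parameters the sample was simulated at.
#' @param sample list of restricted networks, or a M x q matrix of their
#'   statistic vectors.
#' @return named numeric vector; attributes `objective`, `weights`
#'   (normalized importance weights at the maximizer) and `gradient`.
#' @export
update_theta <- function(h_obs, spec, theta_tilde, sample) {
  spec <- as_stat_spec(spec)
  q <- length(spec$names)
  if (inherits(h_obs, "valued_network")) h_obs <- compute_stats(h_obs, spec)
  H <- if (is.matrix(sample)) sample else
    t(vapply(sample, compute_stats, numeric(q), spec = spec))
  if (ncol(H) != q) stop("statistic sample has wrong width", call. = FALSE)
  M <- nrow(H)

  ## necessary hull condition: componentwise range
  lo <- apply(H, 2L, min); hi <- apply(H, 2L, max)
  out_lo <- h_obs < lo; out_hi <- h_obs > hi
  if (any(out_lo | out_hi))
    stop_hull(spec$names[out_lo | out_hi])

  lse <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }
  negobj <- function(th) {
    w <- drop(H %*% (th - theta_tilde))
    -(sum(th * h_obs) - (lse(w) - log(M)))
  }
  grad <- function(th) {
    w <- drop(H %*% (th - theta_tilde))
    w <- exp(w - max(w)); w <- w / sum(w)
    -(h_obs - drop(crossprod(H, w)))
  }
  opt <- stats::optim(as.numeric(theta_tilde), negobj, grad,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  g <- -grad(opt$par)
  scale_h <- pmax(apply(H, 2L, stats::sd), 1e-8)
  if (max(abs(g) / scale_h) > 1e-4 ||
      any(abs(opt$par - theta_tilde) > 50))
    stop_hull(spec$names[abs(g) == max(abs(g))])
  th <- opt$par
  names(th) <- spec$names
  w <- drop(H %*% (th - theta_tilde)); w <- exp(w - max(w)); w <- w / sum(w)
  attr(th, "objective") <- -opt$value
  attr(th, "gradient") <- g
  attr(th, "weights") <- w
  attr(th, "mc_se") <- update_mc_se(H, w)
  th
}

## Monte Carlo standard error of the importance-sampling theta update:
## the update solves h_obs = sum_m w_m h_m; linearizing, the noise in the
## weighted mean (covariance ~ Cov_w(h) * sum w^2) maps through the
## inverse weighted covariance, giving Cov_MC(theta) ~ Cov_w(h)^{-1} sum w^2.
update_mc_se <- function(H, w) {
  hbar <- drop(crossprod(H, w))
  Hc <- sweep(H, 2L, hbar)
  Cw <- crossprod(Hc * w, Hc)
  s2 <- sum(w^2)
  se <- tryCatch(sqrt(pmax(diag(solve(Cw)), 0) * s2),
                 error = function(e) sqrt(s2 / pmax(diag(Cw), 1e-12)))
  se
}

stop_hull <- function(which_stats) {
  stop("observed statistics lie outside the convex hull of the ",
       "simulated statistics (", paste(which_stats, collapse = ", "),
       "); draw a fresh, larger sample at the current theta",
       call. = FALSE)
}

## simulate M restricted networks at theta for the Monte Carlo sample
mc_sample <- function(theta, spec, x_hat, control,
                      burnin_mult = 1L) {
  n <- nrow(x_hat)
  cfg <- gibbs_config(
    sweeps = control$sim_burnin * burnin_mult + control$M * control$sim_thin,
    burnin = control$sim_burnin * burnin_mult,
    thin = control$sim_thin, init = as_edge_matrix(x_hat))
  sim <- simulate_restricted(theta, spec, n, cfg)
  H <- t(apply(sim$draws, 2L, function(v)
    cpp_compute_stats(edge_matrix(v, n, diag = 0), stat_codes(spec)) /
      spec$scaling))
  if (length(spec$names) == 1L) H <- matrix(H, ncol = 1L)
  list(H = H, sim = sim)
}

#' Fit a generalized exponential random graph model
#'
#' Estimates a GERGM for a directed valued network by alternating maximum
#' likelihood for the marginal transformation parameters \eqn{\beta =
#' (\eta, \log\alpha)} with Monte Carlo maximum likelihood for the
#' dependence parameters \eqn{\theta}:
#' \enumerate{
#'   \item fit the marginal model with \eqn{\theta = 0} (the nested
#'     independence regression), map the data to the restricted network
#'     \eqn{\hat x = F(y \mid \hat\beta)};
#'   \item initialize \eqn{\theta} at the maximum pseudolikelihood
#'     estimate;
#'   \item repeat until the largest parameter change drops below `tol`:
#'     simulate `M` restricted networks at the current \eqn{\tilde\theta}
#'     by Gibbs sampling, update \eqn{\theta} by importance-sampling MLE
#'     ([update_theta()]), update \eqn{\beta} by [fit_beta()] at the new
#'     \eqn{\theta}, recompute \eqn{\hat x}.
#' }
#' The covariance matrix is the negative inverse of the numerical Hessian
#' of the approximated joint log likelihood at the final estimates.
#'
#' @param y observed network: a `valued_network` or square numeric matrix
#'   (directed).
#' @param statistics dependence statistics: a [stat_spec()] or character
#'   vector (see [gergm_statistics()]).
#' @param family marginal family, see [marginal_model()].
#' @param design optional [edge_design()] of edge covariates (default
#'   intercept only).
#' @param bounds support bounds for the `interval` family.
#' @param control a [gergm_control()].
#' @param seed optional integer seed for the simulation steps.
#' @return an object of class `gergm`; see [coef.gergm()],
#'   [summary.gergm()], [simulate.gergm()], [gof_dependence()].
#' @examples
#' set.seed(7)
#' truth <- c(edge_sum = -0.5, reciprocity = 0.8)
#' sim <- simulate_restricted(truth, names(truth), n = 10,
#'                            gibbs_config(sweeps = 600, burnin = 599))
#' y <- to_observed(sim$networks[[1]], marginal_model("gaussian"))
#' \donttest{
#' fit <- gergm(y, names(truth), family = "gaussian",
#'              control = gergm_control(M = 200), seed = 1)
#' summary(fit)
#' }
#' @export
gergm <- function(y, statistics, family = c("gaussian", "cauchy",
                                            "interval"),
                  design = NULL, bounds = NULL,
                  control = gergm_control(), seed = NULL) {
  cl <- match.call()
  family <- match.arg(family)
  if (!inherits(y, "valued_network")) y <- valued_network(y)
  if (!is_directed(y))
    stop("estimation is implemented for directed networks", call. = FALSE)
  spec <- as_stat_spec(statistics)
  n <- nrow(y)
  if (is.null(design)) design <- intercept_design(n)
  if (!is.null(seed)) set.seed(seed)

  model <- if (family == "interval")
    marginal_model("interval", bounds = bounds)
  else marginal_model(family, eta = numeric(ncol(design$covariates)),
                      alpha = 1)

  ## step 1: independence fit of the marginal, restricted network, MPLE
  model <- fit_beta(y, model, design, theta = NULL)
  x_hat <- to_restricted(y, model, design)
  theta <- mple(x_hat, spec)
  attributes(theta) <- list(names = names(theta))

  trace <- data.frame(iter = 0L,
                      loglik = log_marginal_density(y, model, design),
                      max_delta = NA_real_)
  converged <- FALSE
  sample_info <- NULL

  for (it in seq_len(control$max_iter)) {
    theta_old <- theta
    beta_old <- beta_pack(model)

    ## Monte Carlo sample at the provisional theta, with hull retries
    upd <- NULL
    for (try in 0:control$hull_retries) {
      smp <- mc_sample(theta, spec, x_hat, control,
                       burnin_mult = 2L^try)
      upd <- tryCatch(
        update_theta(compute_stats(x_hat, spec), spec, theta, smp$H),
        error = function(e)
          if (try < control$hull_retries &&
              grepl("convex hull", conditionMessage(e))) NULL
          else stop(e))
      if (!is.null(upd)) break
    }
    mc_se <- attr(upd, "mc_se")
    theta <- upd
    attributes(theta) <- list(names = names(theta))
    sample_info <- smp

    model <- fit_beta(y, model, design, theta, spec)
    x_hat <- to_restricted(y, model, design)

    delta <- max(abs(c(theta - theta_old, beta_pack(model) - beta_old)))
    ll <- attr(upd, "objective") +
      log_marginal_density(y, model, design)
    trace <- rbind(trace, data.frame(iter = it, loglik = ll,
                                     max_delta = delta))
    ## converged when every parameter change is below tol or within the
    ## Monte Carlo jitter of the theta update (changes smaller than the
    ## update's own sampling noise carry no information)
    tol_theta <- pmax(control$tol, 2 * mc_se)
    tol_beta <- max(control$tol, 2 * max(mc_se))
    ## the first sample is generated at the MPLE, which can sit off the
    ## MLE; never declare convergence before a second resampled update
    if (it >= 2L &&
        all(abs(theta - theta_old) < tol_theta) &&
        all(abs(beta_pack(model) - beta_old) < tol_beta)) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    warning("estimation did not converge in ", control$max_iter,
            " outer iterations (last max |delta| = ",
            format(trace$max_delta[nrow(trace)], digits = 3), ")",
            call. = FALSE)

  ## fresh sample at the final theta for the covariance estimate
  smp <- mc_sample(theta, spec, x_hat, control)
  fit <- structure(list(
    call = cl, theta = theta, model = model, spec = spec,
    design = design, y = y, x_hat = x_hat,
    sample_stats = smp$H, loglik_trace = trace,
    converged = converged, control = control, seed = seed,
    n = n), class = "gergm")
  fit$vcov <- vcov_estimate(fit)
  fit
}

#' Covariance of the GERGM estimates
#'
#' Negative inverse of the numerical Hessian of the approximated joint log
#' likelihood — the importance-sampling objective in \eqn{\theta} (fixed
#' final Monte Carlo sample) plus the marginal/Jacobian terms in
#' \eqn{\beta} — evaluated jointly at \eqn{(\hat\theta, \hat\beta)}.
#'
#' @param fit a fitted `gergm` object.
#' @param blockwise if `TRUE`, zero the cross block and invert the
#'   \eqn{\theta} and \eqn{\beta} blocks separately.
#' @return symmetric covariance matrix with parameter names.
#' @export
vcov_estimate <- function(fit, blockwise = FALSE) {
  spec <- fit$spec; model <- fit$model; design <- fit$design
  y <- fit$y; H <- fit$sample_stats
  theta_hat <- as.numeric(fit$theta)
  q <- length(theta_hat)
  pb <- n_beta(model, design)
  lse <- function(v) { mx <- max(v); mx + log(sum(exp(v - mx))) }

  joint <- function(par) {
    th <- par[seq_len(q)]
    mod <- if (pb > 0) beta_unpack(model, par[q + seq_len(pb)]) else model
    x <- to_restricted(y, mod, design)
    h <- compute_stats(x, spec)
    w <- drop(H %*% (th - theta_hat))
    sum(th * h) - (lse(w) - log(nrow(H))) +
      log_marginal_density(y, mod, design)
  }
  par <- c(theta_hat, beta_pack(model))
  Hs <- stats::optimHess(par, joint)
  Hs <- (Hs + t(Hs)) / 2

  nm <- c(names(fit$theta), beta_names(model, design))
  if (blockwise && pb > 0) {
    V <- matrix(0, q + pb, q + pb)
    V[seq_len(q), seq_len(q)] <- inv_neg_hess(
      Hs[seq_len(q), seq_len(q), drop = FALSE], nm[seq_len(q)])
    V[q + seq_len(pb), q + seq_len(pb)] <- inv_neg_hess(
      Hs[q + seq_len(pb), q + seq_len(pb), drop = FALSE], nm[q + seq_len(pb)])
  } else {
    V <- inv_neg_hess(Hs, nm)
  }
  dimnames(V) <- list(nm, nm)
  V
}

## Invert the negative Hessian.  Directions of non-negative curvature
## (weakly identified parameter combinations, e.g. near-collinearity of
## the density dependence term with the marginal location at small n, or
## Monte Carlo noise) are treated as carrying essentially no information:
## their curvature is capped at a small negative value, which yields very
## large variances along them instead of meaningless negative ones.
inv_neg_hess <- function(Hs, nm) {
  if (any(!is.finite(Hs))) {
    bad <- nm[unique(which(!is.finite(Hs), arr.ind = TRUE)[, 1L])]
    stop("Hessian is not finite; offending parameter block near '",
         paste(bad, collapse = "', '"), "'", call. = FALSE)
  }
  ev <- eigen(Hs, symmetric = TRUE)
  neg <- ev$values[ev$values < 0]
  if (length(neg) == 0L)
    stop("Hessian has no negative curvature; no parameter is identified",
         call. = FALSE)
  cap <- -1e-6 * max(-neg)
  vals <- pmin(ev$values, cap)
  V <- ev$vectors %*% (t(ev$vectors) / (-vals))
  V <- (V + t(V)) / 2
  attr(V, "flat_directions") <- sum(ev$values >= cap)
  V
}

#' Wald test of a block restriction
#'
#' Tests the restriction that a subset S of the parameters is zero:
#' \eqn{W = \hat\gamma_S' \hat V_{SS}^{-1} \hat\gamma_S \sim \chi^2_{|S|}}
#' under the null.  The canonical use is testing all dependence parameters
#' jointly against the nested independence regression.
#'
#' @param fit a fitted `gergm` object.
#' @param parameters indices or names of the tested parameters; defaults
#'   to all dependence parameters \eqn{\theta}.
#' @return list with `statistic`, `df`, `p.value`, `parameters`.
#' @export
wald_block_test <- function(fit, parameters = NULL) {
  est <- coef(fit)
  V <- fit$vcov
  if (is.null(parameters)) parameters <- names(fit$theta)
  if (is.character(parameters)) {
    idx <- match(parameters, names(est))
    if (anyNA(idx)) stop("unknown parameter(s): ",
                         paste(parameters[is.na(idx)], collapse = ", "),
                         call. = FALSE)
  } else idx <- as.integer(parameters)
  g <- est[idx]
  Vss <- V[idx, idx, drop = FALSE]
  Vinv <- tryCatch(solve(Vss), error = function(e)
    stop("singular sub-covariance for the tested block", call. = FALSE))
  W <- drop(t(g) %*% Vinv %*% g)
  df <- length(idx)
  list(statistic = W, df = df,
       p.value = stats::pchisq(W, df, lower.tail = FALSE),
       parameters = names(est)[idx])
}

#' Likelihood-ratio test between two nested GERGM fits
#'
#' Twice the difference of the approximated log likelihoods at the last
#' iteration.  The approximation is Monte Carlo noisy; the Wald test
#' ([wald_block_test()]) is usually preferable.
#'
#' @param full,reduced fitted `gergm` objects on the same data, `reduced`
#'   nested in `full`.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
lr_block_test <- function(full, reduced) {
  ll <- function(f) f$loglik_trace$loglik[nrow(f$loglik_trace)]
  df <- (length(coef(full)) - length(coef(reduced)))
  if (df <= 0) stop("'reduced' must have fewer parameters", call. = FALSE)
  stat <- 2 * (ll(full) - ll(reduced))
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}
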