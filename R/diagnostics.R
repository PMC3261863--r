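#' Geweke convergence diagnostic
#'
#' Compares the means of two non-overlapping windows of a Markov chain,
#' one early and one late:
#' \deqn{z = \frac{\bar g_A - \bar g_B}{\sqrt{S_A/n_A + S_B/n_B}},}
#' where \eqn{S} is the spectral density of the window at frequency zero
#' (estimated by an autoregressive fit, which accounts for the chain's
#' autocorrelation).  Under convergence z is asymptotically standard
#' normal; \eqn{|z| > 2} conventionally flags non-convergence.
#'
#' @param series numeric chain (length >= 100).
#' @param first_frac fraction of the series in the early window
#'   (default 0.1).
#' @param last_frac fraction in the late window (default 0.5).
#' @return the z statistic.
#' @export
geweke_z <- function(series, first_frac = 0.1, last_frac = 0.5) {
  series <- as.numeric(series)
  len <- length(series)
  if (len < 100L) stop("series too short for the Geweke diagnostic ",
                       "(need >= 100)", call. = FALSE)
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac >= 1)
    stop("windows must be non-overlapping: first_frac + last_frac < 1",
         call. = FALSE)
  na <- floor(first_frac * len)
  nb <- floor(last_frac * len)
  A <- series[seq_len(na)]
  B <- series[seq.int(len - nb + 1L, len)]
  sa <- spectrum0_ar(A)
  sb <- spectrum0_ar(B)
  if (sa <= 0 || sb <= 0)
    stop("degenerate (constant) window: spectral density at zero is 0",
         call. = FALSE)
  (mean(A) - mean(B)) / sqrt(sa / na + sb / nb)
}

## spectral density at frequency zero via an AIC-selected AR fit:
## S(0) = sigma^2 / (1 - sum(phi))^2
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(length(x) - 1L,
                                             floor(10 * log10(length(x))))),
    error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Gelman-Rubin shrink factor
#'
#' Potential scale reduction over parallel chains started from
#' overdispersed points.  With m chains of length n, the within-chain
#' variance \eqn{W} is the mean of the chain variances and the
#' between-chain variance is \eqn{B = n \,\mathrm{var}(\bar x_k)}.  The
#' pooled variance estimate is \eqn{\hat\sigma^2 = \frac{n-1}{n} W +
#' \frac{B}{n}} and the shrink factor \eqn{\hat R =
#' \sqrt{\hat\sigma^2 / W}}; values at or above about 1.1 indicate
#' non-convergence.
#'
#' @param chains list of numeric chains of equal length (>= 2 chains,
#'   length >= 10).
#' @param corrected if `TRUE`, include the sampling-variability inflation
#'   \eqn{(m+1)/m} on the between term.
#' @return the shrink factor \eqn{\hat R}.
#' @export
gelman_rubin <- function(chains, corrected = FALSE) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains", call. = FALSE)
  len <- lengths(chains)
  if (length(unique(len)) != 1L)
    stop("chains must have equal length", call. = FALSE)
  n <- len[1L]
  if (n < 10L) stop("chains too short (need length >= 10)", call. = FALSE)
  m <- length(chains)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) stop("zero within-chain variance", call. = FALSE)
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sigma2 <- (n - 1) / n * W + B / n
  if (corrected) sigma2 <- sigma2 + B / (n * m)
  sqrt(sigma2 / W)
}

#' Degeneracy and convergence report for simulated GERGM chains
#'
#' A GERGM is degenerate when its simulated networks pile up near the
#' full or the empty graph.  The report flags degeneracy when the grand
#' mean edge value across chains is closer to 0 or to 1 than to the mean
#' of the observed network, and summarizes convergence: the Geweke z per
#' chain (with the share beyond 1.96, nominally 5%), and, given at least
#' two chains, the Gelman-Rubin factor per edge series (or for the mean
#' trace) with the count at or above 1.1.
#'
#' @param chains list of per-sweep mean-edge-value traces (one per chain),
#'   or a list of sampler outputs from [simulate_restricted()].
#' @param observed_mean mean edge value of the observed restricted
#'   network.
#' @param edge_series optional list (one per chain) of m x sweeps matrices
#'   of per-edge traces for per-edge diagnostics; thinned as supplied.
#' @return object of class `degeneracy_report`: list with `degenerate`,
#'   `grand_mean`, `geweke` (per chain), `geweke_share_gt2`,
#'   `gelman_rubin` (per edge, or `NA` with a note if a single chain),
#'   `n_rhat_ge_1.1`.
#' @export
degeneracy_report <- function(chains, observed_mean,
                              edge_series = NULL) {
  if (!is.list(chains)) chains <- list(chains)
  chains <- lapply(chains, function(ch)
    if (is.list(ch) && !is.null(ch$mean_trace)) ch$mean_trace
    else as.numeric(ch))
  if (length(chains) < 1L) stop("need at least one chain", call. = FALSE)
  if (!is.finite(observed_mean) || observed_mean <= 0 ||
      observed_mean >= 1)
    stop("'observed_mean' must lie in (0,1)", call. = FALSE)

  grand <- mean(unlist(chains))
  degenerate <- min(grand, 1 - grand) < abs(grand - observed_mean)

  gz <- vapply(chains, function(ch)
    tryCatch(geweke_z(ch), error = function(e) NA_real_), numeric(1))
  share <- mean(abs(gz) > 1.96, na.rm = TRUE)

  rhat <- NA_real_; n_bad <- NA_integer_; rhat_note <- NULL
  if (!is.null(edge_series) && length(edge_series) >= 2L) {
    m_edges <- nrow(edge_series[[1L]])
    rhat <- vapply(seq_len(m_edges), function(e)
      gelman_rubin(lapply(edge_series, function(s) s[e, ])), numeric(1))
    n_bad <- sum(rhat >= 1.1)
  } else if (length(chains) >= 2L) {
    rhat <- gelman_rubin(chains)
    n_bad <- sum(rhat >= 1.1)
  } else {
    rhat_note <- "Gelman-Rubin unavailable: a single chain was supplied"
  }

  structure(list(degenerate = degenerate, grand_mean = grand,
                 observed_mean = observed_mean, geweke = gz,
                 geweke_share_gt2 = share, gelman_rubin = rhat,
                 n_rhat_ge_1.1 = n_bad, rhat_note = rhat_note),
            class = "degeneracy_report")
}

#' @export
print.degeneracy_report <- function(x, ...) {
  cat("GERGM degeneracy / convergence report\n")
  cat(sprintf("  grand mean edge value: %.4f (observed %.4f) -> %s\n",
              x$grand_mean, x$observed_mean,
              if (x$degenerate) "DEGENERATE" else "not degenerate"))
  cat(sprintf("  Geweke |z| > 1.96 share: %.3f (chains: %s)\n",
              x$geweke_share_gt2,
              paste(format(x$geweke, digits = 3), collapse = ", ")))
  if (!is.null(x$rhat_note)) cat(" ", x$rhat_note, "\n")
  else cat(sprintf("  Gelman-Rubin >= 1.1: %d of %d\n",
                   x$n_rhat_ge_1.1, length(x$gelman_rubin)))
  invisible(x)
}

#' Simulation-based goodness of fit for the dependence structure
#'
#' Simulates `nsim` restricted networks from the fitted dependence model
#' and compares each statistic's simulated distribution to its value on
#' the estimated restricted network \eqn{\hat x = F(y \mid \hat\beta)}.
#' A feature is adequately captured when the observed value falls inside
#' the simulated inter-quartile range.
#'
#' @param fit a fitted `gergm`.
#' @param nsim number of simulated networks (> 0).
#' @param seed optional seed.
#' @param burnin,thin Gibbs settings for the simulation.
#' @return list with `observed` (statistics on \eqn{\hat x}), `simulated`
#'   (nsim x q matrix), `percentile` of the observed value in the
#'   simulated distribution, and `in_iqr` flags.
#' @export
gof_dependence <- function(fit, nsim = 1000L, seed = NULL,
                           burnin = 100L, thin = 2L) {
  nsim <- as.integer(nsim)
  if (nsim < 1L) stop("'nsim' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cfg <- gibbs_config(sweeps = burnin + nsim * thin, burnin = burnin,
                      thin = thin, init = as_edge_matrix(fit$x_hat))
  sim <- simulate_restricted(fit$theta, fit$spec, fit$n, cfg)
  q <- length(fit$spec$names)
  sims <- t(vapply(sim$networks, compute_stats, numeric(q),
                   spec = fit$spec))
  if (q == 1L) sims <- matrix(sims, ncol = 1L)
  colnames(sims) <- fit$spec$names
  obs <- compute_stats(fit$x_hat, fit$spec)
  pct <- vapply(seq_len(q), function(k) mean(sims[, k] <= obs[k]),
                numeric(1))
  iqr <- vapply(seq_len(q), function(k) {
    qs <- stats::quantile(sims[, k], c(.25, .75))
    obs[k] >= qs[1] && obs[k] <= qs[2]
  }, logical(1))
  names(pct) <- names(iqr) <- fit$spec$names
  list(observed = obs, simulated = sims, percentile = pct, in_iqr = iqr)
}
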