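#' Gibbs sampler configuration
#'
#' Controls the Gibbs sampler over restricted networks.  In every sweep
#' each of the \eqn{n(n-1)} directed edges is redrawn once from its exact
#' full conditional.  The default burn-in of 10,000 sweeps matches the
#' diagnostic setup used for the chain-convergence checks; simulation for
#' estimation typically uses far shorter chains (set explicitly).
#'
#' @param sweeps total full sweeps.
#' @param burnin sweeps discarded before retention.
#' @param thin keep every `thin`-th network after burn-in.
#' @param init `"uniform"` (iid U(0,1) start), `"dispersed"` (U-shaped
#'   Beta(1/2, 1/2) start, the overdispersed start for multi-chain
#'   diagnostics), or a restricted network / matrix to start from.
#' @param random_scan update edges in random order instead of the fixed
#'   row-major enumeration.
#' @export
gibbs_config <- function(sweeps = 1000L, burnin = 10000L, thin = 1L,
                         init = "uniform", random_scan = FALSE) {
  stopifnot(sweeps >= 0, burnin >= 0, thin >= 1)
  structure(list(sweeps = as.integer(sweeps), burnin = as.integer(burnin),
                 thin = as.integer(thin), init = init,
                 random_scan = isTRUE(random_scan)),
            class = "gibbs_config")
}

## tolerance below which the conditional is treated as exactly uniform
DRAW_TOL <- 1e-8

#' Linear coefficient of an edge's full conditional
#'
#' Holding all other edges fixed, \eqn{\theta'h(x)} is affine in
#' \eqn{x_{ij}} with slope \eqn{a = \theta' \Delta_{ij} h}, so the full
#' conditional density of the edge is proportional to \eqn{e^{a x}} on
#' (0,1) — a truncated exponential.
#'
#' @inheritParams edge_delta
#' @param theta dependence parameters, one per statistic in `spec`.
#' @return scalar coefficient a.
#' @export
conditional_coefficient <- function(x, theta, spec, i, j) {
  spec <- as_stat_spec(spec)
  if (length(theta) != length(spec$names))
    stop("length(theta) must equal the number of statistics",
         call. = FALSE)
  sum(theta * edge_delta(x, spec, i, j))
}

#' Inverse-CDF draw from a truncated-exponential conditional
#'
#' Transforms uniform variates through the inverse CDF of the density
#' \eqn{a e^{ax}/(e^a - 1)} on (0,1):
#' \eqn{x = \log\{1 + u(e^a - 1)\}/a}.  When \eqn{|a|} is below `tol` the
#' density degenerates to the uniform and `u` is returned unchanged; for
#' large positive `a` the expression is evaluated in log space to avoid
#' overflow of \eqn{e^a}.
#'
#' @param a conditional coefficient(s); recycled against `u`.
#' @param u uniform(0,1) variates.
#' @param tol uniform-limit threshold.
#' @return draws in (0,1), same length as `u`.
#' @export
draw_edge <- function(a, u, tol = DRAW_TOL) {
  if (any(u <= 0 | u >= 1))
    stop("'u' must lie strictly in (0,1)", call. = FALSE)
  k <- max(length(a), length(u))
  cpp_draw_edge(rep_len(as.numeric(a), k), rep_len(as.numeric(u), k), tol)
}

## mean of the truncated exponential on (0,1) with coefficient a
trunc_exp_mean <- function(a) {
  out <- numeric(length(a))
  small <- abs(a) < 1e-5
  out[small] <- 0.5 + a[small] / 12
  pos <- !small & a > 0
  neg <- !small & a < 0
  out[pos] <- 1 / (1 - exp(-a[pos])) - 1 / a[pos]
  out[neg] <- exp(a[neg]) / (exp(a[neg]) - 1) - 1 / a[neg]
  out
}

## log of the normalizing constant (e^a - 1)/a of exp(a x) on (0,1)
log_trunc_exp_norm <- function(a) {
  out <- numeric(length(a))
  small <- abs(a) < 1e-5
  out[small] <- log1p(a[small] / 2 + a[small]^2 / 24)
  pos <- !small & a > 0
  neg <- !small & a < 0
  out[pos] <- a[pos] + log1p(-exp(-a[pos])) - log(a[pos])
  out[neg] <- log1p(-exp(a[neg])) - log(-a[neg])
  out
}

init_network <- function(init, n) {
  if (is.matrix(init) || inherits(init, "valued_network")) {
    m <- as_edge_matrix(init)
    if (nrow(m) != n) stop("init network has wrong size", call. = FALSE)
    return(clamp01(m) * (1 - diag(n)))
  }
  v <- switch(init,
    uniform   = runif(n * n),
    dispersed = rbeta(n * n, 0.5, 0.5),
    stop("unknown init '", init, "'", call. = FALSE))
  m <- matrix(clamp01(v), n, n)
  diag(m) <- 0
  m
}

#' One Gibbs sweep over all edges
#'
#' Resamples every off-diagonal edge once from its full conditional in the
#' fixed row-major edge order (or a random scan), using the current values
#' of all other edges.  Uses R's RNG stream.
#'
#' @param x restricted network (or matrix).
#' @inheritParams conditional_coefficient
#' @param random_scan see [gibbs_config()].
#' @return a `restricted_network` after one sweep.
#' @export
gibbs_sweep <- function(x, theta, spec, random_scan = FALSE) {
  spec <- as_stat_spec(spec)
  m <- as_edge_matrix(x)
  out <- cpp_gibbs_sweep(m, as.numeric(theta), stat_codes(spec),
                         spec$scaling, random_scan, DRAW_TOL)
  restricted_network(out + diag(nrow(out)) * 0)
}

#' Simulate restricted networks from a GERGM dependence model
#'
#' Runs the Gibbs sampler for the exponential family with statistics
#' `spec` and parameters `theta` on `n` vertices, returning the retained
#' networks plus per-sweep traces (mean edge value and statistic vector)
#' for convergence and degeneracy diagnostics.
#'
#' @param theta dependence parameters.
#' @param spec a [stat_spec()] or character vector.
#' @param n vertex count (>= 2).
#' @param config a [gibbs_config()].
#' @return list with elements
#'   \describe{
#'     \item{`networks`}{list of `restricted_network` objects,}
#'     \item{`draws`}{m x kept matrix of edge vectors (enumeration order),}
#'     \item{`mean_trace`}{per-sweep mean edge value,}
#'     \item{`stat_trace`}{kept-by-q matrix of per-sweep statistics,}
#'     \item{`final`}{final state of the chain.}
#'   }
#' @examples
#' set.seed(1)
#' sim <- simulate_restricted(c(edge_sum = -1), "edge_sum", n = 5,
#'                            gibbs_config(sweeps = 50, burnin = 10))
#' @export
simulate_restricted <- function(theta, spec, n,
                                config = gibbs_config()) {
  spec <- as_stat_spec(spec)
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  if (length(theta) != length(spec$names))
    stop("length(theta) must equal the number of statistics",
         call. = FALSE)
  init <- init_network(config$init, n)
  run <- cpp_gibbs_run(init, as.numeric(theta), stat_codes(spec),
                       spec$scaling, config$sweeps, config$burnin,
                       config$thin, config$random_scan, DRAW_TOL)
  draws <- run$draws
  nets <- lapply(seq_len(ncol(draws)), function(k)
    restricted_network(edge_matrix(draws[, k], n, diag = 0)))
  list(networks = nets, draws = draws,
       mean_trace = as.numeric(run$mean_trace),
       stat_trace = t(run$stat_trace),
       final = restricted_network(run$final + 0), spec = spec,
       theta = as.numeric(theta))
}

#' Simulate observed networks from a full GERGM
#'
#' Simulates restricted networks with [simulate_restricted()] and maps
#' each onto the observed support with [to_observed()].
#'
#' @inheritParams simulate_restricted
#' @inheritParams to_observed
#' @return as [simulate_restricted()], with an extra element `observed`, a
#'   list of `valued_network` objects.
#' @export
simulate_observed <- function(theta, spec, model, design = NULL, n,
                              config = gibbs_config()) {
  sim <- simulate_restricted(theta, spec, n, config)
  if (is.null(design)) design <- intercept_design(n)
  sim$observed <- lapply(sim$networks, to_observed,
                         model = model, design = design)
  sim
}
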