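#' Synthetic GERGM scenarios
#'
#' Named, fully reproducible data-generating scenarios used throughout the
#' tests and examples: each simulates one observed network from a stated
#' truth (long-run Gibbs on the restricted network, then the marginal
#' transformation) and returns the data together with the generating
#' parameters, so estimator-recovery checks can compare against the truth.
#'
#' Scenarios:
#' \describe{
#'   \item{`two_vertex_reciprocity`}{2 vertices, negative density and
#'     positive reciprocity (`edge_sum` = -2, `reciprocity` = 2),
#'     standard-normal marginal.  The two-edge joint density is cheap to
#'     integrate numerically, making this the exactness benchmark for the
#'     sampler.}
#'   \item{`gaussian_recovery`}{15 vertices, `edge_sum` = -0.5,
#'     `reciprocity` = 0.8, Gaussian marginal with two nodal covariates
#'     (standard-normal attribute expanded to sender and receiver
#'     columns), eta = (1, 0.5, -0.5), alpha = 1.}
#'   \item{`heavy_tail_flows`}{20 vertices, Cauchy marginal with sender /
#'     receiver covariates and anti-reciprocal dependence
#'     (`edge_sum` = 0.5, `reciprocity` = -0.8) — a miniature of a
#'     heavy-tailed flow-change network.}
#' }
#' All truths sit inside the non-degenerate parameter region for their
#' network size.
#'
#' @param name scenario name.
#' @param seed integer seed; a scenario regenerates identically from
#'   `(name, seed)`.
#' @param burnin Gibbs sweeps run before the single retained network.
#' @return list with `network` (observed `valued_network`), `restricted`
#'   (the latent network it was transformed from), `design`, `model`,
#'   `spec`, `theta` (the generating dependence parameters).
#' @export
make_scenario <- function(name = c("two_vertex_reciprocity",
                                   "gaussian_recovery",
                                   "heavy_tail_flows"),
                          seed = 1L, burnin = 2000L) {
  name <- match.arg(name)
  set.seed(seed)
  sc <- switch(name,
    two_vertex_reciprocity = list(
      n = 2L, theta = c(edge_sum = -2, reciprocity = 2),
      model = marginal_model("gaussian", eta = 0, alpha = 1),
      attributes = NULL, expand = NULL),
    gaussian_recovery = list(
      n = 15L, theta = c(edge_sum = -0.5, reciprocity = 0.8),
      model = marginal_model("gaussian", eta = c(1, 0.5, -0.5),
                             alpha = 1),
      attributes = data.frame(u = stats::rnorm(15)),
      expand = list(u = c("sender", "receiver"))),
    heavy_tail_flows = list(
      n = 20L, theta = c(edge_sum = 0.5, reciprocity = -0.8),
      model = marginal_model("cauchy", eta = c(0, 1, -1), alpha = 2),
      attributes = data.frame(u = stats::rnorm(20)),
      expand = list(u = c("sender", "receiver"))))

  design <- if (is.null(sc$attributes)) intercept_design(sc$n)
            else node_design(sc$attributes, sc$expand, n = sc$n)
  spec <- stat_spec(names(sc$theta))
  cfg <- gibbs_config(sweeps = burnin + 1L, burnin = burnin, thin = 1L)
  sim <- simulate_restricted(sc$theta, spec, sc$n, cfg)
  x <- sim$networks[[1L]]
  y <- to_observed(x, sc$model, design)
  list(network = y, restricted = x, design = design, model = sc$model,
       spec = spec, theta = sc$theta, name = name, seed = seed)
}

#' Dependence summaries of simulated network sets
#'
#' Behavioural summaries of what each dependence statistic does to
#' simulated networks, as functions of its parameter:
#' `dyad_correlation()` is the Pearson correlation between the two edges
#' of a dyad, pooled over all dyads and networks (reciprocity);
#' `indegree_variance()` is the variance across vertices of the in-degree
#' (column sums), averaged over networks (in-two-stars);
#' `third_edge_mean_surface()` bins the values of two edges of a
#' transitive triad and reports the mean value of the closing third edge
#' per bin (transitivity).
#'
#' @param networks list of `restricted_network` objects (>= 2).
#' @return `dyad_correlation`, `indegree_variance`: a scalar.
#'   `third_edge_mean_surface`: a `breaks` x `breaks` matrix of
#'   conditional means of \eqn{x_{ik}} given bins of
#'   \eqn{(x_{ij}, x_{jk})}.
#' @export
dyad_correlation <- function(networks) {
  check_netlist(networks)
  n <- nrow(networks[[1L]])
  ut <- which(upper.tri(matrix(0, n, n)))
  a <- unlist(lapply(networks, function(x) as_edge_matrix(x)[ut]))
  b <- unlist(lapply(networks, function(x) t(as_edge_matrix(x))[ut]))
  stats::cor(a, b)
}

#' @rdname dyad_correlation
#' @export
indegree_variance <- function(networks) {
  check_netlist(networks)
  mean(vapply(networks, function(x)
    stats::var(colSums(as_edge_matrix(x))), numeric(1)))
}

#' @rdname dyad_correlation
#' @param breaks number of bins per axis.
#' @export
third_edge_mean_surface <- function(networks, breaks = 5L) {
  check_netlist(networks)
  n <- nrow(networks[[1L]])
  tri <- ordered_triples(n)
  acc <- matrix(0, breaks, breaks)
  cnt <- matrix(0, breaks, breaks)
  edges <- function(m, ij) m[cbind(ij[, 1L], ij[, 2L])]
  for (x in networks) {
    m <- as_edge_matrix(x)
    a <- edges(m, tri[, c(1L, 2L)])   # x_ij
    b <- edges(m, tri[, c(2L, 3L)])   # x_jk
    cc <- edges(m, tri[, c(1L, 3L)])  # x_ik, the closing edge
    ia <- pmin(pmax(ceiling(a * breaks), 1L), breaks)
    ib <- pmin(pmax(ceiling(b * breaks), 1L), breaks)
    for (k in seq_along(a)) {
      acc[ia[k], ib[k]] <- acc[ia[k], ib[k]] + cc[k]
      cnt[ia[k], ib[k]] <- cnt[ia[k], ib[k]] + 1
    }
  }
  out <- acc / cnt
  dimnames(out) <- list(x_ij = seq_len(breaks), x_jk = seq_len(breaks))
  out
}

check_netlist <- function(networks) {
  if (!is.list(networks) || length(networks) < 2L)
    stop("need a list of at least 2 networks", call. = FALSE)
  invisible(TRUE)
}

ordered_triples <- function(n) {
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  g <- g[g$i != g$j & g$j != g$k & g$i != g$k, ]
  as.matrix(g[, c("i", "j", "k")])
}

#' Simulate a dependence-parameter grid
#'
#' For a single dependence statistic, simulates `nsim` restricted
#' networks at each value of a parameter grid and returns the relevant
#' behavioural summary per grid point — the simulation experiment that
#' shows each statistic's parameter produces its intended network
#' feature (dyadic correlation for `reciprocity`, in-degree variance for
#' `in_two_stars` / `out_two_stars`, mean edge value otherwise).
#'
#' @param statistic one statistic name.
#' @param grid numeric parameter values.
#' @param n vertex count.
#' @param nsim networks per grid point.
#' @param burnin,thin Gibbs settings per grid point.
#' @return data frame with columns `theta`, `summary`, `mean_edge`.
#' @export
dependence_grid <- function(statistic, grid, n = 25L, nsim = 1000L,
                            burnin = 100L, thin = 2L) {
  stopifnot(length(statistic) == 1L)
  spec <- stat_spec(statistic)
  out <- lapply(grid, function(th) {
    cfg <- gibbs_config(sweeps = burnin + nsim * thin, burnin = burnin,
                        thin = thin)
    sim <- simulate_restricted(th, spec, n, cfg)
    s <- switch(statistic,
      reciprocity = dyad_correlation(sim$networks),
      in_two_stars = indegree_variance(sim$networks),
      out_two_stars = mean(vapply(sim$networks, function(x)
        stats::var(rowSums(as_edge_matrix(x))), numeric(1))),
      mean(unlist(lapply(sim$networks, edge_vector))))
    data.frame(theta = th, summary = s,
               mean_edge = mean(sim$draws))
  })
  do.call(rbind, out)
}
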