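#' Network dependence statistics
#'
#' A statistic specification is an ordered set of named dependence
#' statistics \eqn{h_1, \dots, h_q}, each a sum of products of edge values
#' over small subgraphs of the restricted network.  Because every edge
#' enters each product to the first power at most, each statistic is
#' multilinear in the edges, which yields truncated-exponential full
#' conditionals and closed-form per-edge coefficients.
#'
#' Available statistics (directed network, edges \eqn{x_{ij} \in (0,1)}):
#' \describe{
#'   \item{`edge_sum`}{\eqn{\sum_{i \ne j} x_{ij}} — overall density.}
#'   \item{`reciprocity`}{\eqn{\sum_{i<j} x_{ij} x_{ji}} — dyadic exchange.}
#'   \item{`transitive_triads`}{\eqn{\sum x_{ij} x_{jk} x_{ik}} over ordered
#'     distinct triples (six terms per unordered triple) — clustering.}
#'   \item{`cyclic_triads`}{both directed three-cycles per unordered triple
#'     — generalized reciprocity through a third vertex.}
#'   \item{`in_two_stars`}{\eqn{\sum_j \sum_{i<k} x_{ij} x_{kj}} — shared
#'     receivers; degree heterogeneity of inflows.}
#'   \item{`out_two_stars`}{\eqn{\sum_i \sum_{j<k} x_{ij} x_{ik}} — shared
#'     senders.}
#' }
#'
#' @param names character vector of statistic names, a subset of
#'   [gergm_statistics()]; order fixes the order of the parameter vector
#'   \eqn{\theta}.
#' @param scaling positive divisor applied per statistic (default 1, i.e.
#'   unnormalized counts); recycled.
#' @return an object of class `stat_spec`.
#' @examples
#' spec <- stat_spec(c("edge_sum", "reciprocity"))
#' x <- restricted_network(matrix(.5, 3, 3))
#' compute_stats(x, spec)
#' @export
stat_spec <- function(names, scaling = 1) {
  names <- as.character(names)
  if (length(names) == 0L) stop("at least one statistic is required",
                                call. = FALSE)
  unknown <- setdiff(names, gergm_statistics())
  if (length(unknown))
    stop("unknown statistic(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names))
    stop("statistic names must be unique", call. = FALSE)
  scaling <- rep_len(as.numeric(scaling), length(names))
  if (any(!is.finite(scaling)) || any(scaling <= 0))
    stop("'scaling' must be positive", call. = FALSE)
  structure(list(names = names, scaling = scaling), class = "stat_spec")
}

#' @rdname stat_spec
#' @export
gergm_statistics <- function() {
  c("edge_sum", "reciprocity", "transitive_triads", "cyclic_triads",
    "in_two_stars", "out_two_stars")
}

## integer codes passed to the C++ kernels; order matches gergm_statistics()
stat_codes <- function(spec) {
  match(spec$names, gergm_statistics()) - 1L
}

as_stat_spec <- function(spec) {
  if (inherits(spec, "stat_spec")) spec else stat_spec(spec)
}

#' @export
print.stat_spec <- function(x, ...) {
  cat("Dependence statistics (", length(x$names), "):\n", sep = "")
  for (k in seq_along(x$names))
    cat(sprintf("  %-18s scaling %g\n", x$names[k], x$scaling[k]))
  invisible(x)
}

## statistics that are undefined once direction collapses
directed_only_statistics <- function() {
  c("reciprocity", "transitive_triads", "cyclic_triads")
}

check_spec_network <- function(spec, x) {
  if (inherits(x, "valued_network") && !is_directed(x)) {
    bad <- intersect(spec$names, directed_only_statistics())
    if (length(bad))
      stop("statistic(s) undefined for undirected networks: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Compute the dependence-statistic vector h(x)
#'
#' Evaluates every statistic in `spec` on a restricted network and divides
#' by the per-statistic scaling.  All statistics are finite for any network
#' with edges in the unit interval (each subgraph product is at most 1).
#'
#' @param x a `restricted_network` (or a square numeric matrix taken as
#'   one, diagonal ignored).
#' @param spec a [stat_spec()] or character vector of statistic names.
#' @return named numeric vector, one entry per statistic.
#' @export
compute_stats <- function(x, spec) {
  spec <- as_stat_spec(spec)
  check_spec_network(spec, x)
  m <- as_edge_matrix(x)
  h <- cpp_compute_stats(m, stat_codes(spec)) / spec$scaling
  names(h) <- spec$names
  h
}

#' Per-edge statistic change scores
#'
#' By multilinearity, each statistic is affine in any single edge:
#' \eqn{h(x) = a \cdot x_{ij} + c} holding all other edges fixed.  This
#' returns the slope vector \eqn{h(x_{ij}{=}1) - h(x_{ij}{=}0)} per
#' statistic in closed form, the quantity that drives the
#' truncated-exponential full conditional of edge (i, j).
#'
#' @inheritParams compute_stats
#' @param i,j sender and receiver vertex indices (1-based), `i != j`.
#' @return named numeric vector of change scores (scaled like
#'   [compute_stats()]).
#' @export
edge_delta <- function(x, spec, i, j) {
  spec <- as_stat_spec(spec)
  check_spec_network(spec, x)
  n <- nrow(x)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("self-loop (i == j) has no edge delta", call. = FALSE)
  if (i < 1L || j < 1L || i > n || j > n)
    stop("vertex index out of range", call. = FALSE)
  m <- as_edge_matrix(x)
  d <- cpp_edge_delta(m, stat_codes(spec), i - 1L, j - 1L) / spec$scaling
  names(d) <- spec$names
  d
}

#' Number of subgraph configurations counted by a statistic
#'
#' Upper bound of the unscaled statistic on a network with all edges at 1;
#' usable as the `scaling` divisor to make statistics comparable across
#' network sizes.
#'
#' @param names statistic names.
#' @param n vertex count.
#' @export
stat_config_counts <- function(names, n) {
  n <- as.numeric(n)
  counts <- c(
    edge_sum          = n * (n - 1),
    reciprocity       = n * (n - 1) / 2,
    transitive_triads = n * (n - 1) * (n - 2),
    cyclic_triads     = n * (n - 1) * (n - 2) / 3,
    in_two_stars      = n * choose(n - 1, 2),
    out_two_stars     = n * choose(n - 1, 2)
  )
  counts[names]
}
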