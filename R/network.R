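#' Construct a valued network from an adjacency matrix
#'
#' A valued network is an \eqn{n \times n} real adjacency matrix whose
#' off-diagonal entries are continuous edge values on an arbitrary support
#' (flows, correlations, intensities).  Diagonal entries (self-loops) are
#' undefined and ignored by every computation in the package.
#'
#' @param values square numeric matrix of edge values; off-diagonal entries
#'   must be finite.  The diagonal is set to `NA`.
#' @param directed logical; if `FALSE` the matrix must be symmetric (within
#'   `tol`) and only the upper triangle carries information.
#' @param labels optional character vector of vertex labels; defaults to the
#'   matrix dimnames or `V1..Vn`.
#' @param tol symmetry tolerance for undirected networks.
#' @return an object of class `valued_network`: the matrix with attributes
#'   `directed` and vertex labels as dimnames.
#' @examples
#' y <- valued_network(matrix(c(0, .3, .7, 0), 2, 2, byrow = TRUE))
#' n_edges(y)
#' @seealso [restricted_network()], [read_network()]
#' @export
valued_network <- function(values, directed = TRUE, labels = NULL,
                           tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  n <- nrow(values)
  if (ncol(values) != n)
    stop("adjacency matrix must be square, got ", n, "x", ncol(values),
         call. = FALSE)
  if (n < 2L)
    stop("a network needs at least 2 vertices", call. = FALSE)
  off <- values[row(values) != col(values)]
  if (any(!is.finite(off)))
    stop("all off-diagonal edge values must be finite", call. = FALSE)
  if (!directed) {
    d <- abs(values - t(values))
    d[!is.finite(d)] <- 0
    if (max(d[row(d) != col(d)]) > tol)
      stop("matrix declared undirected but is asymmetric ",
           "(max |y_ij - y_ji| = ", format(max(d)), ")", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("V", seq_len(n))
  }
  if (length(labels) != n)
    stop("'labels' must have length n = ", n, call. = FALSE)
  diag(values) <- NA_real_
  dimnames(values) <- list(labels, labels)
  structure(values, directed = isTRUE(directed), class = "valued_network")
}

#' @export
print.valued_network <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Valued %s network: %d vertices, %d edges\n",
              if (is_directed(x)) "directed" else "undirected", n,
              n_edges(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a restricted (unit-interval) network
#'
#' The restricted network is the latent object on which network dependence
#' is modelled: same shape as a valued network, but every off-diagonal entry
#' lies strictly inside (0, 1).  It arises as the joint quantiles of the
#' observed edges under the marginal model.  Values are clamped to
#' `[1e-10, 1 - 1e-10]` so that CDF transforms that hit machine 0 or 1
#' remain usable.
#'
#' @param values square numeric matrix with off-diagonal entries in `[0, 1]`.
#' @inheritParams valued_network
#' @return an object of classes `restricted_network` and `valued_network`.
#' @export
restricted_network <- function(values, directed = TRUE, labels = NULL) {
  off <- values[row(values) != col(values)]
  if (any(!is.finite(off)) || any(off < 0) || any(off > 1))
    stop("restricted-network edges must lie in [0, 1]", call. = FALSE)
  x <- valued_network(clamp01(values), directed = directed, labels = labels)
  class(x) <- c("restricted_network", class(x))
  x
}

## clamping policy: keep transformed edges strictly inside (0,1)
CLAMP_EPS <- 1e-10

clamp01 <- function(v) pmin(pmax(v, CLAMP_EPS), 1 - CLAMP_EPS)

#' @rdname valued_network
#' @param x a network object.
#' @export
is_directed <- function(x) isTRUE(attr(x, "directed"))

#' @rdname valued_network
#' @export
n_vertices <- function(x) nrow(x)

#' Number of (ordered) edges in a network
#'
#' `n(n-1)` for a directed network, `n(n-1)/2` otherwise.
#' @param x a network object or vertex count.
#' @param directed used when `x` is a plain vertex count.
#' @export
n_edges <- function(x, directed = TRUE) {
  if (inherits(x, "valued_network")) {
    n <- nrow(x); directed <- is_directed(x)
  } else n <- as.integer(x)
  if (directed) n * (n - 1L) else n * (n - 1L) %/% 2L
}

#' Edge enumeration for directed networks
#'
#' Edges are enumerated row-major over ordered pairs: (1,2), (1,3), ...,
#' (1,n), (2,1), (2,3), ..., (n,n-1).  Every per-edge vector in the package
#' (covariate rows, locations, quantiles) follows this order.
#'
#' @param n vertex count.
#' @return integer matrix with columns `i` (sender) and `j` (receiver).
#' @export
edge_index <- function(n) {
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  keep <- i != j
  cbind(i = i[keep], j = j[keep])
}

## extract / insert the off-diagonal entries in enumeration order
edge_vector <- function(m) {
  idx <- edge_index(nrow(m))
  m[cbind(idx[, 1L], idx[, 2L])]
}

edge_matrix <- function(v, n, diag = NA_real_) {
  m <- matrix(diag, n, n)
  idx <- edge_index(n)
  m[cbind(idx[, 1L], idx[, 2L])] <- v
  m
}

## strip classes/attributes, zero the diagonal: the numeric workhorse form
as_edge_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "directed") <- NULL
  diag(m) <- 0
  m
}
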