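#' Marginal transformation families
#'
#' The observed network is a monotone, parameterized, edgewise
#' transformation \eqn{y_{ij} = T(x_{ij})} of the restricted network.  Here
#' \eqn{T} is a quantile function, so \eqn{x_{ij} = F(y_{ij})} is the
#' marginal CDF of the edge, and the Jacobian of the change of variables is
#' the diagonal matrix of marginal densities.  Three families are built in:
#'
#' \describe{
#'   \item{`gaussian`}{\eqn{y \sim N(\mu_{ij}, \alpha^2)}; unbounded
#'     support, edge location \eqn{\mu_{ij} = z_{ij}'\eta} a linear
#'     function of edge covariates, shared scale \eqn{\alpha}.  With no
#'     dependence (\eqn{\theta = 0}) the model is exactly the linear
#'     regression model on the edges.}
#'   \item{`cauchy`}{location-scale Cauchy with density
#'     \eqn{f(y) = 1/\{\pi\alpha(1 + ((y-\mu)/\alpha)^2)\}}; heavy-tailed
#'     unbounded support.  With \eqn{\theta = 0}: Cauchy regression.}
#'   \item{`interval`}{linear map from fixed bounds `(a, b)` onto (0,1),
#'     \eqn{x = (y-a)/(b-a)}; no free parameters.  Natural for correlation
#'     networks with `bounds = c(-1, 1)`, i.e. \eqn{y = 2x - 1}.}
#' }
#'
#' Scale parameters are carried on the log scale internally so that
#' unconstrained optimization keeps \eqn{\alpha > 0}.  Any family supplying
#' a CDF, quantile and log-density of this shape can be added.
#'
#' @param family `"gaussian"`, `"cauchy"` or `"interval"`.
#' @param eta numeric vector of location coefficients (one per column of
#'   the edge design); unused for `interval`.
#' @param alpha positive scale; unused for `interval`.
#' @param bounds length-2 numeric `(a, b)`, `a < b`; `interval` only.
#' @return an object of class `marginal_model`.
#' @examples
#' mm <- marginal_model("cauchy", eta = 0, alpha = 1)
#' @export
marginal_model <- function(family = c("gaussian", "cauchy", "interval"),
                           eta = NULL, alpha = NULL, bounds = NULL) {
  family <- match.arg(family)
  if (family == "interval") {
    if (is.null(bounds) || length(bounds) != 2L || !(bounds[1] < bounds[2]))
      stop("interval family needs bounds = c(a, b) with a < b",
           call. = FALSE)
    eta <- numeric(0); alpha <- NULL
  } else {
    if (is.null(eta)) eta <- 0
    if (is.null(alpha)) alpha <- 1
    if (!is.finite(alpha) || alpha <= 0)
      stop("scale 'alpha' must be positive", call. = FALSE)
    bounds <- NULL
  }
  structure(list(family = family, eta = as.numeric(eta),
                 alpha = alpha, bounds = bounds),
            class = "marginal_model")
}

#' @export
print.marginal_model <- function(x, ...) {
  cat("Marginal family:", x$family, "\n")
  if (x$family == "interval") {
    cat("  bounds: [", x$bounds[1], ",", x$bounds[2], "]\n")
  } else {
    cat("  eta:", format(x$eta, digits = 4), "\n")
    cat("  alpha:", format(x$alpha, digits = 4), "\n")
  }
  invisible(x)
}

## number of free transformation parameters (eta plus one log-scale)
n_beta <- function(model, design = NULL) {
  if (model$family == "interval") return(0L)
  p <- if (!is.null(design)) ncol(design$covariates) else length(model$eta)
  p + 1L
}

## pack/unpack the unconstrained parameter vector beta = (eta, log alpha)
beta_pack <- function(model) {
  if (model$family == "interval") return(numeric(0))
  c(model$eta, log(model$alpha))
}

beta_unpack <- function(model, beta) {
  if (model$family == "interval") return(model)
  p <- length(beta) - 1L
  model$eta <- beta[seq_len(p)]
  model$alpha <- exp(beta[p + 1L])
  model
}

beta_names <- function(model, design = NULL) {
  if (model$family == "interval") return(character(0))
  nm <- if (!is.null(design)) colnames(design$covariates)
        else paste0("eta", seq_along(model$eta))
  c(nm, "log_alpha")
}

#' Edge covariate designs
#'
#' An edge design is an \eqn{m \times p} matrix of per-edge covariate
#' vectors \eqn{z_{ij}} (first column an intercept), rows in the row-major
#' ordered-pair enumeration of [edge_index()].  The edge location of the
#' marginal model is \eqn{\mu_{ij} = z_{ij}'\eta}.
#'
#' `edge_design()` builds one from a matrix; `node_design()` expands
#' per-vertex attributes to edge covariates by the standard recipes:
#' sender value (\eqn{z_{ij} = u_i}), receiver value (\eqn{u_j}), and
#' absolute difference (\eqn{|u_i - u_j|}).
#'
#' @param covariates numeric matrix (m rows); an intercept column is
#'   prepended unless the first column is constant 1.
#' @param names optional column labels.
#' @param n vertex count the design refers to.
#' @return object of class `edge_design`.
#' @export
edge_design <- function(covariates, n, names = NULL) {
  covariates <- as.matrix(covariates)
  m <- n_edges(n, directed = TRUE)
  if (nrow(covariates) != m)
    stop("edge design needs one row per ordered pair: expected ", m,
         ", got ", nrow(covariates), call. = FALSE)
  if (!all(covariates[, 1L] == 1)) {
    covariates <- cbind(1, covariates)
    if (!is.null(names)) names <- c("(Intercept)", names)
  }
  if (is.null(names)) {
    names <- colnames(covariates)
    if (is.null(names))
      names <- c("(Intercept)",
                 paste0("z", seq_len(ncol(covariates) - 1L)))
  }
  colnames(covariates) <- names
  structure(list(covariates = covariates, n = n), class = "edge_design")
}

#' @rdname edge_design
#' @export
intercept_design <- function(n) {
  edge_design(matrix(1, n_edges(n), 1L), n, names = "(Intercept)")
}

#' @rdname edge_design
#' @param attributes data frame or named matrix of per-vertex numeric
#'   attributes (one row per vertex).
#' @param expand named character vector / list mapping attribute names to
#'   one or more of `"sender"`, `"receiver"`, `"absdiff"`.
#' @export
node_design <- function(attributes, expand, n = nrow(attributes)) {
  attributes <- as.data.frame(attributes)
  if (nrow(attributes) != n)
    stop("one attribute row per vertex is required", call. = FALSE)
  idx <- edge_index(n)
  cols <- list(); labs <- character(0)
  for (nm in names(expand)) {
    if (!nm %in% names(attributes))
      stop("attribute '", nm, "' not found", call. = FALSE)
    u <- attributes[[nm]]
    if (!is.numeric(u))
      stop("attribute '", nm, "' is not numeric", call. = FALSE)
    for (how in expand[[nm]]) {
      v <- switch(how,
        sender   = u[idx[, 1L]],
        receiver = u[idx[, 2L]],
        absdiff  = abs(u[idx[, 1L]] - u[idx[, 2L]]),
        stop("unknown expansion '", how, "'", call. = FALSE))
      cols[[length(cols) + 1L]] <- v
      labs <- c(labs, paste0(nm, "_", how))
    }
  }
  edge_design(do.call(cbind, cols), n, names = labs)
}

#' Per-edge locations
#'
#' \eqn{\mu_{ij} = z_{ij}'\eta} for every edge in enumeration order.
#'
#' @param design an [edge_design()].
#' @param eta location coefficients, one per design column.
#' @return numeric vector of length m.
#' @export
edge_locations <- function(design, eta) {
  Z <- design$covariates
  if (length(eta) != ncol(Z))
    stop("length(eta) = ", length(eta), " but design has ", ncol(Z),
         " columns", call. = FALSE)
  drop(Z %*% eta)
}

## family kernels on vectors ------------------------------------------------

marg_cdf <- function(model, y, mu) {
  switch(model$family,
    gaussian = pnorm(y, mean = mu, sd = model$alpha),
    cauchy   = pcauchy(y, location = mu, scale = model$alpha),
    interval = (y - model$bounds[1]) / diff(model$bounds))
}

marg_quantile <- function(model, x, mu) {
  switch(model$family,
    gaussian = qnorm(x, mean = mu, sd = model$alpha),
    cauchy   = qcauchy(x, location = mu, scale = model$alpha),
    interval = model$bounds[1] + diff(model$bounds) * x)
}

marg_logpdf <- function(model, y, mu) {
  switch(model$family,
    gaussian = dnorm(y, mean = mu, sd = model$alpha, log = TRUE),
    cauchy   = dcauchy(y, location = mu, scale = model$alpha, log = TRUE),
    interval = rep(-log(diff(model$bounds)), length(y)))
}

check_support <- function(model, y) {
  if (model$family == "interval") {
    b <- model$bounds
    if (any(y < b[1] | y > b[2]))
      stop("edge values outside the interval family's bounds [",
           b[1], ", ", b[2], "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Map an observed network to its restricted (quantile) network
#'
#' Applies the marginal CDF edgewise: \eqn{x_{ij} = F(y_{ij} \mid
#' \mu_{ij}, \alpha)}.  The result is the network of joint quantiles on
#' which dependence is modelled; output is clamped strictly inside (0,1).
#'
#' @param y a `valued_network`.
#' @param model a [marginal_model()] carrying current parameters.
#' @param design an [edge_design()]; defaults to intercept only.
#' @return a `restricted_network`.
#' @export
to_restricted <- function(y, model, design = NULL) {
  if (!inherits(y, "valued_network")) y <- valued_network(y)
  if (is.null(design)) design <- intercept_design(nrow(y))
  yv <- edge_vector(y)
  check_support(model, yv)
  mu <- if (model$family == "interval") NULL
        else edge_locations(design, model$eta)
  xv <- clamp01(marg_cdf(model, yv, mu))
  restricted_network(edge_matrix(xv, nrow(y), diag = 0),
                     directed = is_directed(y), labels = rownames(y))
}

#' Map a restricted network onto the observed support
#'
#' Applies the marginal quantile function edgewise, the exact inverse of
#' [to_restricted()]: Cauchy \eqn{y = \mu + \alpha\tan(\pi(x - 1/2))},
#' interval \eqn{y = a + (b-a)x}, Gaussian the normal quantile.
#'
#' @param x a `restricted_network`.
#' @inheritParams to_restricted
#' @return a `valued_network`.
#' @export
to_observed <- function(x, model, design = NULL) {
  if (!inherits(x, "valued_network"))
    x <- restricted_network(x)
  if (is.null(design)) design <- intercept_design(nrow(x))
  xv <- edge_vector(x)
  mu <- if (model$family == "interval") NULL
        else edge_locations(design, model$eta)
  yv <- marg_quantile(model, xv, mu)
  valued_network(edge_matrix(yv, nrow(x), diag = 0),
                 directed = is_directed(x), labels = rownames(x))
}

#' Log marginal density of an observed network
#'
#' \eqn{\sum_{ij} \log f(y_{ij} \mid \mu_{ij}, \alpha)} over all edges —
#' the log of the Jacobian term of the model density (the Jacobian of the
#' edgewise transformation is diagonal, so its determinant is the product
#' of marginal densities).
#'
#' @inheritParams to_restricted
#' @return scalar log density.
#' @export
log_marginal_density <- function(y, model, design = NULL) {
  if (!inherits(y, "valued_network")) y <- valued_network(y)
  if (is.null(design)) design <- intercept_design(nrow(y))
  yv <- edge_vector(y)
  check_support(model, yv)
  mu <- if (model$family == "interval") NULL
        else edge_locations(design, model$eta)
  sum(marg_logpdf(model, yv, mu))
}
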