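#' Read a valued network from disk
#'
#' Two plain-text dialects are supported: a dense adjacency matrix
#' (comma- or tab-delimited; an optional header row and first column carry
#' vertex labels) and a three-column edge list `source,target,value`.
#' Edge-list input must contain every ordered pair exactly once — the
#' continuous model has no notion of an absent dyad.  Lines starting with
#' `#` are comments.
#'
#' @param path file path.
#' @param format `"matrix"` or `"edgelist"`; guessed from the header when
#'   omitted.
#' @param directed logical.
#' @return a `valued_network`.
#' @export
read_network <- function(path, format = c("auto", "matrix", "edgelist"),
                         directed = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 10L)
  first <- first[!startsWith(first, "#")][1L]
  sep <- if (grepl("\t", first)) "\t" else ","
  if (format == "auto") {
    nfields <- length(strsplit(first, sep, fixed = TRUE)[[1L]])
    format <- if (nfields == 3L &&
                  !grepl("^\\s*$", first)) "edgelist" else "matrix"
  }
  if (format == "matrix") {
    raw <- utils::read.table(path, sep = sep, header = FALSE,
                             comment.char = "#",
                             stringsAsFactors = FALSE)
    labels <- NULL
    ## header row of labels present if first cell is non-numeric
    if (suppressWarnings(is.na(as.numeric(raw[1L, 2L])))) {
      labels <- as.character(unlist(raw[1L, -1L]))
      raw <- raw[-1L, -1L, drop = FALSE]
    } else if (suppressWarnings(is.na(as.numeric(raw[1L, 1L])))) {
      labels <- as.character(raw[[1L]])
      raw <- raw[, -1L, drop = FALSE]
    }
    m <- as.matrix(raw)
    storage.mode(m) <- "double"
    if (nrow(m) != ncol(m))
      stop("adjacency matrix in ", path, " is not square", call. = FALSE)
    diag(m)[is.na(diag(m))] <- 0
    return(valued_network(m, directed = directed, labels = labels))
  }
  ## edge list
  el <- utils::read.table(path, sep = sep, header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(el) != 3L)
    stop("edge list must have exactly 3 columns (source, target, value)",
         call. = FALSE)
  labels <- sort(unique(c(as.character(el[[1L]]), as.character(el[[2L]]))))
  n <- length(labels)
  key <- paste(el[[1L]], el[[2L]], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge(s): ",
         paste(gsub("\r", " -> ", key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  m[cbind(as.character(el[[1L]]), as.character(el[[2L]]))] <-
    as.numeric(el[[3L]])
  diag(m) <- 0
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss))
    stop("edge list is missing ordered pair(s): ",
         paste(labels[miss[, 1L]], "->", labels[miss[, 2L]],
               collapse = ", "),
         call. = FALSE)
  valued_network(m, directed = directed, labels = labels)
}

#' Write a valued network to disk
#'
#' @param x a network object (or matrix).
#' @param path output file.
#' @param format `"matrix"` (labeled CSV adjacency matrix) or
#'   `"edgelist"`.
#' @export
write_network <- function(x, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  if (!inherits(x, "valued_network")) x <- valued_network(x)
  m <- unclass(x); diag(m) <- 0
  if (format == "matrix") {
    out <- cbind(rownames(m), format(m, digits = 10, trim = TRUE,
                                     scientific = FALSE))
    writeLines(c(paste(c("", colnames(m)), collapse = ","),
                 apply(out, 1L, paste, collapse = ",")), path)
  } else {
    idx <- edge_index(nrow(m))
    df <- data.frame(source = rownames(m)[idx[, 1L]],
                     target = rownames(m)[idx[, 2L]],
                     value = signif(m[idx], 10))
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read per-vertex attributes and expand to an edge design
#'
#' Reads a CSV node-attribute table (first column vertex labels, remaining
#' columns numeric) and expands the requested attributes to edge
#' covariates via [node_design()]; labels must match the network's.
#'
#' @param path node-attribute CSV.
#' @param network the `valued_network` the design refers to.
#' @param expand named list mapping attribute names to expansions
#'   (`"sender"`, `"receiver"`, `"absdiff"`).
#' @return an [edge_design()].
#' @export
read_covariates <- function(path, network, expand) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  labels <- as.character(tab[[1L]])
  want <- rownames(network)
  idx <- match(want, labels)
  if (anyNA(idx))
    stop("attribute table is missing vertex label(s): ",
         paste(want[is.na(idx)], collapse = ", "), call. = FALSE)
  tab <- tab[idx, -1L, drop = FALSE]
  bad <- names(tab)[!vapply(tab, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric attribute column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  node_design(tab, expand, n = nrow(network))
}

RESULT_SCHEMA <- "gergm-results/1"

#' Write estimation, simulation, or diagnostic results
#'
#' Emits a deterministic file set under `outdir`: for a fit, a
#' `coefficients.tsv` (name / estimate / se / z / p) and a
#' schema-versioned `fit.json` carrying the configuration, seed,
#' log-likelihood trace and convergence flag; for simulations, CSV network
#' matrices plus a per-sweep `trace.tsv`; for a degeneracy report, a
#' `diagnostics.json`.  Floats are written at 10 significant digits.
#'
#' @param object a `gergm` fit, a [simulate_restricted()] result, or a
#'   [degeneracy_report()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(object, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  j <- function(x, file) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, null = "null")
    file
  }
  if (inherits(object, "gergm")) {
    s <- summary(object)
    tab <- data.frame(name = rownames(s$coefficients),
                      signif(s$coefficients, 10))
    names(tab) <- c("name", "estimate", "se", "z", "p")
    f1 <- file.path(outdir, "coefficients.tsv")
    utils::write.table(tab, f1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    rec <- list(schema = RESULT_SCHEMA,
                family = object$model$family,
                statistics = object$spec$names,
                scaling = object$spec$scaling,
                theta = as.list(object$theta),
                beta = as.list(stats::setNames(
                  beta_pack(object$model),
                  beta_names(object$model, object$design))),
                converged = object$converged,
                seed = object$seed,
                control = unclass(object$control),
                loglik_trace = object$loglik_trace$loglik,
                wald_dependence = s$wald_dependence[c("statistic", "df",
                                                     "p.value")])
    paths <- c(f1, j(rec, file.path(outdir, "fit.json")))
  } else if (is.list(object) && !is.null(object$mean_trace)) {
    for (k in seq_along(object$networks)) {
      f <- file.path(outdir, sprintf("network_%04d.csv", k))
      write_network(object$networks[[k]], f)
      paths <- c(paths, f)
    }
    tr <- data.frame(sweep = seq_along(object$mean_trace),
                     mean_edge = signif(object$mean_trace, 10),
                     signif(object$stat_trace, 10))
    names(tr) <- c("sweep", "mean_edge", object$spec$names)
    f <- file.path(outdir, "trace.tsv")
    utils::write.table(tr, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, f,
               j(list(schema = RESULT_SCHEMA,
                      theta = as.list(stats::setNames(object$theta,
                                                      object$spec$names)),
                      statistics = object$spec$names),
                 file.path(outdir, "simulation.json")))
  } else if (inherits(object, "degeneracy_report")) {
    rec <- c(list(schema = RESULT_SCHEMA), unclass(object))
    paths <- j(rec, file.path(outdir, "diagnostics.json"))
  } else stop("don't know how to write this object", call. = FALSE)
  invisible(paths)
}
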