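# Graph data model and structural utilities.
#
# A `tt_graph` is a simple undirected unweighted graph: a sparse symmetric
# hollow binary adjacency matrix plus optional per-vertex label tracks.
# Vertex ids are 1-based inside R objects and 0-based in all files.

#' Construct a simple graph from an adjacency matrix
#'
#' Validates and canonicalizes an adjacency matrix into the package's graph
#' container: sparse, symmetric (\eqn{A = A^\top}), hollow
#' (\eqn{\mathrm{diag}(A) = 0}) and binary.
#'
#' @param adjacency A square matrix (dense or \pkg{Matrix} sparse). Must be
#'   symmetric; the diagonal is required to be zero; nonzero entries must be 1.
#' @param labels Optional data frame of per-vertex label tracks with one row
#'   per vertex (see [vertex_labels()]).
#' @return An object of class `tt_graph` with elements `n`, `adjacency`
#'   (a symmetric sparse `Matrix`), and `labels` (or `NULL`).
#' @examples
#' g <- tt_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' g$n
#' @export
tt_graph <- function(adjacency, labels = NULL) {
  A <- as(as(adjacency, "CsparseMatrix"), "generalMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  n <- nrow(A)
  if (n < 1L) stop("graph must have at least one vertex", call. = FALSE)
  A <- drop0(A)
  if (!isTRUE(all.equal(max(abs(A - Matrix::t(A))), 0))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(Matrix::diag(A) != 0)) {
    stop("adjacency must be hollow (zero diagonal)", call. = FALSE)
  }
  if (length(A@x) && !all(A@x == 1)) {
    stop("adjacency entries must be in {0, 1}", call. = FALSE)
  }
  A <- forceSymmetric(A, uplo = "U")
  labels <- validate_labels(labels, n)
  structure(list(n = n, adjacency = A, labels = labels), class = "tt_graph")
}

# Build a tt_graph from a 2-column matrix of 1-based endpoints: symmetrizes,
# collapses duplicates, drops self loops (message with count).
graph_from_edges <- function(edges, n, labels = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (length(edges) && (min(edges) < 1L || max(edges) > n)) {
    stop("edge endpoints outside 1..n", call. = FALSE)
  }
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(cbind(lo, hi))
  A <- sparseMatrix(i = lo[keep], j = hi[keep], x = 1, dims = c(n, n),
                    symmetric = TRUE)
  tt_graph(A, labels = labels)
}

#' Per-vertex label tracks
#'
#' Assembles the two binary label tracks used throughout the package.
#' When both tracks are present the combined track (e.g. `"LG"` for a
#' Left/Gray vertex) is derived deterministically from their first letters.
#'
#' @param hemisphere Character/factor vector in `{"Left","Right"}`, or `NULL`.
#' @param tissue Character/factor vector in `{"Gray","White"}`, or `NULL`.
#' @param block Optional integer vector of true block memberships (1-based).
#' @return A data frame with the supplied columns plus `combined` when both
#'   tracks are given.
#' @export
vertex_labels <- function(hemisphere = NULL, tissue = NULL, block = NULL) {
  cols <- list()
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (!all(hemisphere %in% c("Left", "Right"))) {
      stop('hemisphere labels must be "Left" or "Right"', call. = FALSE)
    }
    cols$hemisphere <- hemisphere
  }
  if (!is.null(tissue)) {
    tissue <- as.character(tissue)
    if (!all(tissue %in% c("Gray", "White"))) {
      stop('tissue labels must be "Gray" or "White"', call. = FALSE)
    }
    cols$tissue <- tissue
  }
  if (!is.null(block)) cols$block <- as.integer(block)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (!is.null(hemisphere) && !is.null(tissue)) {
    df$combined <- paste0(substr(df$hemisphere, 1L, 1L),
                          substr(df$tissue, 1L, 1L))
  }
  df
}

validate_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (nrow(labels) != n) {
    stop("labels must have one row per vertex", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("every vertex needs a value in each label track", call. = FALSE)
  }
  if (all(c("hemisphere", "tissue") %in% names(labels)) &&
      !"combined" %in% names(labels)) {
    labels$combined <- paste0(substr(labels$hemisphere, 1L, 1L),
                              substr(labels$tissue, 1L, 1L))
  }
  labels
}

#' @export
print.tt_graph <- function(x, ...) {
  e <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("tt_graph: %d vertices, %d edges%s\n", x$n, e,
              if (!is.null(x$labels)) {
                paste0(" [tracks: ", paste(names(x$labels), collapse = ", "), "]")
              } else ""))
  invisible(x)
}

#' Construct a weighted graph
#'
#' Container for a symmetric, hollow, nonnegative weight matrix, as produced
#' by averaging a collection of binary graphs into a composite graph.
#'
#' @param weights Square symmetric nonnegative matrix with zero diagonal.
#' @return An object of class `tt_weighted_graph`.
#' @export
tt_weighted_graph <- function(weights) {
  W <- as(as(weights, "CsparseMatrix"), "generalMatrix")
  if (nrow(W) != ncol(W)) stop("weights must be square", call. = FALSE)
  W <- drop0(W)
  if (!isTRUE(all.equal(max(abs(W - Matrix::t(W))), 0))) {
    stop("weights must be symmetric", call. = FALSE)
  }
  if (any(Matrix::diag(W) != 0)) stop("weights must be hollow", call. = FALSE)
  if (length(W@x) && any(W@x < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  structure(list(n = nrow(W), weights = forceSymmetric(W, uplo = "U")),
            class = "tt_weighted_graph")
}

#' @export
print.tt_weighted_graph <- function(x, ...) {
  cat(sprintf("tt_weighted_graph: %d vertices, %d weighted dyads\n",
              x$n, Matrix::nnzero(x$weights) / 2))
  invisible(x)
}

#' Read a graph from disk
#'
#' Supports two plain-text formats: a TSV edge list with two integer columns
#' of 0-based vertex ids (an optional third weight column is ignored; `#`
#' starts a comment; a `# n <count>` comment records the vertex count) and
#' MatrixMarket coordinate format for the sparse adjacency.
#' Duplicate edges are collapsed, edges are symmetrized, and self-loops are
#' dropped with a message.
#'
#' @param path File to read.
#' @param format `"edgelist"` or `"matrix-market"`.
#' @param n_hint Vertex count override for edge lists (needed when trailing
#'   vertices are isolated and no `# n` comment is present).
#' @return A [tt_graph()].
#' @export
read_graph <- function(path, format = c("edgelist", "matrix-market"),
                       n_hint = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "matrix-market") {
    M <- readMM(path)
    if (nrow(M) != ncol(M)) stop("matrix-market matrix must be square",
                                 call. = FALSE)
    M <- as(as(M, "dMatrix"), "CsparseMatrix")  # pattern files have no values
    if (length(M@x)) M@x[] <- 1
    M <- forceSymmetric(as(M, "generalMatrix") +
                          Matrix::t(as(M, "generalMatrix")), uplo = "U")
    if (length(M@x)) M@x[] <- 1
    Matrix::diag(M) <- 0
    return(tt_graph(drop0(M)))
  }
  lines <- readLines(path)
  n_comment <- grep("^#\\s*n\\s+\\d+", lines, value = TRUE)
  n_from_file <- if (length(n_comment)) {
    as.integer(sub("^#\\s*n\\s+(\\d+).*$", "\\1", n_comment[1L]))
  } else NULL
  body <- sub("#.*$", "", lines)
  keep <- which(trimws(body) != "")
  edges <- matrix(integer(0), ncol = 2L)
  if (length(keep)) {
    toks <- strsplit(trimws(body[keep]), "\\s+")
    bad <- which(vapply(toks, function(t) {
      length(t) < 2L || anyNA(suppressWarnings(as.numeric(t[1:2])))
    }, logical(1L)))
    if (length(bad)) {
      stop(sprintf("malformed edge on line %d of %s", keep[bad[1L]], path),
           call. = FALSE)
    }
    ij <- t(vapply(toks, function(t) as.numeric(t[1:2]), numeric(2L)))
    if (any(ij != floor(ij))) stop("vertex ids must be integers", call. = FALSE)
    if (any(ij < 0)) stop("vertex ids must be nonnegative", call. = FALSE)
    edges <- matrix(as.integer(ij) + 1L, ncol = 2L)
  }
  n <- max(n_hint %||% 0L, n_from_file %||% 0L,
           if (length(edges)) max(edges) else 1L)
  graph_from_edges(edges, n)
}

#' Write a graph to disk
#'
#' Canonical output: each undirected edge appears once with the smaller
#' 0-based id first, rows sorted lexicographically. Edge lists carry a
#' `# n <count>` comment so isolated trailing vertices round-trip.
#'
#' @param g A [tt_graph()].
#' @param path Output file.
#' @param format `"edgelist"` or `"matrix-market"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("edgelist", "matrix-market")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "tt_graph"))
  if (format == "matrix-market") {
    writeMM(g$adjacency, path)
    return(invisible(path))
  }
  A <- as(g$adjacency, "TsparseMatrix")  # upper triangle stored
  i <- pmin(A@i, A@j)
  j <- pmax(A@i, A@j)
  o <- order(i, j)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n %d", g$n), con)
  if (length(i)) {
    writeLines(paste(i[o], j[o], sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write vertex label tracks
#'
#' Labels are stored as TSV with columns `vertex_id` (0-based), `hemisphere`
#' and `tissue`.
#'
#' @param path File to read or write.
#' @return `read_labels` returns the label data frame ordered by vertex id
#'   (with the derived `combined` track); `write_labels` returns `path`
#'   invisibly.
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  df <- df[order(df$vertex_id), , drop = FALSE]
  validate_labels(df[setdiff(names(df), "vertex_id")], nrow(df))
}

#' @param labels Label data frame (one row per vertex, vertex order).
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  out <- cbind(vertex_id = seq_len(nrow(labels)) - 1L,
               labels[intersect(c("hemisphere", "tissue"), names(labels))])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Largest connected component
#'
#' Extracts the largest connected component of a graph, subsetting any label
#' tracks, and records the index map from old to new vertex ids.
#'
#' @param g A [tt_graph()].
#' @return A list with `graph` (the induced subgraph on the largest component,
#'   itself connected) and `index_map` (integer vector over the original
#'   vertices: the new 1-based id, or `NA` for dropped vertices).
#' @export
largest_connected_component <- function(g) {
  stopifnot(inherits(g, "tt_graph"))
  A <- as(as(g$adjacency, "generalMatrix"), "TsparseMatrix")
  up <- A@i < A@j
  edges <- rbind(A@i[up] + 1L, A@j[up] + 1L)
  ig <- igraph::make_graph(as.vector(edges), n = g$n, directed = FALSE)
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  index_map <- rep(NA_integer_, g$n)
  index_map[keep] <- seq_along(keep)
  sub <- g$adjacency[keep, keep, drop = FALSE]
  labels <- if (!is.null(g$labels)) g$labels[keep, , drop = FALSE] else NULL
  if (!is.null(labels)) rownames(labels) <- NULL
  list(graph = tt_graph(sub, labels = labels), index_map = index_map)
}

#' Average a collection of graphs into a composite weighted graph
#'
#' Entrywise mean of the adjacency matrices of `m` graphs on a shared vertex
#' set: `weight(i,j)` is the fraction of graphs containing edge `(i,j)`.
#'
#' @param gs List of [tt_graph()] objects with identical vertex counts.
#' @return A [tt_weighted_graph()].
#' @export
average_graphs <- function(gs) {
  if (!length(gs)) stop("need at least one graph", call. = FALSE)
  ns <- vapply(gs, function(g) g$n, integer(1L))
  if (length(unique(ns)) != 1L) {
    stop("all graphs must share the same vertex count", call. = FALSE)
  }
  W <- Reduce(`+`, lapply(gs, function(g) g$adjacency)) / length(gs)
  tt_weighted_graph(W)
}

#' Binarize a weighted graph
#'
#' Keeps an edge wherever the weight strictly exceeds the threshold `tau`.
#' With the default `tau = 0` an edge survives if it occurs in any of the
#' averaged input graphs.
#'
#' @param w A [tt_weighted_graph()].
#' @param tau Threshold in `[0, 1)`.
#' @return A [tt_graph()].
#' @export
binarize <- function(w, tau = 0) {
  stopifnot(inherits(w, "tt_weighted_graph"))
  stop_if_not_scalar_number(tau, "tau")
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)", call. = FALSE)
  W <- as(as(w$weights, "generalMatrix"), "TsparseMatrix")
  keep <- W@x > tau
  A <- sparseMatrix(i = W@i[keep] + 1L, j = W@j[keep] + 1L, x = 1,
                    dims = c(w$n, w$n))
  A <- forceSymmetric(A, uplo = "U")
  tt_graph(A)
}
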