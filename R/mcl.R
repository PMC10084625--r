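# Markov clustering of weighted undirected graphs.

#' Construct a weighted undirected graph
#'
#' @param nodes Character vector of node ids (isolated nodes allowed).
#' @param edges A `data.frame` with columns `from`, `to`, `weight`
#'   (positive). Edges are undirected; supplying both orientations of the
#'   same edge with different weights is an error.
#' @return An object of class `euk_graph`: list with `nodes` (sorted) and
#'   `edges` (canonical orientation, `from < to`).
#' @export
weighted_graph <- function(nodes, edges = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    if (any(edges$weight <= 0)) stop("edge weights must be > 0")
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes)) {
      stop("edge endpoints must be listed in nodes")
    }
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste0(a, "\r", b)
    if (anyDuplicated(key)) {
      w <- split(edges$weight, key)
      bad <- vapply(w, function(x) max(x) - min(x) > 1e-12, logical(1L))
      if (any(bad)) {
        stop("non-symmetric edge input: conflicting weights for an undirected edge")
      }
      keepi <- !duplicated(key)
      edges <- data.frame(from = a[keepi], to = b[keepi],
                          weight = edges$weight[keepi], stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(from = a, to = b, weight = edges$weight,
                          stringsAsFactors = FALSE)
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "euk_graph")
}

#' @export
print.euk_graph <- function(x, ...) {
  cat("euk_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

.graph_adjacency <- function(graph, self_loops = 1) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  diag(A) <- diag(A) + self_loops
  A
}

#' Markov clustering (MCL)
#'
#' Standard MCL on a weighted undirected graph: self-loops are added, the
#' adjacency matrix is column-normalized into a transition matrix, and
#' expansion (matrix power) alternates with inflation (entrywise power
#' followed by column renormalization) until the matrix changes by less
#' than `tolerance` or `max_iterations` is reached. Clusters are read off
#' the attractor rows of the limit matrix; a node supported by more than
#' one attractor system is assigned to the cluster where its attractor
#' value is largest, ties going to the cluster with the lexicographically
#' smallest representative, so the result is always a partition.
#'
#' @param graph A [weighted_graph()].
#' @param inflation Inflation exponent, `> 1` (default 2).
#' @param expansion Integer matrix-power exponent (default 2).
#' @param self_loops Self-loop weight added to every node (default 1).
#' @param max_iterations Iteration cap (default 100).
#' @param tolerance Convergence threshold on the max absolute change
#'   (default 1e-6).
#' @param prune Entries below this value are zeroed each iteration.
#' @return An object of class `euk_clustering`: a list of character
#'   vectors (sorted within and between clusters) partitioning the nodes.
#' @export
mcl <- function(graph, inflation = 2, expansion = 2L, self_loops = 1,
                max_iterations = 100L, tolerance = 1e-6, prune = 1e-8) {
  stopifnot(inherits(graph, "euk_graph"), inflation > 1, expansion >= 2L)
  n <- length(graph$nodes)
  if (n == 0L) {
    return(structure(list(), class = "euk_clustering"))
  }
  A <- .graph_adjacency(graph, self_loops = self_loops)
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    Mexp <- M
    for (k in seq_len(as.integer(expansion) - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2L, cs, "/")
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2L, cs, "/")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iterations,
            " iterations; returning current partition")
  }
  .mcl_clusters(M, graph$nodes)
}

# Read clusters from a (near-)limit MCL matrix: attractor rows are rows with
# non-negligible diagonal mass; each attractor's support is a candidate
# cluster; overlaps resolved by largest attractor value, ties by smallest
# cluster representative.
.mcl_clusters <- function(M, nodes, eps = 1e-6) {
  n <- length(nodes)
  M[M < eps] <- 0
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0L) {
    # degenerate (should not happen with self-loops); fall back to singletons
    return(structure(lapply(nodes, identity), class = "euk_clustering"))
  }
  supports <- lapply(attractors, function(a) which(M[a, ] > 0))
  keys <- vapply(supports, function(s) paste(s, collapse = ","), "")
  uniq <- !duplicated(keys)
  clusters <- supports[uniq]
  cluster_rows <- split(attractors, match(keys, keys[uniq]))

  assign <- rep(NA_integer_, n)
  best <- rep(-Inf, n)
  rep_node <- vapply(clusters, function(s) nodes[min(s)], "")
  for (ci in seq_along(clusters)) {
    rows <- cluster_rows[[ci]]
    for (j in clusters[[ci]]) {
      val <- max(M[rows, j])
      if (is.na(assign[j]) || val > best[j] + 1e-12 ||
          (abs(val - best[j]) <= 1e-12 && rep_node[ci] < rep_node[assign[j]])) {
        assign[j] <- ci
        best[j] <- val
      }
    }
  }
  # any node not covered by an attractor support becomes a singleton
  uncovered <- which(is.na(assign))
  out <- lapply(seq_along(clusters), function(ci) sort(nodes[which(assign == ci)]))
  out <- out[vapply(out, length, 1L) > 0L]
  out <- c(out, lapply(uncovered, function(j) nodes[j]))
  out <- out[order(vapply(out, `[`, "", 1L))]
  structure(out, class = "euk_clustering")
}

#' @export
print.euk_clustering <- function(x, ...) {
  cat("euk_clustering:", length(x), "clusters\n")
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param clustering A `euk_clustering`.
#' @return Named integer vector mapping node id to cluster index.
#' @export
cluster_membership <- function(clustering) {
  stopifnot(inherits(clustering, "euk_clustering"))
  if (length(clustering) == 0L) return(stats::setNames(integer(), character()))
  sizes <- vapply(clustering, length, 1L)
  stats::setNames(rep(seq_along(clustering), sizes), unlist(clustering))
}
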