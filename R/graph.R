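#' Euclidean distance matrix for pooled samples
#'
#' Computes the exact pairwise Euclidean distance matrix on which the
#' similarity graph (k-MST) is built. Rows are pooled samples; columns are
#' the dimensions of one feature (one column for single-feature screening,
#' several for a feature set).
#'
#' @param view Numeric matrix (N samples x d dimensions) or a numeric vector
#'   (treated as N x 1). All values must be finite; N >= 2.
#' @return A symmetric N x N numeric matrix with zero diagonal.
#' @examples
#' pairwise_distances(c(0, 1, 3))
#' @export
pairwise_distances <- function(view) {
  view <- as_feature_view(view)
  d <- as.matrix(stats::dist(view, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

# Validate and coerce a feature view to an N x d matrix of finite values.
as_feature_view <- function(view) {
  if (is.vector(view) && is.numeric(view)) view <- matrix(view, ncol = 1L)
  if (!is.matrix(view) || !is.numeric(view))
    stop("feature view must be a numeric vector or matrix")
  if (nrow(view) < 2L) stop("feature view needs at least 2 samples")
  bad <- which(!apply(is.finite(view), 1L, all))
  if (length(bad) > 0L)
    stop("non-finite feature values in sample(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  view
}

#' Construct a similarity graph
#'
#' Low-level constructor used by [build_kmst()] and the test suite; checks
#' the basic graph invariants (no self loops, no duplicate edges, indices in
#' range) and computes node degrees.
#'
#' @param n_nodes Number of nodes N.
#' @param edges Integer matrix with two columns (unordered node pairs,
#'   1-based).
#' @return An object of class `similarity_graph` with fields `n_nodes`,
#'   `edges` (each row ordered so the smaller index comes first), `degree`
#'   and `n_edges`.
#' @export
similarity_graph <- function(n_nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoint out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(edges) > 0L) stop("duplicate edges are not allowed")
  }
  degree <- tabulate(edges, nbins = n_nodes)
  structure(
    list(n_nodes = as.integer(n_nodes), edges = edges, degree = degree,
         n_edges = nrow(edges)),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity graph:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  invisible(x)
}

#' Build a k-MST similarity graph
#'
#' Union of k pairwise edge-disjoint minimum spanning trees of the complete
#' graph weighted by `dist`, built sequentially with Kruskal's algorithm:
#' tree t is an MST of the complete graph minus all edges used by trees
#' 1..t-1. Edges are taken in (weight, smaller node index, larger node index)
#' order; inside a group of equal-weight edges, edges whose endpoints
#' currently have the smallest degree sum are preferred. Any maximal
#' acceptable subset of an equal-weight group yields the same tree weight, so
#' this choice only fixes the topology: it is deterministic (reproducible
#' across runs and platforms) and it avoids the degenerate high-degree hubs
#' that blocks of tied values (e.g. clipped or discretized data) would
#' otherwise produce, which matters because the chi-squared limit of the
#' edge-count statistic requires hub-free graphs. A denser graph (k = 3 by
#' default in the screening pipeline) gives a better chi-squared
#' approximation for the edge-count statistic than a single MST.
#'
#' @param dist Symmetric numeric distance matrix (e.g. from
#'   [pairwise_distances()]).
#' @param k Number of edge-disjoint spanning trees; must satisfy
#'   `k <= floor(N/2)` so that k edge-disjoint spanning trees exist in the
#'   complete graph. Near that bound the sequential greedy construction can
#'   still paint itself into a corner (e.g. when ties make an early tree a
#'   star); this is reported as an error. Screening uses small k (default 3),
#'   where Euclidean MSTs have low maximum degree and the construction
#'   succeeds for N >= 2k.
#' @return A `similarity_graph` with `k * (N - 1)` edges.
#' @examples
#' g <- build_kmst(pairwise_distances(c(0, 1, 3)), k = 1)
#' g$edges
#' @export
build_kmst <- function(dist, k = 1L) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("dist must be a square matrix")
  n <- nrow(dist)
  if (n < 2L) stop("need at least 2 samples")
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (k > n %/% 2L)
    stop("k = ", k, " exceeds floor(N/2) = ", n %/% 2L,
         "; that many edge-disjoint spanning trees do not exist")
  edges <- .cpp_kmst_dense(dist, k)
  similarity_graph(n, edges)
}

#' Graph quantities entering the null moments and regularity conditions
#'
#' Computes `C = 0.5 * sum(|G_k|^2) - |G|` (the number of unordered edge
#' pairs sharing a node), the degree sums, the hub term
#' `sum(|G_k|^2) - 4|G|^2/N`, and the cluster term `sum_e |A_e||B_e|`, where
#' `A_e` is edge e plus the edges sharing a node with e and `B_e` is `A_e`
#' plus the edges sharing a node with any member of `A_e`. The hub and
#' cluster terms are the quantities whose growth conditions guarantee the
#' chi-squared limit of the edge-count statistic.
#'
#' @param g A `similarity_graph`.
#' @return List with `n_edges`, `C`, `sum_sq_degree`, `hub_term`,
#'   `cluster_term`.
#' @export
graph_diagnostics <- function(g) {
  stopifnot(inherits(g, "similarity_graph"))
  ssd <- sum(g$degree^2)
  m <- g$n_edges
  cluster <- if (m > 0L) .cpp_sum_AeBe(g$edges, g$n_nodes) else 0
  list(
    n_edges = m,
    C = 0.5 * ssd - m,
    sum_sq_degree = ssd,
    hub_term = ssd - 4 * m^2 / g$n_nodes,
    cluster_term = cluster
  )
}

#' Write a graph as an edge-list TSV
#'
#' @param g A `similarity_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "similarity_graph"))
  df <- data.frame(node_a = g$edges[, 1L], node_b = g$edges[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
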