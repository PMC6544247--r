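# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: brute-force enumeration, direct counting,
# hand-rolled step-up rules.

# Decode a Pruefer sequence into the edge list of the labelled tree on
# n = length(seq) + 2 nodes.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- min(which(degree == 1L))
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- 0L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# Minimum spanning-tree weight by exhaustive enumeration of all n^(n-2)
# labelled trees (n <= 6 keeps this tiny).
brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2L) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[i, ], n)
    w <- sum(d[cbind(e[, 1], e[, 2])])
    if (w < best) best <- w
  }
  best
}

# All distinct assignments of a label multiset (sizes `n`) to N positions.
enumerate_assignments <- function(n) {
  N <- sum(n)
  acc <- list()
  recurse <- function(remaining, assignment, pos) {
    if (pos > N) {
      acc[[length(acc) + 1L]] <<- assignment
      return(invisible())
    }
    for (j in seq_along(remaining)) {
      if (remaining[j] == 0L) next
      assignment[pos] <- j
      remaining[j] <- remaining[j] - 1L
      recurse(remaining, assignment, pos + 1L)
      remaining[j] <- remaining[j] + 1L
    }
  }
  recurse(as.integer(n), integer(N), 1L)
  do.call(rbind, acc)
}

# Within-group edge counts by a naive double loop.
naive_R <- function(edges, y, J) {
  R <- integer(J)
  if (nrow(edges) > 0) for (i in seq_len(nrow(edges))) {
    a <- y[edges[i, 1]]; b <- y[edges[i, 2]]
    if (a == b) R[a] <- R[a] + 1L
  }
  R
}

# Exhaustive permutation-null mean and covariance of R for a fixed graph.
enum_moments <- function(edges, n) {
  assignments <- enumerate_assignments(n)
  J <- length(n)
  Rs <- t(apply(assignments, 1L, function(y) naive_R(edges, y, J)))
  list(mean = colMeans(Rs),
       cov = stats::cov(Rs) * (nrow(Rs) - 1) / nrow(Rs))
}

# Hand-rolled Benjamini-Hochberg step-up (independent of stats::p.adjust).
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * alpha / m)
  sel <- rep(FALSE, m)
  if (length(ok) > 0) sel[o[seq_len(max(ok))]] <- TRUE
  sel
}

# Random connected-ish graph on n nodes (always includes a spanning tree).
random_graph_edges <- function(n, extra = 2L) {
  perm <- sample(n)
  tree <- cbind(perm[-1], perm[sapply(2:n, function(i) sample(i - 1L, 1L))])
  all_pairs <- t(combn(n, 2L))
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  avail <- all_pairs[!(key(all_pairs) %in% key(tree)), , drop = FALSE]
  if (extra > 0L && nrow(avail) > 0L) {
    pick <- sample(nrow(avail), min(extra, nrow(avail)))
    rbind(tree, avail[pick, , drop = FALSE])
  } else tree
}
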