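#' Group labels for the multi-sample edge-count test
#'
#' Encodes a categorical outcome as integer labels 1..J with group sizes.
#' Factors and character vectors keep their level order; integer input is
#' re-coded to consecutive levels.
#'
#' @param y Vector of group memberships (factor, character or integer),
#'   length N.
#' @return Object of class `group_labels` with fields `y` (integer 1..J),
#'   `n` (group sizes), `J`, `N` and `levels`.
#' @export
group_labels <- function(y) {
  if (!is.factor(y)) y <- factor(y, levels = unique(y)[order(unique(y))])
  y <- droplevels(y)
  if (anyNA(y)) stop("group labels must not contain missing values")
  code <- as.integer(y)
  n <- tabulate(code, nbins = nlevels(y))
  structure(
    list(y = code, n = n, J = nlevels(y), N = length(code),
         levels = levels(y)),
    class = "group_labels"
  )
}

as_group_labels <- function(y) {
  if (inherits(y, "group_labels")) y else group_labels(y)
}

#' Within-group edge counts
#'
#' For each group j, counts the edges of the similarity graph whose two
#' endpoints both carry label j. A sample of different distributions across
#' groups leaves more edges within groups (and fewer between) than expected
#' under random labelling, which is what the test statistic measures.
#'
#' @param g A `similarity_graph` on the pooled samples.
#' @param labels A `group_labels` object (or a vector coercible to one) of
#'   length `g$n_nodes`.
#' @return Integer vector R of length J.
#' @examples
#' g <- similarity_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
#' count_within_group_edges(g, c(1, 1, 2, 2, 1))
#' @export
count_within_group_edges <- function(g, labels) {
  stopifnot(inherits(g, "similarity_graph"))
  labels <- as_group_labels(labels)
  if (labels$N != g$n_nodes)
    stop("labels (", labels$N, ") and graph (", g$n_nodes,
         " nodes) have mismatched lengths")
  as.integer(.cpp_count_R(g$edges, labels$y, labels$J))
}

#' Exact permutation-null moments of the within-group edge counts
#'
#' Mean vector and covariance matrix of (R_1, ..., R_J) under the
#' permutation null (uniformly random assignment of the fixed labels to the
#' fixed graph's nodes):
#' \deqn{E(R_j) = |G| n_j (n_j - 1) / (N (N - 1))}
#' with variances and covariances driven by the edge-pair decomposition into
#' identical pairs (|G|), pairs sharing a node (2C ordered pairs) and
#' disjoint pairs (|G|(|G|-1) - 2C ordered pairs), where
#' `C = 0.5 * sum(|G_k|^2) - |G|`.
#'
#' @inheritParams count_within_group_edges
#' @return List with `mean` (length J) and `cov` (J x J).
#' @export
null_moments <- function(g, labels) {
  stopifnot(inherits(g, "similarity_graph"))
  labels <- as_group_labels(labels)
  if (labels$N != g$n_nodes)
    stop("labels and graph have mismatched lengths")
  if (labels$N < 4L)
    stop("null moments need N >= 4: the covariance formulas divide by (N - 3)")
  C <- 0.5 * sum(g$degree^2) - g$n_edges
  moments_from_counts(g$n_edges, C, labels)
}

# Moments from |G| and C directly. The variance/covariance decompose over
# ordered edge pairs: |G| identical pairs, 2C pairs sharing a node, and
# |G|(|G|-1) - 2C disjoint pairs.
moments_from_counts <- function(m, C, labels) {
  N <- labels$N
  n <- labels$n
  ER <- m * n * (n - 1) / (N * (N - 1))
  disj <- m * (m - 1) - 2 * C
  VR <- ER * (1 - ER) +
    2 * C * n * (n - 1) * (n - 2) / (N * (N - 1) * (N - 2)) +
    disj * n * (n - 1) * (n - 2) * (n - 3) /
      (N * (N - 1) * (N - 2) * (N - 3))
  cov <- disj * outer(n * (n - 1), n * (n - 1)) /
    (N * (N - 1) * (N - 2) * (N - 3)) - outer(ER, ER)
  diag(cov) <- VR
  list(mean = ER, cov = cov)
}

# Symmetric (pseudo-)inverse quadratic form: (r - mu)' cov^{-1} (r - mu).
# Falls back to the Moore-Penrose pseudo-inverse when cov is numerically
# singular (e.g. a group of size 1 yields a zero row/column).
quad_form_stat <- function(r, m) {
  d <- r - m$mean
  ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- max(abs(ev)) <= 0
  if (degenerate) return(list(S = 0, degenerate = TRUE))
  use_pinv <- min(ev) <= 0 || max(ev) / min(ev) > 1e12
  Vinv <- if (use_pinv) MASS::ginv(m$cov) else solve(m$cov)
  S <- max(0, as.numeric(t(d) %*% Vinv %*% d))
  list(S = S, degenerate = FALSE)
}

#' Edge-count test statistic and asymptotic p-value
#'
#' The quadratic form `S = (R - E(R))' V(R)^{-1} (R - E(R))`, which under the
#' permutation null is asymptotically chi-squared with J degrees of freedom
#' (given the regularity conditions on graph density, hubs and clusters that
#' Euclidean k-MSTs satisfy).
#'
#' @param r Integer vector of within-group edge counts (length J).
#' @param m Null moments as returned by [null_moments()].
#' @return Object of class `edge_count_result`: `S`, `df` (= J), `p_value`,
#'   `method = "asymptotic"`, and `degenerate` (TRUE when the covariance is
#'   identically zero, in which case S = 0 and p = 1).
#' @export
edge_count_statistic <- function(r, m) {
  if (length(r) != length(m$mean))
    stop("edge-count vector and moments have mismatched dimensions")
  qf <- quad_form_stat(r, m)
  J <- length(r)
  p <- if (qf$degenerate) 1 else pchisq(qf$S, df = J, lower.tail = FALSE)
  structure(
    list(S = qf$S, df = J, p_value = p, method = "asymptotic",
         degenerate = qf$degenerate),
    class = "edge_count_result"
  )
}

#' @export
print.edge_count_result <- function(x, ...) {
  cat(sprintf("edge-count test: S = %.4f, df = %d, p = %.4g (%s%s)\n",
              x$S, x$df, x$p_value, x$method,
              if (!is.null(x$n_permutations))
                paste0(", B = ", x$n_permutations) else ""))
  invisible(x)
}

#' Permutation p-value for the edge-count statistic
#'
#' Holds the similarity graph fixed and permutes the group labels uniformly,
#' recomputing S for each permutation. The add-one estimator
#' `p = (1 + #\{S* >= S\}) / (B + 1)` keeps p strictly positive. Recommended
#' when any group is small (the asymptotic chi-squared approximation
#' deteriorates for group sizes of about 10 or fewer).
#'
#' @inheritParams count_within_group_edges
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return An `edge_count_result` with `method = "permutation"` and
#'   `n_permutations = B`.
#' @export
permutation_pvalue <- function(g, labels, B = 1000L, seed = NULL) {
  stopifnot(inherits(g, "similarity_graph"))
  labels <- as_group_labels(labels)
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  m <- null_moments(g, labels)
  r <- count_within_group_edges(g, labels)
  obs <- quad_form_stat(r, m)
  Rperm <- .cpp_perm_R(g$edges, labels$y, labels$J, as.integer(B))
  Sperm <- apply(Rperm, 1L, function(rp) quad_form_stat(rp, m)$S)
  p <- (1 + sum(Sperm >= obs$S)) / (B + 1)
  structure(
    list(S = obs$S, df = labels$J, p_value = p, method = "permutation",
         n_permutations = as.integer(B), degenerate = obs$degenerate),
    class = "edge_count_result"
  )
}

#' k-MST edge-count test of equal conditional distributions
#'
#' Full pipeline for one feature (or multivariate feature set): Euclidean
#' distances on the pooled samples, k-MST similarity graph, within-group
#' edge counts, permutation-null moments, quadratic statistic S, and a
#' p-value. `mode = "auto"` uses the asymptotic chi-squared p-value unless
#' the smallest group has 10 or fewer samples, in which case it switches to
#' the permutation p-value.
#'
#' @param view Numeric vector or N x d matrix of feature values.
#' @param labels Group memberships (length N).
#' @param k Number of edge-disjoint spanning trees (default 3).
#' @param mode One of "auto", "asymptotic", "permutation".
#' @param B Number of permutations when a permutation p-value is used.
#' @param seed Optional seed for the permutation stream.
#' @return An `edge_count_result`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(30), rnorm(30, 5))
#' edge_count_test(x, rep(1:2, each = 30))
#' @export
edge_count_test <- function(view, labels, k = 3L,
                            mode = c("auto", "asymptotic", "permutation"),
                            B = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  view <- as_feature_view(view)
  labels <- as_group_labels(labels)
  if (labels$J < 2L) stop("testing needs at least 2 groups")
  if (nrow(view) != labels$N)
    stop("feature view and labels have mismatched lengths")
  # the seed also pins down the graph when tied distances are present
  if (!is.null(seed)) set.seed(seed)
  g <- build_kmst(pairwise_distances(view), k = k)
  if (mode == "auto")
    mode <- if (min(labels$n) <= 10L) "permutation" else "asymptotic"
  if (mode == "permutation")
    return(permutation_pvalue(g, labels, B = B, seed = seed))
  r <- count_within_group_edges(g, labels)
  edge_count_statistic(r, null_moments(g, labels))
}
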