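#' Welch's unequal-variance two-sample t test
#'
#' The standard unequal-variance t statistic with Welch-Satterthwaite
#' degrees of freedom,
#' \deqn{t = (\bar x_1 - \bar x_0) / \sqrt{s_1^2/n_1 + s_0^2/n_0},}
#' \deqn{\nu = (s_1^2/n_1 + s_0^2/n_0)^2 /
#'   \{ s_1^4/(n_1^2 (n_1 - 1)) + s_0^4/(n_0^2 (n_0 - 1)) \},}
#' plus the quantile-normalized z-value `z = qnorm(pt(t, df = nu))`. The
#' comparator test in the screening benchmark: powerful for mean shifts,
#' blind to symmetric distributional changes.
#'
#' @param x1,x0 Numeric vectors (the two groups), each of length >= 2.
#' @return List of class `welch_result` with `t`, `df`, `z`, and `degenerate`
#'   (TRUE when both group variances are zero, in which case the statistic is
#'   undefined and `t`, `z` are `NA`).
#' @examples
#' welch_t(c(0, 1, 2), c(1, 2, 3)) # t = -sqrt(3/2), df = 4
#' @export
welch_t <- function(x1, x0) {
  if (length(x1) < 2L || length(x0) < 2L)
    stop("each group needs at least 2 samples")
  n1 <- length(x1); n0 <- length(x0)
  v1 <- var(x1); v0 <- var(x0)
  se2 <- v1 / n1 + v0 / n0
  if (se2 <= 0) {
    return(structure(list(t = NA_real_, df = NA_real_, z = NA_real_,
                          degenerate = TRUE), class = "welch_result"))
  }
  t <- (mean(x1) - mean(x0)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
  z <- quantile_normalize(t, null = "t", df = df)
  structure(list(t = t, df = df, z = z, degenerate = FALSE),
            class = "welch_result")
}

# Vectorised Welch statistics over the columns of an N x p matrix.
# Returns t, df, z per feature; zero-variance features come back NA with a
# warning and are skipped by the selection step.
welch_t_matrix <- function(X, y01) {
  X1 <- X[y01 == 1L, , drop = FALSE]
  X0 <- X[y01 == 0L, , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  if (n1 < 2L || n0 < 2L) stop("each group needs at least 2 samples")
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(X0^2) - n0 * m0^2) / (n0 - 1)
  v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)
  se2 <- v1 / n1 + v0 / n0
  bad <- se2 <= 0
  if (any(bad))
    warning(sum(bad), " zero-variance feature(s) skipped by Welch's t test")
  t <- ifelse(bad, NA_real_, (m1 - m0) / sqrt(se2))
  df <- ifelse(bad, NA_real_,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1))))
  z <- rep(NA_real_, length(t))
  z[!bad] <- quantile_normalize(t[!bad], null = "t", df = df[!bad])
  list(t = t, df = df, z = z)
}

#' Equal-frequency discretization
#'
#' Bins a continuous vector into `n_bins` bins by empirical quantiles: value
#' with rank r goes to bin `ceiling(n_bins * r / N)` (average ranks, so tied
#' values share a bin). With distinct values the bin sizes differ by at most
#' one; ties can unbalance the bins.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer vector of bin indices in 1..n_bins.
#' @export
discretize_equal_frequency <- function(x, n_bins) {
  if (n_bins < 2L) stop("need at least 2 bins")
  r <- rank(x, ties.method = "average")
  pmin(pmax(ceiling(n_bins * r / length(x)), 1L), as.integer(n_bins))
}

#' Mutual-information z test
#'
#' Plug-in mutual information between the group labels and the feature
#' discretized into `ceiling(N^(1/3))` equal-frequency bins, normalized by
#' the sum of the two marginal entropies (natural log throughout),
#' `I* = I / (H(Y) + H(X))`, then Fisher-z transformed:
#' `z_mi = 0.5 * log((1 + I*) / (1 - I*))`. Under independence `z_mi` is
#' approximately N(0, 1/(N-3)), the null used for quantile normalization.
#'
#' @param x Numeric feature vector.
#' @param y Group labels (length N).
#' @param n_bins Number of bins; defaults to `ceiling(N^(1/3))`.
#' @return List of class `mi_result` with `I_hat`, `H_y`, `H_x`, `I_star`,
#'   `z_mi`, `n_bins`, and `z` (quantile-normalized against
#'   N(0, 1/(N-3))).
#' @examples
#' # perfectly aligned binary case: I* = 0.5, z_mi = 0.5 * log(3)
#' mutual_information_z(rep(c(0, 1), each = 4), rep(1:2, each = 4))
#' @export
mutual_information_z <- function(x, y, n_bins = NULL) {
  labels <- as_group_labels(y)
  N <- length(x)
  if (labels$N != N) stop("x and y have mismatched lengths")
  if (N < 5L) stop("mutual-information z test needs N >= 5")
  if (is.null(n_bins)) n_bins <- max(2L, as.integer(ceiling(N^(1 / 3))))
  xb <- if (length(unique(x)) < 2L) rep(1L, N)
        else discretize_equal_frequency(x, n_bins)
  tab <- table(xb, labels$y)
  I_hat <- plugin_mi(tab)
  H_y <- plugin_entropy(colSums(tab))
  H_x <- plugin_entropy(rowSums(tab))
  if (labels$J < 2L || H_y + H_x <= 0) {
    I_star <- 0; z_mi <- 0
  } else {
    I_star <- I_hat / (H_y + H_x)
    z_mi <- 0.5 * log((1 + I_star) / (1 - I_star))
  }
  z <- quantile_normalize(z_mi, null = "normal", sd = 1 / sqrt(N - 3))
  structure(
    list(I_hat = I_hat, H_y = H_y, H_x = H_x, I_star = I_star, z_mi = z_mi,
         n_bins = as.integer(n_bins), z = z),
    class = "mi_result"
  )
}

# Plug-in entropy (nats) of a vector of counts.
plugin_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Plug-in mutual information (nats) of a contingency table.
plugin_mi <- function(tab) {
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  idx <- pxy > 0
  sum(pxy[idx] * (log(pxy[idx]) - log(outer(px, py))[idx]))
}

# Vectorised MI z over matrix columns.
mi_z_matrix <- function(X, labels, n_bins = NULL) {
  N <- nrow(X)
  res <- apply(X, 2L, function(x)
    mutual_information_z(x, labels, n_bins = n_bins))
  list(z_mi = vapply(res, `[[`, numeric(1), "z_mi"),
       z = vapply(res, `[[`, numeric(1), "z"))
}
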