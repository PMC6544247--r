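# Constants of Efron's dispersion estimate. P0 is the central standard-normal
# mass on [-1, 1]; Q0 is the second-Hermite-polynomial coefficient
# -integral_{-1}^{1} phi(z) (z^2 - 1) / sqrt(2) dz = 1 / sqrt(pi * e),
# which makes A = (P0 - P0_hat) / Q0 a proper dispersion estimate of the
# empirical null. Both are exposed as arguments so alternative readings can
# be swapped in.
efron_P0 <- function() 2 * pnorm(1) - 1
efron_Q0 <- function() 1 / sqrt(pi * exp(1))

#' Quantile-normalize test statistics to z-values
#'
#' Maps a statistic through its null CDF and then the standard-normal
#' quantile function, `z = qnorm(F_null(stat))`. CDF values are clamped to
#' `[eps, 1 - eps]` before inversion so extreme statistics stay finite and
#' rank correctly.
#'
#' @param stats Numeric vector of statistics.
#' @param null One of `"chisq"` (chi-squared with `df` degrees of freedom,
#'   used for the edge-count statistic), `"t"` (Student t with per-feature
#'   `df`, used for Welch statistics), or `"normal"` (N(0, sd^2), used for
#'   the mutual-information z with `sd = 1/sqrt(N - 3)`).
#' @param df Degrees of freedom (scalar or per-feature vector) for the
#'   chi-squared and t nulls.
#' @param sd Null standard deviation for the normal null.
#' @param eps Clamping bound for the CDF values (default 1e-15).
#' @return Numeric vector of z-values.
#' @examples
#' quantile_normalize(2 * log(2), null = "chisq", df = 2) # the chisq_2 median
#' @export
quantile_normalize <- function(stats, null = c("chisq", "t", "normal"),
                               df = NULL, sd = NULL, eps = 1e-15) {
  null <- match.arg(null)
  u <- switch(null,
    chisq = {
      if (is.null(df)) stop("chisq null needs df")
      pchisq(stats, df = df)
    },
    t = {
      if (is.null(df)) stop("t null needs df")
      pt(stats, df = df)
    },
    normal = {
      if (is.null(sd)) stop("normal null needs sd")
      pnorm(stats, mean = 0, sd = sd)
    }
  )
  qnorm(pmin(pmax(u, eps), 1 - eps))
}

#' Efron's dispersion statistic A
#'
#' `A = (P0 - P0_hat) / Q0`, where `P0 = 2 * pnorm(1) - 1` is the
#' standard-normal mass of `[-1, 1]`, `P0_hat` is the observed fraction of
#' z-values with `|z| <= 1`, and `Q0 = 1/sqrt(pi * e)`. Under independence
#' the central mass matches the theoretical one and A is near 0; correlation
#' between the tests widens or narrows the central mass, and |A| measures
#' that dispersion.
#'
#' @param z Numeric vector of z-values.
#' @param P0,Q0 Constants of the estimate; override only to explore
#'   alternative conventions.
#' @return Scalar A.
#' @export
estimate_A <- function(z, P0 = efron_P0(), Q0 = efron_Q0()) {
  if (length(z) < 1L) stop("need at least one z-value")
  P0_hat <- mean(abs(z) <= 1)
  (P0 - P0_hat) / Q0
}

#' Correlation correction factor A(z)
#'
#' `A(z) = 1 / (1 + |A| |z| phi(z) / (sqrt(2) (1 - Phi(z))))`, the factor by
#' which the nominal tail area is shrunk to compensate for correlation
#' between test statistics; `|z| phi(z)/sqrt(2)` is the Hermite
#' tail-correction of the normal tail integral. Under independence (A = 0)
#' the factor is identically 1 and the selection rule reduces to
#' Benjamini-Hochberg. The normal tail is evaluated on the log scale so the
#' factor stays accurate far in the tail.
#'
#' @param z Numeric vector of thresholds.
#' @param A Dispersion statistic from [estimate_A()].
#' @param sqrt2 The constant in the denominator; exposed so the alternative
#'   reading without the radical can be restored.
#' @return Numeric vector with values in (0, 1].
#' @export
correlation_adjustment <- function(z, A, sqrt2 = sqrt(2)) {
  stopifnot(all(is.finite(z)), is.finite(A))
  # |z| phi(z) / (1 - Phi(z)) via logs; stable for large z.
  log_ratio <- log(abs(z)) + dnorm(z, log = TRUE) -
    pnorm(z, lower.tail = FALSE, log.p = TRUE)
  ratio <- ifelse(z == 0, 0, exp(log_ratio))
  1 / (1 + abs(A) * ratio / sqrt2)
}

#' Dependence-adjusted FDR selection (Efron's procedure)
#'
#' Finds the cutoff
#' `z0 = inf{ z : 1 - Phi(z) <= alpha * A(z) * max(1, #\{z_i >= z\}) / p }`
#' and rejects the hypotheses with `z_i > z0`. The count term is piecewise
#' constant between observed z-values, so the scan runs over the observed
#' values in descending order; within the interval below the smallest
#' satisfying observed value the criterion function changes sign, and the
#' continuous infimum is located there by root finding. With `A = 0` the
#' rejection set is exactly the Benjamini-Hochberg set on the one-sided
#' p-values `1 - Phi(z_i)`.
#'
#' @param z Numeric vector of z-values (length p).
#' @param alpha Targeted FDR level in (0, 1).
#' @param A Optional fixed dispersion value; estimated from `z` via
#'   [estimate_A()] when `NULL`.
#' @param P0,Q0 Passed to [estimate_A()].
#' @return Object of class `efron_fit`: `P0`, `P0_hat`, `Q0`, `A`, `alpha`,
#'   `z0` (above `max(z)` when nothing is selected), `selected` (logical
#'   vector) and `n_selected`.
#' @export
efron_select <- function(z, alpha = 0.10, A = NULL, P0 = efron_P0(),
                         Q0 = efron_Q0()) {
  if (length(z) < 1L) stop("empty z vector")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  p <- length(z)
  P0_hat <- mean(abs(z) <= 1)
  if (is.null(A)) A <- (P0 - P0_hat) / Q0

  zs <- sort(unique(z), decreasing = TRUE)
  counts <- vapply(zs, function(zz) sum(z >= zz), numeric(1))
  crit <- function(zz, cnt) {
    pnorm(zz, lower.tail = FALSE) -
      alpha * correlation_adjustment(zz, A) * pmax(1, cnt) / p
  }
  ok <- crit(zs, counts) <= 0
  if (!any(ok)) {
    # the criterion always holds far enough in the right tail (the count
    # term bottoms out at 1); the infimum sits above the largest z-value
    # and nothing is selected
    upper <- max(zs) + 1
    while (crit(upper, 1) > 0 && upper < max(zs) + 64) upper <- upper + 1
    z0 <- if (crit(upper, 1) <= 0)
      uniroot(crit, c(max(zs), upper), cnt = 1, tol = 1e-12)$root
    else Inf
    selected <- rep(FALSE, p)
  } else {
    i_hat <- max(which(ok))  # smallest satisfying observed z
    z_hat <- zs[i_hat]
    cnt <- counts[i_hat]
    selected <- z >= z_hat
    # Continuous infimum: inside (next lower observed z, z_hat] the count is
    # constant and the criterion fails at the lower end (a larger count was
    # already rejected there), so a sign change is bracketed.
    lower <- if (i_hat < length(zs)) zs[i_hat + 1L] else z_hat - 1
    z0 <- z_hat
    if (crit(z_hat, cnt) < 0) {
      while (crit(lower, cnt) <= 0 && i_hat == length(zs) && lower > z_hat - 64)
        lower <- lower - 1
      if (crit(lower, cnt) > 0)
        z0 <- uniroot(crit, c(lower, z_hat), cnt = cnt, tol = 1e-12)$root
      else
        z0 <- lower
    }
  }
  structure(
    list(P0 = P0, P0_hat = P0_hat, Q0 = Q0, A = A, alpha = alpha, z0 = z0,
         selected = selected, n_selected = sum(selected)),
    class = "efron_fit"
  )
}

#' @export
print.efron_fit <- function(x, ...) {
  cat(sprintf(
    "Efron selection: A = %.4f, z0 = %.4f, %d of %d selected (alpha = %g)\n",
    x$A, x$z0, x$n_selected, length(x$selected), x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg selection
#'
#' Standard step-up procedure: reject the k* smallest p-values where
#' `k* = max{k : p_(k) <= k * alpha / p}` (equivalently, BH-adjusted p-values
#' at or below alpha). Controls the FDR under independent or weakly
#' dependent p-values; provided as the comparator to [efron_select()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha Targeted FDR level.
#' @return List of class `selection_result`: `selected`, `n_selected`,
#'   `procedure = "bh"`.
#' @export
bh_select <- function(pvalues, alpha = 0.10) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  selected <- p.adjust(pvalues, method = "BH") <= alpha
  structure(
    list(selected = selected, n_selected = sum(selected), procedure = "bh"),
    class = "selection_result"
  )
}
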