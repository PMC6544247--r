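test_that("within-group edge counts match hand counts and the naive loop", {
  g <- similarity_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  expect_equal(count_within_group_edges(g, c(1, 1, 2, 2, 1)), c(1L, 1L))

  # single label: every edge is within-group
  expect_equal(count_within_group_edges(g, rep(1, 5)), g$n_edges)

  set.seed(10)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    edges <- random_graph_edges(n, extra = sample(0:4, 1))
    g <- similarity_graph(n, edges)
    J <- sample(2:3, 1)
    y <- sample(J, n, replace = TRUE)
    while (length(unique(y)) < J) y <- sample(J, n, replace = TRUE)
    expect_equal(count_within_group_edges(g, y), naive_R(g$edges, y, J))
    # conservation: within + between = |G|
    between <- sum(y[g$edges[, 1]] != y[g$edges[, 2]])
    expect_equal(sum(count_within_group_edges(g, y)) + between, g$n_edges)
  }

  expect_error(count_within_group_edges(g, c(1, 2)), "mismatch")
})

test_that("null moments match the printed formulas and the enumeration oracle", {
  path5 <- similarity_graph(5, cbind(1:4, 2:5))
  m <- null_moments(path5, c(1, 1, 1, 2, 2))
  expect_equal(m$mean, c(4 * 3 * 2 / 20, 4 * 2 * 1 / 20))  # (1.2, 0.4)
  oracle <- enum_moments(path5$edges, c(3, 2))
  expect_equal(m$mean, oracle$mean, tolerance = 1e-10)
  expect_equal(unname(m$cov), unname(oracle$cov), tolerance = 1e-10)

  # a singleton group cannot host a within-group edge
  m1 <- null_moments(path5, c(1, 2, 2, 2, 2))
  expect_equal(m1$mean[1], 0)
  expect_equal(m1$cov[1, ], c(0, 0))
  expect_equal(m1$cov[, 1], c(0, 0))

  expect_error(null_moments(similarity_graph(3, rbind(c(1, 2))), c(1, 2, 2)),
               "N - 3")
})

test_that("analytic moments equal exhaustive enumeration on random graphs", {
  set.seed(11)
  cases <- list(c(3, 2), c(2, 2, 2), c(4, 3), c(3, 2, 2), c(5, 2), c(2, 2))
  for (n_sizes in cases) {
    N <- sum(n_sizes)
    edges <- random_graph_edges(N, extra = sample(0:3, 1))
    g <- similarity_graph(N, edges)
    lab <- group_labels(rep(seq_along(n_sizes), n_sizes))
    m <- null_moments(g, lab)
    oracle <- enum_moments(g$edges, n_sizes)
    expect_equal(m$mean, oracle$mean, tolerance = 1e-10)
    expect_equal(unname(m$cov), unname(oracle$cov), tolerance = 1e-10)
  }
})

test_that("the quadratic statistic matches explicit 2x2 inversion", {
  m <- list(mean = c(3, 2), cov = matrix(c(2, 0.5, 0.5, 1.5), 2))
  r <- c(5, 1)
  res <- edge_count_statistic(r, m)
  d <- r - m$mean
  det <- 2 * 1.5 - 0.5^2
  S_hand <- (1.5 * d[1]^2 - 2 * 0.5 * d[1] * d[2] + 2 * d[2]^2) / det
  expect_equal(res$S, S_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(S_hand, 2, lower.tail = FALSE))

  # R at its expectation: no evidence at all
  res0 <- edge_count_statistic(m$mean, m)
  expect_equal(res0$S, 0)
  expect_equal(res0$p_value, 1)

  # identically-zero covariance is flagged degenerate
  resd <- edge_count_statistic(c(0, 0), list(mean = c(0, 0),
                                             cov = matrix(0, 2, 2)))
  expect_true(resd$degenerate)
  expect_equal(resd$p_value, 1)
  expect_equal(resd$S, 0)

  expect_error(edge_count_statistic(c(1, 2, 3), m), "dimensions")
})

test_that("null S follows its chi-squared reference distribution", {
  set.seed(12)
  y <- rep(1:2, each = 100)
  lab <- group_labels(y)
  S <- numeric(0)
  for (r in 1:4) {
    X <- matrix(rnorm(200 * 250), 200)
    S <- c(S, edgescreen:::compute_method_z(X, lab, "edgecount", k = 3,
                                            mode = "asymptotic")$stat)
  }
  # 1000 null statistics vs chi^2_2: quantiles and a coarse KS distance
  expect_equal(median(S), qchisq(0.5, 2), tolerance = 0.15)
  expect_lt(abs(mean(S <= qchisq(0.9, 2)) - 0.9), 0.03)
  expect_lt(abs(mean(S) - 2), 0.25)
})

test_that("permutation p-values behave at the extremes and match enumeration", {
  # glaring separation: observed S tops every permuted S*
  x <- c(rnorm(8), rnorm(8, 50))
  y <- rep(1:2, each = 8)
  res <- permutation_pvalue(build_kmst(pairwise_distances(x), 2),
                            y, B = 99, seed = 1)
  expect_equal(res$p_value, 1 / 100)
  expect_equal(res$method, "permutation")

  # identical feature values: the graph is a tie-broken tree that carries no
  # information about the labels, so the test finds nothing remarkable
  set.seed(2)
  g_tied <- build_kmst(pairwise_distances(rep(1, 10)), 2)
  res_t <- permutation_pvalue(g_tied, rep(1:2, each = 5), B = 200, seed = 2)
  expect_gte(res_t$p_value, 1 / 201)
  expect_lte(res_t$p_value, 1)
  expect_gt(res_t$p_value, 0.01)

  # N = 6 balanced: exhaustive p over all 20 assignments vs Monte Carlo
  set.seed(13)
  x <- rnorm(6)
  y <- rep(1:2, each = 3)
  g <- build_kmst(pairwise_distances(x), 2)
  m <- null_moments(g, y)
  S_obs <- edge_count_statistic(count_within_group_edges(g, y), m)$S
  asg <- enumerate_assignments(c(3, 3))
  S_all <- apply(asg, 1, function(yy)
    edge_count_statistic(naive_R(g$edges, yy, 2), m)$S)
  p_exact <- mean(S_all >= S_obs - 1e-12)
  res <- permutation_pvalue(g, y, B = 4000, seed = 3)
  expect_lt(abs(res$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
})

test_that("the full test pipeline detects separation and is calibrated under the null", {
  set.seed(14)
  x <- c(rnorm(30), rnorm(30, 5))
  y <- rep(1:2, each = 30)
  expect_lt(edge_count_test(x, y, k = 3)$p_value, 0.01)

  # shuffled labels: p-values uniform (KS at the 1% level)
  ps <- replicate(200, {
    edge_count_test(rnorm(60), sample(y), k = 3, mode = "asymptotic")$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # three identical groups: rejection close to nominal
  y3 <- rep(1:3, each = 20)
  rej <- mean(replicate(400, {
    edge_count_test(rnorm(60), y3, k = 3, mode = "asymptotic")$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # auto mode switches to permutation for small groups
  small <- edge_count_test(rnorm(16), rep(1:2, each = 8), k = 2, B = 99,
                           seed = 5)
  expect_equal(small$method, "permutation")
  big <- edge_count_test(rnorm(60), y, k = 3)
  expect_equal(big$method, "asymptotic")
})

test_that("power against a mean shift increases with the shift", {
  set.seed(15)
  y <- rep(1:2, each = 25)
  power_at <- function(delta) {
    mean(replicate(200, {
      x <- c(rnorm(25), rnorm(25, delta))
      edge_count_test(x, y, k = 3, mode = "asymptotic")$p_value < 0.05
    }))
  }
  p <- vapply(c(0.5, 1.25, 2.5), power_at, numeric(1))
  expect_gt(p[2], p[1] - 0.05)  # monotone up to Monte-Carlo noise
  expect_gt(p[3], p[2] - 0.05)
  expect_gt(p[3], p[1] + 0.2)   # and clearly increasing overall
})

test_that("asymptotic and permutation p-values agree for moderate samples", {
  set.seed(16)
  y <- rep(1:2, each = 50)
  diffs <- replicate(100, {
    x <- rnorm(100)
    g <- build_kmst(pairwise_distances(x), 3)
    pa <- edge_count_statistic(count_within_group_edges(g, y),
                               null_moments(g, y))$p_value
    pp <- permutation_pvalue(g, y, B = 2000)$p_value
    abs(pa - pp)
  })
  expect_lt(median(diffs), 0.02)
})
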