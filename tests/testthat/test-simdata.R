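test_that("signal transformations follow the four design blocks", {
  expect_equal(transform_signal(-1, 5), -1)        # odd cube
  expect_equal(transform_signal(1.5, 9), sin(pi), tolerance = 1e-12)
  expect_equal(transform_signal(0.5, 7), 0.25)     # quadratic block
  expect_equal(transform_signal(0.7, 2), 0.7)      # linear block
  expect_equal(transform_signal(0.5, 4), 0.125)
  expect_equal(transform_signal(-0.9, 10), sin(-2 * pi * 0.9 / 3))
  expect_error(transform_signal(1, 11), "1..10")
})

test_that("the random correlation matrix is a proper mixed-sign correlation", {
  S <- make_correlation_matrix(40, seed = 5)
  expect_equal(diag(S), rep(1, 40))
  expect_equal(S, t(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  off <- S[upper.tri(S)]
  expect_true(any(off > 0) && any(off < 0))
  expect_identical(S, make_correlation_matrix(40, seed = 5))
  expect_false(identical(S, make_correlation_matrix(40, seed = 6)))
})

test_that("independent features have Unif(-1.5, 1.5) moments", {
  set.seed(50)
  cfg <- simulation_config("logistic", "independent", N = 2000L, p = 20L)
  X <- generate_features(cfg)
  se_mean <- sqrt(0.75 / 2000)
  expect_lt(max(abs(colMeans(X))), 3.5 * se_mean + 0.02)
  expect_lt(max(abs(apply(X, 2, var) - 0.75)), 0.08)
  expect_true(all(X > -1.5 & X < 1.5))
})

test_that("dependent features are truncated and keep their dependence", {
  set.seed(51)
  cfg <- simulation_config("latent", "dependent", N = 2000L, p = 10L,
                           seed = 3L)
  X <- generate_features(cfg)
  expect_true(all(abs(X) <= 1.5))
  # quantile truncation leaves no boundary atoms
  expect_equal(sum(abs(X) == 1.5), 0L)
  # the strongest Sigma pair keeps its correlation sign in the sample
  S <- crossprod(cfg$Sigma_chol)
  off <- abs(S) * upper.tri(S)
  idx <- which(off == max(off), arr.ind = TRUE)[1, ]
  r <- cor(X[, idx[1]], X[, idx[2]])
  expect_equal(sign(r), sign(S[idx[1], idx[2]]))
  expect_gt(abs(r), abs(S[idx[1], idx[2]]) * 0.5)

  # literal clipping alternative creates the boundary atoms
  set.seed(51)
  Xc <- generate_features(cfg, method = "clip")
  expect_gt(mean(abs(Xc) == 1.5), 0.3)
})

test_that("responses follow the logistic and latent mechanisms", {
  set.seed(52)
  cfg0 <- simulation_config("logistic", "independent", N = 4000L, p = 12L,
                            betas = rep(0, 10))
  X <- generate_features(cfg0)
  y <- generate_response(X, cfg0)
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 4000))

  # latent model with vanishing noise is the indicator of the score
  cfg_l <- simulation_config("latent", "independent", N = 500L, p = 12L,
                             noise_sd = 1e-12)
  X <- generate_features(cfg_l)
  score <- rowSums(sapply(1:10, function(i)
    cfg_l$betas[i] * transform_signal(X[, i], i)))
  expect_equal(generate_response(X, cfg_l), as.integer(score > 0))

  # logistic calibration at scale: empirical P(Y=1|score) tracks plogis
  cfg <- simulation_config("logistic", "independent", N = 100000L, p = 10L)
  X <- generate_features(cfg)
  score <- rowSums(sapply(1:10, function(i)
    cfg$betas[i] * transform_signal(X[, i], i)))
  y <- generate_response(X, cfg)
  bins <- cut(score, breaks = quantile(score, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  emp <- tapply(y, bins, mean)
  thr <- tapply(plogis(score), bins, mean)
  expect_lt(max(abs(emp - thr)), 0.02)
})

test_that("power and FDP are counted per definition", {
  expect_equal(evaluate_replication(rep(FALSE, 50)),
               c(fdp = 0, power = 0))
  sel <- rep(FALSE, 50); sel[1:10] <- TRUE
  expect_equal(evaluate_replication(sel), c(fdp = 0, power = 1))
  sel2 <- rep(FALSE, 50); sel2[c(1:5, 21:25)] <- TRUE
  expect_equal(evaluate_replication(sel2), c(fdp = 0.5, power = 0.5))
  expect_error(evaluate_replication(c(TRUE, FALSE), rep(TRUE, 3)),
               "mismatch")
})

test_that("the experiment runner is reproducible and well-formed", {
  t1 <- run_experiment(models = "logistic", dependencies = "independent",
                       Ns = 60L, p = 20L, replications = 3L, seed = 9)
  t2 <- run_experiment(models = "logistic", dependencies = "independent",
                       Ns = 60L, p = 20L, replications = 3L, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 6)  # 3 methods x 2 procedures
  expect_true(all(t1$power >= 0 & t1$power <= 1))
  expect_true(all(t1$fdp >= 0 & t1$fdp <= 1))
  expect_true(all(is.finite(t1$power_se) & is.finite(t1$fdp_se)))

  # a sub-grid reproduces the corresponding cells of a larger grid
  t3 <- run_experiment(models = "logistic",
                       dependencies = c("independent", "dependent"),
                       Ns = 60L, p = 20L, replications = 3L, seed = 9)
  ind <- t3[t3$dependency == "independent", ]
  rownames(ind) <- rownames(t1) <- NULL
  class(ind) <- class(t1) <- "data.frame"
  expect_equal(ind, t1)
})

test_that("every procedure keeps FDP near the target under the global null", {
  cfg_null <- simulation_config("latent", "independent", N = 100L, p = 100L,
                                betas = rep(0, 10), seed = 77)
  set.seed(77)
  acc <- list(edgecount_efron = c(), edgecount_bh = c(),
              welch_efron = c(), welch_bh = c())
  for (r in 1:30) {
    dat <- edgescreen:::generate_dataset(cfg_null)
    lab <- group_labels(dat$y)
    for (m in c("edgecount", "welch")) {
      zres <- edgescreen:::compute_method_z(dat$X, lab, m, k = 3,
                                            mode = "asymptotic")
      ok <- is.finite(zres$z)
      fe <- efron_select(zres$z[ok], alpha = 0.10)
      fb <- bh_select(pmin(pmax(zres$p_value[ok], 0), 1), alpha = 0.10)
      sel_e <- sel_b <- rep(FALSE, 100)
      sel_e[ok] <- fe$selected; sel_b[ok] <- fb$selected
      acc[[paste0(m, "_efron")]] <-
        c(acc[[paste0(m, "_efron")]], evaluate_replication(sel_e)["fdp"])
      acc[[paste0(m, "_bh")]] <-
        c(acc[[paste0(m, "_bh")]], evaluate_replication(sel_b)["fdp"])
    }
  }
  se <- sqrt(0.1 * 0.9 / 30)
  for (nm in names(acc)) expect_lte(mean(acc[[nm]]), 0.10 + 3 * se)
})

test_that("the edge-count test sees the quadratic effect the t test misses", {
  # pure symmetric quadratic effect: group means coincide, so the t test
  # stays at its nominal size while the edge-count test gains power; the
  # gap widens with the quadratic coefficient
  quad_powers <- function(beta, reps, seed) {
    set.seed(seed)
    N <- 500
    hits_ec <- hits_w <- 0
    for (r in 1:reps) {
      x <- runif(N, -1.5, 1.5)
      y <- rbinom(N, 1, plogis(beta * (x^2 - 0.75)))
      lab <- group_labels(y)
      ec <- edgescreen:::compute_method_z(matrix(x), lab, "edgecount",
                                          k = 3, mode = "asymptotic")
      w <- edgescreen:::compute_method_z(matrix(x), lab, "welch")
      hits_ec <- hits_ec + (ec$p_value < 0.05)
      hits_w <- hits_w + (2 * pmin(pnorm(w$z), 1 - pnorm(w$z)) < 0.05)
    }
    c(edge = hits_ec / reps, welch = hits_w / reps)
  }
  # the design's own coefficient: a real but modest edge-count advantage
  p_weak <- quad_powers(0.5, reps = 150, seed = 53)
  expect_lt(p_weak["welch"], 0.12)
  expect_gt(p_weak["edge"] - p_weak["welch"], 0.05)
  # a stronger quadratic tilt: the advantage exceeds 0.2
  p_strong <- quad_powers(1.5, reps = 150, seed = 54)
  expect_lt(p_strong["welch"], 0.12)
  expect_gt(p_strong["edge"] - p_strong["welch"], 0.2)
})
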