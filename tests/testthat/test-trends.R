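test_that("session normalization maps the first session to 0 and the last to 1", {
  expect_equal(normalize_sessions(1:21), seq(0, 1, by = 0.05))
  expect_equal(normalize_sessions(c(4, 9)), c(0, 1))
  # ordering preserved
  set.seed(31)
  idx <- sample(1:30, 12)
  expect_equal(order(normalize_sessions(idx)), order(idx))
  expect_error(normalize_sessions(5), "2 distinct")
  expect_error(normalize_sessions(c(3, 3, 3)), "2 distinct")
})

test_that("slope CIs drive the sign call", {
  x <- 0:5
  up <- slope_with_ci(2 * x, x)
  expect_equal(up$slope, 2)
  expect_equal(up$ci, c(2, 2))
  expect_equal(up$sign_call, "positive")

  flat <- slope_with_ci(rep(3, 6), x)
  expect_equal(flat$slope, 0)
  expect_equal(flat$sign_call, "zero")

  dn <- slope_with_ci(10 - x + c(0.01, -0.01, 0, 0.01, -0.01, 0), x)
  expect_equal(dn$sign_call, "negative")

  # sign_call invariant under positive rescaling (Z-scoring cannot flip it)
  set.seed(32)
  y <- 0.5 * x + rnorm(6, 0, 0.1)
  f1 <- slope_with_ci(y, x)
  f2 <- slope_with_ci(zscore_sessions(y), x)
  expect_equal(f1$sign_call, f2$sign_call)

  expect_error(slope_with_ci(1:2, 1:2), "at least 3")
  expect_error(slope_with_ci(1:5, rep(1, 5)), "constant")

  # methods of the fit object
  expect_equal(unname(coef(up)), c(0, 2))
  expect_equal(confint(up), c(2, 2))
  expect_equal(unname(predict(up, c(10))), 20)
  expect_equal(unname(residuals(flat)), rep(0, 6))
})

test_that("nominal 99% slope CIs achieve their coverage", {
  set.seed(33)
  x <- seq(0, 1, length.out = 15)
  beta <- 1.3
  hits <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    y <- 0.2 + beta * x + rnorm(15, 0, 0.4)
    ci <- slope_with_ci(y, x)$ci
    if (ci[1] <= beta && beta <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.97)
})

test_that("stage summaries partition sessions and test stage contrasts", {
  # constant series: equal means, p = 1
  cs <- stage_summary(rep(2, 9))
  expect_equal(cs$mean, rep(2, 3))
  expect_equal(cs$p_value[1, 3], 1)

  # step increase: 1st vs 3rd stage significant
  set.seed(34)
  step <- c(rnorm(7, 0, 0.2), rnorm(7, 0.5, 0.2), rnorm(7, 2, 0.2))
  ss <- stage_summary(step)
  expect_lt(ss$p_value[1, 3], 0.001)
  expect_true(all(diff(ss$mean) > 0))

  # stage means equal brute-force partition means; remainder goes last
  v <- rnorm(10)
  s10 <- stage_summary(v, 3)
  expect_equal(s10$sizes, c(3, 3, 4))
  expect_equal(s10$mean, c(mean(v[1:3]), mean(v[4:6]), mean(v[7:10])))

  # count-weighted stage means of a Z-scored series average to ~0
  z <- zscore_sessions(rnorm(11))
  sz <- stage_summary(z, 3)
  expect_lt(abs(sum(sz$mean * sz$sizes) / 11), 1e-9)

  expect_error(stage_summary(1:2, 3), "fewer values")
})

test_that("per-subject accuracy-vs-behavior slopes pool into a cohort test", {
  beh <- seq(0.3, 0.8, length.out = 10)
  acc <- 0.5 + 0.4 * beh
  subj <- list(a = acc, b = acc, c = acc)
  behs <- list(a = beh, b = beh, c = beh)
  res <- accuracy_vs_behavior(subj, behs)
  expect_equal(unname(res$slopes), rep(0.4, 3))
  # per-subject slope equals the trend-fit slope
  expect_equal(res$slopes[["a"]], slope_with_ci(acc, beh)$slope)

  # cohort where decoding tracks behavior -> positive mean slope
  set.seed(35)
  subj2 <- lapply(1:5, function(i) 0.45 + 0.5 * beh + rnorm(10, 0, 0.02))
  res2 <- accuracy_vs_behavior(subj2, rep(list(beh), 5))
  expect_gt(mean(res2$slopes), 0)
  expect_lt(res2$slope_test$p.value, 0.01)

  expect_message(
    res1 <- accuracy_vs_behavior(list(a = acc), list(a = beh)),
    "omitted")
  expect_null(res1$slope_test)
})

test_that("the ANCOVA interaction detects unequal slopes and matches a permutation oracle", {
  x <- seq(0, 1, length.out = 20)
  set.seed(36)
  noise <- rnorm(20, 0, 0.01)
  same <- 0.2 + 0.5 * x + noise
  expect_gt(slope_comparison(same, same, x)$p_value, 0.99)

  flat <- 0.5 + rnorm(20, 0, 0.005)
  steep <- 0.5 + 0.04 * x + rnorm(20, 0, 0.005)
  cmp <- slope_comparison(flat, steep, x)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$slopes[["a"]], cmp$slopes[["b"]])

  # permutation oracle: permute the pairing of series to groups
  perm_p <- function(a, b, x, n_perm = 200) {
    obs <- abs(slope_comparison(a, b, x)$slopes %*% c(1, -1))
    y <- cbind(a, b)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      flip <- sample(c(TRUE, FALSE), length(x), replace = TRUE)
      ap <- ifelse(flip, y[, 2], y[, 1]); bp <- ifelse(flip, y[, 1], y[, 2])
      d <- abs(slope_comparison(ap, bp, x)$slopes %*% c(1, -1))
      if (d >= obs) hits <- hits + 1L
    }
    hits / n_perm
  }
  set.seed(37)
  # a clear effect: both routes call it significant
  expect_lt(perm_p(flat, steep, x), 0.05)
  # a null: the two routes agree within Monte-Carlo slack
  null_a <- 0.5 + 0.02 * x + rnorm(20, 0, 0.02)
  null_b <- 0.5 + 0.02 * x + rnorm(20, 0, 0.02)
  p_anc <- slope_comparison(null_a, null_b, x)$p_value
  expect_gt(p_anc, 0.01)
  expect_lt(abs(perm_p(null_a, null_b, x) - p_anc), 0.2)

  expect_error(slope_comparison(flat, steep, rep(1, 20)), "degenerate")
})

test_that("behavior summaries capture learning and latency stabilization", {
  cfg <- generator_config(n_units = 1, n_sessions = 10, trials_per_class = 25,
                          tuning_amplitude = 0,
                          behavior = make_learning_curve(10, 0.308, 0.760,
                                                         0.44, 0.32),
                          seed = 38)
  exp1 <- simulate_experiment(cfg)
  bs <- behavior_summary(exp1)
  expect_equal(bs$n_sessions, 10L)
  expect_lt(bs$mean_accuracy[1], 0.45)
  expect_gt(bs$mean_accuracy[10], 0.65)
  expect_lt(bs$first_vs_last$p.value, 0.001)
  expect_lt(bs$latency_anova_p, 1e-4)
  # latency flat after session 3 -> zero sign call on sessions 4+
  expect_equal(bs$latency_trend$sign_call, "zero")

  # flat curves -> no significant first-vs-last change
  cfg_flat <- generator_config(n_units = 1, n_sessions = 6,
                               trials_per_class = 25, tuning_amplitude = 0,
                               behavior = make_learning_curve(6, 0.7, 0.7,
                                                              0.35, 0.35),
                               seed = 39)
  bs_flat <- behavior_summary(simulate_experiment(cfg_flat))
  expect_gt(bs_flat$first_vs_last$p.value, 0.05)

  # multi-subject cohort uses the across-subject rank-sum
  cfg2 <- cfg; cfg2$seed <- 40L
  bs2 <- behavior_summary(list(exp1, simulate_experiment(cfg2)))
  expect_equal(bs2$n_subjects, 2L)
})
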