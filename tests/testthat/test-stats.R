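test_that("pooled t and Cohen's d agree between raw samples and summaries", {
  set.seed(71)
  a <- rnorm(18, 9.6, 3.2); b <- rnorm(18, 6.0, 2.7)
  raw <- t_and_d(a, b)
  sum_in <- t_and_d(c(mean = mean(a), sd = sd(a), n = 18),
                    c(mean = mean(b), sd = sd(b), n = 18))
  expect_equal(raw$t_stat, sum_in$t_stat, tolerance = 1e-12)
  expect_equal(raw$cohens_d, sum_in$cohens_d, tolerance = 1e-12)
  expect_equal(raw$p_two_sided, sum_in$p_two_sided, tolerance = 1e-12)
  expect_equal(raw$df, 34)

  # cross-check against the standard library implementation on raw data
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(raw$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$p_two_sided, tt$p.value, tolerance = 1e-12)

  # Welch option
  w <- t_and_d(a, b, var_equal = FALSE)
  tw <- t.test(a, b)
  expect_equal(w$t_stat, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-9)
})

test_that("t and d are antisymmetric and vanish for identical groups", {
  set.seed(72)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  ab <- t_and_d(a, b); ba <- t_and_d(b, a)
  expect_equal(ab$t_stat, -ba$t_stat)
  expect_equal(ab$cohens_d, -ba$cohens_d)
  same <- t_and_d(a, a)
  expect_equal(same$t_stat, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(t_and_d(rep(1, 5), rep(1, 6)), "pooled variance")
  expect_error(t_and_d(1, rnorm(5)), "n >= 2")
})

test_that("t-test p-values are uniform under the null", {
  set.seed(73)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    t_and_d(rnorm(10), rnorm(10))$p_two_sided
  }, numeric(1))
  # DKW bound: sup|ecdf - uniform| > 0.05 has prob < 2 exp(-2*2000*0.0025)
  grid <- seq(0.05, 0.95, by = 0.05)
  ec <- ecdf(p)
  expect_lt(max(abs(ec(grid) - grid)), 0.05)
})

test_that("Mann-Whitney U matches the pair-count oracle and wilcox.test", {
  u0 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u0$u_stat, 0)              # complete separation

  same <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$p_two_sided, 1)       # identical multisets, exact

  set.seed(74)
  for (rep in 1:10) {
    a <- sample(1:5, 18, replace = TRUE)  # Likert-style, heavy ties
    b <- sample(1:5, 18, replace = TRUE)
    mw <- mann_whitney(a, b)
    expect_equal(mw$u_stat, oracle_u(a, b))
    expect_equal(mw$u_stat,
                 unname(suppressWarnings(wilcox.test(a, b))$statistic))
  }

  # untied small samples: exact p equals wilcox.test's exact p
  for (rep in 1:10) {
    v <- sample(1:1000, 13)
    a <- v[1:6]; b <- v[7:13]
    expect_equal(mann_whitney(a, b)$p_two_sided,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  # large-sample branch agrees with the corrected normal approximation
  set.seed(75)
  a <- rnorm(30); b <- rnorm(30, 0.3)
  expect_equal(mann_whitney(a, b)$p_two_sided,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("Pearson correlation matches the sum-formula oracle", {
  x <- c(12.1, 8.4, 15.0, 9.9, 11.2, 14.3, 10.5)
  y <- c(9.6, 7.1, 10.2, 8.8, 9.9, 9.1, 8.2)
  got <- pearson_cor(x, y)
  n <- length(x)
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  t_r <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
  expect_equal(got$p_two_sided, 2 * pt(-abs(t_r), n - 2), tolerance = 1e-12)

  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  resid_y <- residuals(lm(y ~ x))
  expect_equal(pearson_cor(x, resid_y)$r, 0, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 7)), "constant")
  expect_error(pearson_cor(1:2, 2:3), "3 complete pairs")
})

test_that("leave-one-dyad-out re-tests with the dyad removed from its group", {
  set.seed(76)
  feats <- data.frame(dyad_id = sprintf("D%02d", 1:36),
                      group = rep(c("TD", "ASD"), each = 18),
                      density = c(rnorm(18, 9.6, 3.2), rnorm(18, 6, 2.7)))
  full <- compare_groups(feats, "density")$density
  expect_equal(full$df, 34)
  loo <- leave_one_out(feats, "density", "D20")
  expect_equal(loo$df, 33)                         # 18 + 17 - 2
  expect_equal(loo$n_b, 17)
  # removing a value equal to its group mean leaves that mean unchanged
  feats$density[1] <- mean(feats$density[feats$group == "TD"][-1])
  m0 <- mean(feats$density[feats$group == "TD"])
  loo1 <- leave_one_out(feats, "density", "D01")
  expect_equal(loo1$mean_a, m0, tolerance = 1e-9)
  expect_error(leave_one_out(feats, "density", "NOPE"), "unknown dyad")
})

test_that("significance pattern is stable under any single exclusion when the effect is large", {
  set.seed(77)
  feats <- data.frame(dyad_id = sprintf("D%02d", 1:36),
                      group = rep(c("TD", "ASD"), each = 18),
                      density = c(rnorm(18, 9.6, 1.2), rnorm(18, 5.9, 1.2)))
  ps <- vapply(feats$dyad_id, function(d)
    leave_one_out(feats, "density", d)$p_two_sided, numeric(1))
  expect_true(all(ps < 0.01))
})

test_that("score summaries return mean and sample SD", {
  s <- score_summary(c(4, 4, 4))
  expect_equal(unname(s[c("mean", "sd")]), c(4, 0))
  one <- score_summary(10)
  expect_equal(unname(one["mean"]), 10)
  expect_true(is.na(one["sd"]))
})

test_that("compare_groups validates structure and orients TD as group A", {
  feats <- data.frame(dyad_id = c("a", "b", "c", "d"),
                      group = c("TD", "TD", "ASD", "ASD"),
                      density = c(9, 10, 5, 6))
  tab <- compare_groups(feats, "density")
  expect_equal(attr(tab, "groups")[["a"]], "TD")
  expect_gt(tab$density$t_stat, 0)
  feats$group <- c("A", "B", "C", "A")
  expect_error(compare_groups(feats, "density"), "two levels")
})
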