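test_that("assumption gate runs Shapiro-Wilk and Levene and flags failures", {
  set.seed(17)
  g <- assumption_gate(list(a = rnorm(30), b = rnorm(30)), alpha = 0.05)
  expect_true(all(g$shapiro$p >= 0 & g$shapiro$p <= 1))
  expect_true(g$levene$p >= 0 && g$levene$p <= 1)

  # a constant group surfaces as an assumption failure, not an abort
  g2 <- assumption_gate(list(a = rep(1, 10), b = rnorm(10)))
  expect_false(g2$shapiro$pass[g2$shapiro$group == "a"])
  expect_false(is.na(g2$shapiro$note[g2$shapiro$group == "a"]))

  expect_error(assumption_gate(list(a = c(1, 2), b = rnorm(10))), "n >= 3")
})

test_that("Levene under the null rarely rejects; Shapiro detects heavy tails", {
  set.seed(29)
  lev_p <- replicate(100, {
    assumption_gate(list(a = rnorm(30), b = rnorm(30)))$levene$p
  })
  expect_gte(mean(lev_p > 0.05), 0.90)
  sw_p <- replicate(100, {
    assumption_gate(list(a = rcauchy(50)))$shapiro$p
  })
  expect_gte(mean(sw_p < 0.05), 0.95)
})

test_that("Levene (center = mean) equals an ANOVA on absolute deviations", {
  set.seed(41)
  groups <- list(a = rnorm(12, sd = 1), b = rnorm(9, sd = 2), c = rnorm(15))
  lv <- assumption_gate(groups)$levene
  absdev <- lapply(groups, function(g) abs(g - mean(g)))
  manual <- one_way_anova(absdev)
  expect_equal(lv$statistic, manual$statistic, tolerance = 1e-10)
  expect_equal(lv$p, manual$p_value, tolerance = 1e-10)
})

test_that("independent t matches stats::t.test on random instances", {
  set.seed(53)
  for (i in 1:100) {
    n1 <- sample(4:25, 1); n2 <- sample(4:25, 1)
    g1 <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    g2 <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    mine <- independent_t(g1, g2, "pooled")
    ref <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df1, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    w <- independent_t(g1, g2, "welch")
    refw <- t.test(g1, g2, var.equal = FALSE)
    expect_equal(w$statistic, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(w$p_value, refw$p.value, tolerance = 1e-10)
  }
})

test_that("independent t handles identical and degenerate samples", {
  g <- c(1.2, 3.4, 2.2, 5.1)
  res <- independent_t(g, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$effect, 0)
  # zero variance in both groups
  same <- independent_t(rep(2, 5), rep(2, 6))
  expect_equal(same$statistic, 0)
  diffm <- independent_t(rep(2, 5), rep(3, 6))
  expect_true(is.infinite(diffm$statistic))
  expect_match(diffm$note, "infinite")
})

test_that("summary-statistic t is self-consistent and reproduces printed tests", {
  set.seed(61)
  g1 <- rnorm(9); g2 <- rnorm(13)
  a <- independent_t(g1, g2, "pooled")
  b <- summary_stat_t(mean(g1), sd(g1), length(g1), mean(g2), sd(g2), length(g2))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(summary_stat_t(5, 1, 7, 5, 2, 7)$statistic, 0)
  # published-summary audit: means 1.79 vs 1.62, SDs 0.55 vs 0.46, n 7/7
  audit <- summary_stat_t(1.79, 0.55, 7, 1.62, 0.46, 7)
  expect_equal(audit$df1, 12)
  expect_equal(audit$statistic, 0.63, tolerance = 0.005)
})

test_that("paired t matches closed form and stats::t.test", {
  res <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # differences {1,1,1,2}: t = 1.25 / (0.5 / 2) = 5, df 3
  res2 <- paired_t(c(0, 0, 0, 0), c(1, 1, 1, 2))
  expect_equal(res2$statistic, 5, tolerance = 1e-12)
  expect_equal(res2$df1, 3)
  set.seed(67)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    pre <- rnorm(n); post <- pre + rnorm(n, 0.3)
    mine <- paired_t(pre, post)
    ref <- t.test(post, pre, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("a 20-degree training shift is detected by the paired test", {
  # metric-level emulation of the preset effect size: pre ~ N(17, 5),
  # post = N(37, 7) drawn independently, n = 7 subjects
  set.seed(71)
  hits <- replicate(50, {
    pre <- rnorm(7, 17, 5)
    post <- rnorm(7, 37, 7)
    paired_t(pre, post)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.80)
})

test_that("one-way ANOVA matches aov and the t-squared identity", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- one_way_anova(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$effect, 0)

  set.seed(73)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(4:15, 1), runif(1)))
    names(groups) <- paste0("g", seq_len(k))
    mine <- one_way_anova(groups)
    y <- unlist(groups, use.names = FALSE)
    f <- factor(rep(names(groups), lengths(groups)))
    ref <- anova(aov(y ~ f))
    expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
    eta_ref <- ref[1, "Sum Sq"] / sum(ref[, "Sum Sq"])
    expect_equal(mine$effect, eta_ref, tolerance = 1e-10)
    expect_true(mine$effect >= 0 && mine$effect <= 1)
  }

  # two-group ANOVA F equals the pooled t statistic squared
  set.seed(79)
  g1 <- rnorm(8); g2 <- rnorm(11, 0.5)
  f2 <- one_way_anova(list(a = g1, b = g2))
  t2 <- independent_t(g1, g2, "pooled")
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-9)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-9)
})

test_that("post hoc pairwise table has per-pair df, symmetry, and Bonferroni", {
  set.seed(83)
  groups <- list(control = rnorm(7), test = rnorm(7), target = rnorm(14, 1))
  ph <- posthoc_pairwise(groups)
  expect_equal(nrow(ph), 6)  # both orderings of 3 pairs
  expect_setequal(unique(ph$df1), c(12, 19))
  # symmetry: p and |t| identical across orderings
  for (i in seq_len(nrow(ph))) {
    mirror <- ph[ph$group1 == ph$group2[i] & ph$group2 == ph$group1[i], ]
    expect_equal(mirror$p_value, ph$p_value[i])
    expect_equal(abs(mirror$statistic), abs(ph$statistic[i]))
  }
  # Bonferroni multiplies by the number of pairs, capped at 1
  phb <- posthoc_pairwise(groups, correction = "bonferroni")
  expect_equal(phb$p_adjusted, pmin(1, phb$p_value * 3))
})

test_that("type-I error of the pooled t is near nominal under the null", {
  set.seed(89)
  rejections <- replicate(400, {
    independent_t(rnorm(7), rnorm(7), "pooled")$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})
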