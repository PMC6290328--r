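# group_stats: every operation is checked against an independent oracle
# (hand-computed sums of squares or the corresponding stats:: routine).

test_that("one-way ANOVA matches hand-computed sums of squares and stats::aov", {
  # {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6, df (2,6) -> F = 3 exactly
  toy <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- one_way_anova(toy)
  expect_equal(res$statistic, 3.0)
  expect_equal(res$df, c(2, 6))
  expect_equal(attr(res, "ss_between"), 6)
  expect_equal(attr(res, "ss_within"), 6)
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))

  # random instances against stats::aov
  set.seed(11)
  for (i in 1:20) {
    g <- lapply(seq_len(sample(2:5, 1)), function(j) rnorm(sample(2:9, 1), j))
    res <- one_way_anova(g)
    d <- data.frame(y = unlist(g), f = factor(rep(seq_along(g), lengths(g))))
    or <- summary(stats::aov(y ~ f, d))[[1]]
    expect_equal(res$statistic, or[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p, or[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases: identical groups and zero within-variance", {
  res <- one_way_anova(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  res <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(res$statistic, Inf)
  expect_equal(res$p, 0)
  expect_true(res$significant)
})

test_that("two-sample t matches hand computation and stats::t.test", {
  # x={1,2,3}, y={4,5,6}: pooled sd = 1, t = -3/sqrt(2/3), df 4
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1), 0.5)
    for (ve in c(TRUE, FALSE)) {
      res <- two_sample_t(x, y, var_equal = ve)
      or <- stats::t.test(x, y, var.equal = ve)
      expect_equal(res$statistic, unname(or$statistic), tolerance = 1e-10)
      expect_equal(res$p, or$p.value, tolerance = 1e-10)
      expect_equal(unname(res$df), unname(or$parameter), tolerance = 1e-8)
    }
  }
  # identical samples and Welch = pooled under equal variance/sizes
  res <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0); expect_equal(res$p, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(two_sample_t(x, y, TRUE)$p, two_sample_t(x, y, FALSE)$p,
               tolerance = 1e-12)
})

test_that("F on two groups equals pooled t squared", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 1)
    Fst <- one_way_anova(list(x, y))$statistic
    tst <- two_sample_t(x, y)$statistic
    expect_equal(Fst, tst^2, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney exact p matches enumeration and wilcox.test", {
  # x={1,2,3}, y={4,5,6}: U = 0, 2/20 labelings as extreme -> p = 0.1
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_match(res$test, "exact")

  set.seed(41)
  for (i in 1:40) {
    nx <- sample(1:6, 1); ny <- sample(1:6, 1)
    if (nx + ny < 2) next
    vals <- sample(1000, nx + ny)   # untied
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    res <- mann_whitney_u(x, y)
    or <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(res$statistic, unname(or$statistic))
    expect_equal(res$p, or$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation is close to exact for n = 4 vs 4", {
  set.seed(51)
  for (i in 1:10) {
    vals <- sample(10000, 8)
    x <- vals[1:4]; y <- vals[5:8]
    pe <- mann_whitney_u(x, y, exact = TRUE)$p
    pa <- mann_whitney_u(x, y, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.05)
  }
  # all ties
  expect_equal(mann_whitney_u(c(3, 3, 3), c(3, 3, 3))$p, 1)
})

test_that("two-way ANOVA matches stats::aov on balanced designs", {
  set.seed(61)
  for (i in 1:10) {
    a <- sample(2:3, 1); b <- sample(2:3, 1); n <- sample(2:4, 1)
    d <- expand.grid(f1 = factor(seq_len(a)), f2 = factor(seq_len(b)),
                     rep = seq_len(n))
    d$y <- rnorm(nrow(d), as.integer(d$f1) + 0.5 * as.integer(d$f2))
    res <- two_way_anova(d$y, d$f1, d$f2)
    or <- summary(stats::aov(y ~ f1 * f2, d))[[1]]
    expect_equal(res$factor1$statistic, or[["F value"]][1], tolerance = 1e-9)
    expect_equal(res$factor2$statistic, or[["F value"]][2], tolerance = 1e-9)
    expect_equal(res$interaction$statistic, or[["F value"]][3], tolerance = 1e-9)
    expect_equal(res$interaction$p, or[["Pr(>F)"]][3], tolerance = 1e-9)
  }
})

test_that("two-way ANOVA edge cases: unbalance, one obs per cell, one level", {
  d <- expand.grid(f1 = factor(1:2), f2 = factor(1:2), rep = 1:3)
  d$y <- rnorm(nrow(d))
  d2 <- rbind(d, data.frame(f1 = factor(1, levels = 1:2),
                            f2 = factor(1, levels = 1:2), rep = 4, y = 1))
  expect_warning(res <- two_way_anova(d2$y, d2$f1, d2$f2), "unbalanced")
  expect_true(is.finite(res$factor1$p))

  d1 <- expand.grid(f1 = factor(1:2), f2 = factor(1:3))
  d1$y <- rnorm(6)
  res <- two_way_anova(d1$y, d1$f1, d1$f2)
  expect_true(is.na(res$interaction$p))
  expect_match(res$interaction$note, "untestable")

  expect_error(two_way_anova(rnorm(4), factor(rep(1, 4)), factor(c(1, 2, 1, 2))),
               "2 levels")
})

test_that("paired comparison: t, exact permutation, and the all-zero null", {
  x <- c(1, 2, 3, 4); y <- x
  expect_equal(paired_comparison(x, y, "permutation")$p, 1)
  expect_equal(paired_comparison(x, y, "t")$p, 1)
  set.seed(71)
  x <- rnorm(8); y <- rnorm(8)
  res <- paired_comparison(x, y, "t")
  or <- stats::t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(or$statistic), tolerance = 1e-10)
  expect_equal(res$p, or$p.value, tolerance = 1e-10)
  # exact sign-flip p has resolution 2^-n and is valid under the null
  res <- paired_comparison(x, y + 10, "permutation")
  expect_equal(res$p, 2 / 256, tolerance = 1e-12)
})

test_that("verdicts are consistent with alpha and p stays in [0, 1]", {
  set.seed(81)
  for (i in 1:25) {
    x <- rnorm(5); y <- rnorm(5, sample(c(0, 3), 1))
    for (res in list(two_sample_t(x, y), mann_whitney_u(x, y),
                     one_way_anova(list(x, y)))) {
      expect_gte(res$p, 0); expect_lte(res$p, 1)
      expect_identical(res$significant, res$p < res$alpha)
    }
  }
})
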