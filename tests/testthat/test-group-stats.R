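test_that("effect sizes and tests reproduce hand-computed values", {
  x <- c(1, 2, 3); y <- c(3, 4, 5)
  expect_equal(cohens_d(x, y), -2)            # pooled SD 1
  tt <- two_sample_t(x, y)
  expect_equal(tt$statistic, -2 / sqrt(2/3), tolerance = 1e-12)
  expect_equal(tt$statistic, -2.449, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.070, tolerance = 1e-2)
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  av <- one_way_anova(groups)
  expect_equal(av$statistic, 3)
  expect_equal(av$df, c(2, 6))
  expect_equal(omega_squared(groups), 4 / 13)
})

test_that("degenerate inputs follow the documented conventions", {
  x <- c(1, 2, 3)
  expect_equal(cohens_d(x, x), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero")
  tt <- two_sample_t(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "unequal means")
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(one_way_anova(same)$statistic, 0)
  expect_equal(one_way_anova(same)$p_value, 1)
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "zero within")
  # a far-shifted group drives p toward 0
  expect_lt(one_way_anova(list(rnorm(5), rnorm(5), rnorm(5) + 100))$p_value,
            1e-6)
})

test_that("t test and ANOVA agree with the stats-package oracles", {
  set.seed(101)
  for (r in 1:50) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), mean = runif(1))
    tt <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(tt$statistic, unname(ref$statistic))
    expect_equal(tt$p_value, ref$p.value)
    # d and t are linked: t = d * sqrt(n1 n2 / (n1 + n2))
    n1 <- length(x); n2 <- length(y)
    expect_equal(tt$statistic, cohens_d(x, y) * sqrt(n1 * n2 / (n1 + n2)))
  }
  for (r in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:10, 1), mean = i / 3))
    av <- one_way_anova(groups)
    dat <- data.frame(y = unlist(groups),
                      g = factor(rep(seq_len(k), lengths(groups))))
    ref <- anova(aov(y ~ g, dat))
    expect_equal(av$statistic, ref[1, "F value"])
    expect_equal(av$p_value, ref[1, "Pr(>F)"])
    # omega squared is always below eta squared
    eta <- ref[1, "Sum Sq"] / sum(ref[, "Sum Sq"])
    expect_lt(omega_squared(groups), eta)
  }
})

test_that("omega squared is near zero (possibly negative) under the null", {
  set.seed(111)
  w <- replicate(400, omega_squared(list(rnorm(10), rnorm(10), rnorm(10))))
  expect_lt(abs(mean(w)), 0.02)
  expect_true(any(w < 0))
})

test_that("compare_measures applies the scalar tests column-wise with missing handling", {
  set.seed(121)
  tab <- data.frame(group = rep(c("a", "b"), each = 10),
                    m01A = rnorm(20), m05 = rnorm(20))
  tab$m05[c(1, 12)] <- NA
  res <- compare_measures(tab)
  expect_equal(res$measure, c("m01A", "m05"))
  g <- split(tab$m01A, tab$group)
  expect_equal(res$statistic[1], two_sample_t(g$a, g$b)$statistic)
  expect_equal(res$effect_size[1], cohens_d(g$a, g$b))
  ok <- !is.na(tab$m05)
  g2 <- split(tab$m05[ok], tab$group[ok])
  expect_equal(res$statistic[2], two_sample_t(g2$a, g2$b)$statistic)
  expect_equal(res$n[2], "9,9")
  # an all-missing measure is flagged, not fatal
  tab$m09 <- NA_real_
  res2 <- compare_measures(tab)
  expect_true(res2$flagged[res2$measure == "m09"])
  # three groups switch to ANOVA + omega squared
  tab3 <- data.frame(group = rep(c("a", "b", "c"), each = 8), m01A = rnorm(24))
  res3 <- compare_measures(tab3)
  expect_equal(res3$test, "anova")
  expect_equal(res3$effect_size, omega_squared(split(tab3$m01A, tab3$group)))
})

test_that("type-I error of the measure-level t test is calibrated", {
  set.seed(131)
  p <- replicate(2000, {
    two_sample_t(rnorm(15), rnorm(15))$p_value
  })
  expect_gt(mean(p < 0.05), 0.035)
  expect_lt(mean(p < 0.05), 0.065)
})
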