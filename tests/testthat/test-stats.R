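test_that("identical samples sit at the null centre", {
  res <- rankTest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 4.5)  # n1*n2/2
})

test_that("rank-sum statistic and p match the exhaustive permutation oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(10, 11, 12, 13)
  res <- rankTest(c(x, y), rep(c("a", "b"), each = 4))
  oracle <- permutation_oracle(x, y)
  expect_equal(res$statistic, oracle$statistic)
  expect_equal(res$p_value, oracle$p)
  # random untied inputs with combined n <= 10
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    v <- sample(seq_len(100), n1 + n2)  # distinct -> no ties
    res <- rankTest(v, rep(c("a", "b"), c(n1, n2)))
    oracle <- permutation_oracle(v[seq_len(n1)], v[-seq_len(n1)])
    expect_equal(res$statistic, oracle$statistic)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("three identical groups give Kruskal-Wallis H = 0", {
  v <- rep(c(5, 6, 7), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- rankTest(v, g)
  kw <- res[res$test == "kruskal_wallis", ]
  expect_equal(kw$statistic, 0)
  expect_equal(nrow(res), 1 + 3)  # global + three pairwise rows
  expect_true(all(res$p_adjusted <= 1))
})

test_that("pairwise post-hoc p-values carry BH adjustment", {
  set.seed(8)
  v <- c(rnorm(5), rnorm(5, 3), rnorm(5, 6))
  g <- rep(c("a", "b", "c"), each = 5)
  res <- rankTest(v, g)
  pw <- res[res$test == "wilcoxon_rank_sum", ]
  expect_equal(pw$p_adjusted, p.adjust(pw$p_value, "BH"))
  # BH never decreases a p-value and stays bounded
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15))
  expect_true(all(pw$p_adjusted <= 1))
})

test_that("undersized groups are rejected", {
  expect_error(rankTest(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("the chi-squared screen tests the farthest value once", {
  res <- chisqOutlier(c(1, 2, 3, 100))
  expect_equal(res$candidate, 100)
  m <- mean(c(1, 2, 3, 100))
  v <- var(c(1, 2, 3, 100))
  expect_equal(res$statistic, (100 - m)^2 / v)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  # with n = 4 and the sample variance inflated by the extreme value itself,
  # the single-outlier statistic cannot reach significance here
  expect_false(res$removed)
  expect_identical(res$values, c(1, 2, 3, 100))

  res3 <- chisqOutlier(c(1, 2, 3))
  expect_false(res3$removed)
  expect_gt(res3$p, 0.05)
})

test_that("a clear outlier in a larger sample is removed", {
  vals <- c(rep(c(9.8, 10, 10.2), 10), 100)
  res <- chisqOutlier(vals)
  expect_equal(res$candidate, 100)
  expect_true(res$removed)
  expect_length(res$values, length(vals) - 1)
})

test_that("equidistant extremes break ties deterministically", {
  r1 <- chisqOutlier(c(-5, 0, 5))
  r2 <- chisqOutlier(c(-5, 0, 5))
  expect_identical(r1$candidate, r2$candidate)
  expect_true(abs(r1$candidate) == 5)
})

test_that("remove-and-recall converges without oscillation", {
  set.seed(31)
  vals <- c(rnorm(20), 50)
  for (i in 1:25) {
    res <- chisqOutlier(vals)
    if (!res$removed) break
    expect_lt(length(res$values), length(vals))
    vals <- res$values
  }
  expect_false(chisqOutlier(vals)$removed)
})

test_that("degenerate outlier inputs are rejected", {
  expect_error(chisqOutlier(c(1, 2)), "at least 3")
  expect_error(chisqOutlier(c(2, 2, 2)), "variance")
})
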