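test_that("FPM scales counts by library size", {
  counts <- matrix(c(10, 0, 5, 20), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fpm <- computeFPM(counts, librarySizes = c(1e6, 1e6))
  expect_equal(fpm["g1", "s1"], 10)
  expect_equal(fpm["g2", "s1"], 0)
  # normalization identity: with library sizes = column sums, columns sum to 1e6
  set.seed(2)
  m <- matrix(rpois(200, 50), 20, 10)
  fpm2 <- computeFPM(m)
  expect_equal(unname(colSums(fpm2)), rep(1e6, 10))
  expect_error(computeFPM(m, librarySizes = rep(0, 10)), "> 0")
})

test_that("group means are attached when groups are given", {
  m <- matrix(c(10, 10, 30, 50), 1, 4)
  fpm <- computeFPM(m, librarySizes = rep(1e6, 4),
                    groups = c("a", "a", "b", "b"))
  gm <- attr(fpm, "groupMeans")
  expect_equal(unname(gm[1, ]), c(10, 40))
})

test_that("DEG thresholds are inclusive on FC and FDR, strict on FPM", {
  tab <- data.frame(
    gene_id = c("boundary", "below_fc", "fpm_at_5"),
    log2fc = c(0.59, 0.58, 2.0),
    fdr = c(0.05, 0.01, 0.001),
    fpm_ctrl = c(6, 100, 5),
    fpm_treat = c(1, 100, 5)
  )
  kept <- filterDEGs(tab)
  expect_identical(kept$gene_id, "boundary")
  expect_error(filterDEGs(tab[, -2]), "log2fc")
  expect_error(filterDEGs(tab[, 1:3]), "fpm_")
})

test_that("the DEG filter is monotone in every threshold", {
  set.seed(10)
  tab <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    log2fc = rnorm(200, 0, 1),
    fdr = runif(200),
    fpm_ctrl = exp(rnorm(200, 2, 1)),
    fpm_treat = exp(rnorm(200, 2, 1))
  )
  strict <- filterDEGs(tab)$gene_id
  expect_true(all(strict %in% filterDEGs(tab, fcThreshold = 0.3)$gene_id))
  expect_true(all(strict %in% filterDEGs(tab, fdrThreshold = 0.2)$gene_id))
  expect_true(all(strict %in% filterDEGs(tab, fpmThreshold = 1)$gene_id))
})

test_that("Venn regions agree with exhaustive enumeration", {
  set.seed(33)
  pool <- sprintf("g%02d", 1:20)
  for (i in 1:20) {
    a <- sample(pool, sample(0:20, 1))
    b <- sample(pool, sample(0:20, 1))
    c3 <- sample(pool, sample(0:20, 1))
    vp <- vennPartition(a, b, c3)
    expect_identical(unname(vennCounts(vp)), venn_oracle(a, b, c3))
    # per-set total = sum of its four regions
    cnt <- vennCounts(vp)
    expect_equal(
      unname(vennTotals(vp)["HCl"]),
      unname(sum(cnt[c("HCl", "HCl&LA", "HCl&Na_lactate", "HCl&LA&Na_lactate")]))
    )
  }
  empty <- vennPartition(character(), character(), character())
  expect_true(all(vennCounts(empty) == 0))
})

test_that("the acidosis margin follows from the printed totals", {
  # 492 genes regulated by HCl, 433 of them shared with LA, none shared with
  # the lactate-only set: 59 must be HCl-specific
  hcl <- sprintf("g%04d", 1:492)
  la <- c(sprintf("g%04d", 1:433), sprintf("la%04d", 1:1200))
  lactate <- sprintf("na%04d", 1:15)
  vp <- vennPartition(hcl, la, lactate)
  expect_equal(unname(vennCounts(vp)["HCl"]), 59L)
  expect_equal(unname(vennCounts(vp)["HCl&LA"]), 433L)
})

test_that("concordance handles identity, anti-identity and relabeling", {
  tab <- data.frame(gene_id = letters[1:10], log2fc = c(-2:-1, 1:8) / 2)
  same <- concordance(tab, tab)
  expect_equal(fractionSameSign(same), 1.0)
  expect_equal(concordanceSlope(same), 1.0)
  flipped <- tab
  flipped$log2fc <- -flipped$log2fc
  expect_equal(fractionSameSign(concordance(tab, flipped)), 0.0)
  # fraction invariant under A <-> B
  set.seed(4)
  a <- data.frame(gene_id = letters[1:20], log2fc = rnorm(20))
  b <- data.frame(gene_id = letters[1:20], log2fc = rnorm(20))
  expect_equal(
    fractionSameSign(concordance(a, b)),
    fractionSameSign(concordance(b, a))
  )
  expect_error(
    concordance(a[1, ], b),
    "fewer than 2"
  )
})

test_that("TLS slopes are reciprocal on collinear data", {
  x <- seq(-3, 3, length.out = 30)
  a <- data.frame(gene_id = sprintf("g%02d", 1:30), log2fc = x)
  b <- data.frame(gene_id = sprintf("g%02d", 1:30), log2fc = 0.6 * x)
  s_ab <- concordanceSlope(concordance(a, b, slopeMethod = "tls"))
  s_ba <- concordanceSlope(concordance(b, a, slopeMethod = "tls"))
  expect_equal(s_ab, 0.6, tolerance = 1e-10)
  expect_equal(s_ab * s_ba, 1, tolerance = 1e-10)
})

test_that("exact zero log2FC counts as discordant with non-zero", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(0, 1, -1))
  b <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(1, 1, -1))
  expect_equal(fractionSameSign(concordance(a, b)), 2 / 3)
})
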