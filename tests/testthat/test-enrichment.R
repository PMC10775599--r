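test_that("the fold-enrichment statistic matches the worked formula", {
  domain <- sprintf("g%05d", 1:20000)
  query <- domain[1:100]
  # term of 200 genes, 10 of them in the query
  term <- list(focus = c(domain[1:10], domain[10001:10190]))
  res <- enrich(query, term, domain, filter = FALSE)
  expect_equal(res$E, (10 / 100) / (200 / 20000))  # = 10
  expect_equal(res$intersection_size, 10L)
})

test_that("terms outside the 5-3000 size window are never tested", {
  domain <- sprintf("g%04d", 1:5000)
  terms <- list(
    tiny = domain[1:4],
    ok = domain[1:50],
    huge = domain[1:3001]
  )
  res <- enrich(domain[1:20], terms, domain, filter = FALSE)
  expect_identical(res$term_id, "ok")
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  domain <- sprintf("g%02d", 1:50)
  set.seed(19)
  for (i in 1:10) {
    m <- sample(5:30, 1)
    term <- list(t = sample(domain, m))
    q <- sample(domain, sample(5:25, 1))
    res <- enrich(q, term, domain, filter = FALSE)
    p_oracle <- hyper_oracle(res$intersection_size, m, 50, length(q))
    expect_equal(res$p_hyper, p_oracle, tolerance = 1e-10)
  }
})

test_that("E is invariant to doubling all four set sizes", {
  e_of <- function(k, q, m, N) (k / q) / (m / N)
  expect_equal(e_of(10, 100, 200, 20000), e_of(20, 200, 400, 40000))
})

test_that("the E and adjusted-p thresholds jointly gate the output", {
  set.seed(23)
  domain <- sprintf("g%04d", 1:2000)
  query <- domain[1:80]
  terms <- c(
    # strongly enriched term: 40 of its 60 genes in the query
    list(enriched = c(domain[1:40], domain[1001:1020])),
    # unenriched random terms
    lapply(stats::setNames(nm = paste0("r", 1:10)),
           function(i) sample(domain, 100))
  )
  res <- enrich(query, terms, domain)
  expect_true("enriched" %in% res$term_id)
  expect_true(all(res$p_adjusted <= 0.001))
  expect_true(all(res$E >= 2.5))
  full <- enrich(query, terms, domain, filter = FALSE)
  expect_equal(nrow(full), 11L)
  # BH is monotone and bounded
  ord <- order(full$p_hyper)
  expect_true(all(diff(full$p_adjusted[ord]) >= -1e-12))
  expect_true(all(full$p_adjusted <= 1))
})

test_that("degenerate enrichment inputs are rejected", {
  domain <- sprintf("g%02d", 1:50)
  expect_error(enrich(character(), list(t = domain[1:10]), domain), "empty")
  expect_error(
    enrich("not_in_domain", list(t = domain[1:10]), domain),
    "subset"
  )
  expect_error(
    enrich(domain[1:5], list(t = domain[1:10]), domain = 8),
    "smaller"
  )
})

test_that("GMT files round-trip", {
  sets <- list(a = c("g1", "g2"), b = c("g2", "g3", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sets, path, description = c("first", "second"))
  back <- readGMT(path)
  expect_identical(back[["a"]], sets$a)
  expect_identical(back[["b"]], sets$b)
  expect_identical(attr(back, "description"), c("first", "second"))
})
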