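test_that("the hypergeometric tail matches small closed-form cases", {
  expect_equal(fisherOverrep(0, 5, 5, 10), 1)
  expect_equal(fisherOverrep(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(fisherOverrep(1, 2, 2, 4), 5 / 6)
  expect_error(fisherOverrep(3, 2, 5, 10), "validation error")
  expect_error(fisherOverrep(1, 5, 2, 4), "validation error")
})

test_that("the tail stays exact in log space for large universes", {
  # cross-check against R's own hypergeometric tail (an independent path)
  cases <- list(c(9, 105, 60, 3000), c(25, 105, 400, 9673),
                c(5, 40, 300, 1e5), c(60, 80, 90, 1e5))
  for (cs in cases) {
    p <- fisherOverrep(cs[1], cs[2], cs[3], cs[4])
    ref <- stats::phyper(cs[1] - 1, cs[3], cs[4] - cs[3], cs[2],
                         lower.tail = FALSE)
    expect_equal(p, ref, tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(cs[1], cs[2] - cs[1], cs[3] - cs[1],
                                      cs[4] - cs[3] - cs[2] + cs[1]), 2),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-8)
  }
})

test_that("the hypergeometric pmf sums to one", {
  set.seed(9)
  for (rep in 1:20) {
    N <- sample(5:200, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    pmf <- vapply(ks, function(k) {
      hi <- fisherOverrep(k, n, K, N)
      lo <- if (k + 1 > min(n, K)) 0 else fisherOverrep(k + 1, n, K, N)
      hi - lo
    }, 1.0)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("the EASE score nulls singleton overlaps and dominates Fisher", {
  expect_equal(easeScore(1, 10, 5, 100), 1)
  expect_equal(easeScore(0, 10, 5, 100), 1)
  expect_equal(easeScore(4, 10, 5, 100), fisherOverrep(3, 10, 5, 100))
  set.seed(21)
  for (rep in 1:100) {
    N <- sample(2:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_gte(easeScore(k, n, K, N), fisherOverrep(k, n, K, N))
  }
})

test_that("BH step-up matches the hand computation and stats::p.adjust", {
  expect_equal(bhFDR(0.04), 0.04)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(c(1, 1)), c(1, 1))
  set.seed(31)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bhFDR(p), stats::p.adjust(p, "BH"))
    # permutation invariance
    perm <- sample(seq_along(p))
    expect_equal(bhFDR(p)[perm], bhFDR(p[perm]))
  }
  expect_error(bhFDR(c(0.5, 1.2)), "validation error")
})

test_that("gene-set enrichment ranks a planted covering term first", {
  set.seed(41)
  universe <- sprintf("G%04d", 1:1000)
  query <- sample(universe, 10)
  gs <- generateGeneSets(universe, nTerms = 50, sizeRange = c(10, 12),
                         plantedQuery = query, rngSeed = 99)
  res <- enrichGeneSets(query, gs$sets, universe)
  expect_identical(res$term_id[1], gs$plantedId)
  expect_lt(res$p_value[1], 1e-10)
  # agreement with the exhaustive oracle at reduced size
  small <- enrichGeneSets(c("A", "B"), geneSetList(list(t1 = c("A", "B", "C"))),
                          universe = c("A", "B", "C", "D", "E", "F"),
                          method = "fisher")
  expect_equal(small$p_value, oracle_fisher_tail(2, 2, 3, 6))
})

test_that("enrichment handles disjoint queries, universes and method choice", {
  sets <- geneSetList(list(t1 = c("X1", "X2"), t2 = c("Y1", "Y2", "Y3")))
  uni <- c("A", "B", "X1", "X2", "Y1", "Y2", "Y3")
  res <- enrichGeneSets(c("A", "B"), sets, uni)
  expect_true(all(res$p_value == 1))
  # ease ranks k=1 overlaps last, fisher does not
  sets2 <- geneSetList(list(hit1 = c("A", "Z1"), none = c("Z2", "Z3")))
  rf <- enrichGeneSets("A", sets2, c("A", "Z1", "Z2", "Z3"), method = "fisher")
  re <- enrichGeneSets("A", sets2, c("A", "Z1", "Z2", "Z3"), method = "ease")
  expect_lt(rf$p_value[rf$term_id == "hit1"], 1)
  expect_equal(re$p_value[re$term_id == "hit1"], 1)
  expect_warning(enrichGeneSets(c("A", "OUTSIDE"), sets, uni), "dropped")
  expect_error(enrichGeneSets("A", sets, character()), "empty universe")
})

test_that("significance filtering is strict at both thresholds", {
  df <- data.frame(term_id = c("a", "b", "c"),
                   p_value = c(1e-3, 1e-4, 1e-4),
                   q_bh = c(0.001, 0.01, 0.005))
  kept <- filterSignificant(df, pMax = 1e-3, qMax = 0.01)
  expect_identical(kept$term_id, "c")  # p=1e-3 excluded; q=0.01 excluded
  expect_equal(nrow(filterSignificant(df[0, , drop = FALSE])), 0L)
})
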