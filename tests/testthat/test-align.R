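test_that("label vectors project genes onto one namespace", {
  n <- nbhFromLabels(list("PF1", character(0), c("PF2", "PF3")),
                     anchorIndex = 2L)
  lv <- labelVector(n, "Pfam")
  expect_equal(lv@entries, list("PF1", character(0), c("PF2", "PF3")))
  expect_equal(lv@anchorIndex, 2L)
  # absent namespace: same shape, all entries empty
  lv2 <- labelVector(n, "KEGG")
  expect_equal(length(lv2@entries), 3L)
  expect_true(all(lengths(lv2@entries) == 0))
  expect_equal(lv2@anchorIndex, lv@anchorIndex)
})

test_that("local alignment matches hand-checked examples", {
  p <- alignParams(tryReverse = FALSE)
  # perfect self-alignment of distinct singletons
  u <- list("A", "B", "C", "D")
  expect_equal(alignmentScore(localAlign(u, u, p)), 4)
  # disjoint vectors hit the local floor
  expect_equal(alignmentScore(localAlign(u, list("X", "Y"), p)), 0)
  expect_equal(nrow(alignedPairs(localAlign(u, list("X", "Y"), p))), 0L)
  # the B-C block
  r <- localAlign(u, list("X", "B", "C", "Y"), p)
  expect_equal(alignmentScore(r), 2)
  expect_equal(unname(alignedPairs(r)), matrix(c(2L, 3L, 2L, 3L), ncol = 2))
  # reversal recovers a perfect alignment
  rr <- localAlign(list("A", "B", "C"), list("C", "B", "A"))
  expect_equal(alignmentScore(rr), 3)
  expect_true(isReversed(rr))
  # empty-set entries never match, even against each other
  expect_equal(alignmentScore(localAlign(list(character(0)),
                                         list(character(0)), p)), 0)
  # multi-label sets match on any shared label
  expect_equal(alignmentScore(localAlign(list(c("A", "B")),
                                         list(c("B", "Z")), p)), 1)
  expect_error(localAlign(list(), u), "empty neighborhood")
})

test_that("DP score equals the exhaustive oracle on random short vectors", {
  withr::with_seed(42, {
    for (i in 1:400) {
      u <- randLabelVector()
      v <- randLabelVector()
      p <- alignParams(tryReverse = (i %% 2 == 0))
      expect_equal(alignmentScore(localAlign(u, v, p)),
                   alignScoreExhaustive(u, v, p))
    }
  })
})

test_that("alignment score is symmetric and bounded", {
  withr::with_seed(7, {
    for (i in 1:100) {
      u <- randLabelVector()
      v <- randLabelVector()
      p <- alignParams(tryReverse = (i %% 2 == 0))
      su <- alignmentScore(localAlign(u, v, p))
      sv <- alignmentScore(localAlign(v, u, p))
      expect_equal(su, sv)
      expect_lte(su, p$match * min(length(u), length(v)))
      expect_gte(su, 0)
    }
  })
})

test_that("appending a fresh shared label to both ends adds one match", {
  withr::with_seed(11, {
    for (i in 1:50) {
      u <- randLabelVector()
      v <- randLabelVector()
      p <- alignParams(tryReverse = FALSE)
      s0 <- alignmentScore(localAlign(u, v, p))
      # fresh label seen nowhere else
      u2 <- c(u, list("ZZZ"))
      v2 <- c(v, list("ZZZ"))
      s1 <- alignmentScore(localAlign(u2, v2, p))
      # the new aligned ends contribute exactly one match when the old
      # optimum reached the ends, never more
      expect_gte(s1, s0)
      expect_lte(s1, s0 + p$match)
    }
  })
})

test_that("traceback ties resolve to the smallest coordinates", {
  p <- alignParams(tryReverse = FALSE)
  # two equally good single matches: (1,1) preferred over (2,2)
  r <- localAlign(list("A", "B"), list("A", "B"), p)
  expect_equal(alignmentScore(r), 2)  # diagonal run beats either single
  r2 <- localAlign(list("A", "X"), list("A", "Y"), p)
  expect_equal(unname(alignedPairs(r2)), matrix(c(1L, 1L), ncol = 2))
  r3 <- localAlign(list("A", "A"), list("A", "A"), p)
  expect_equal(alignmentScore(r3), 2)
})

test_that("similarity is self-normalized, symmetric and bounded", {
  u <- list("A", "B", "C", "D")
  v <- list("X", "B", "C", "Y")
  expect_equal(contextSimilarity(u, u), 1)
  expect_equal(contextSimilarity(u, v), 0.5)  # 2 / min(4, 4)
  expect_equal(contextSimilarity(v, u), 0.5)
  expect_equal(contextSimilarity(u, list("Q", "R")), 0)
  # all-empty vectors: similarity 0 with a warning
  expect_warning(
    s0 <- contextSimilarity(list(character(0)), list(character(0))),
    "unannotated")
  expect_equal(s0, 0)
  withr::with_seed(3, {
    for (i in 1:50) {
      a <- randLabelVector()
      b <- randLabelVector()
      s <- suppressWarnings(contextSimilarity(a, b))
      expect_gte(s, 0)
      expect_lte(s, 1)
      expect_equal(s, suppressWarnings(contextSimilarity(b, a)))
    }
  })
})
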