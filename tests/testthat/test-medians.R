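toyTrees <- function() lapply(c("((...))", "((...))", "(.....)"), parseDotBracket)

# uniform random median instance from the complete theta = 0 universe
randomInstanceTrees <- function(n, p) {
  replicate(p, oracleRandomStructure(n, 0L), simplify = FALSE)
}

test_that("majority-rule consensus solves the toy RF median instance", {
  r <- rfMedian(toyTrees())
  expect_equal(writeDotBracket(r$median), "((...))")
  expect_equal(r$cost, 1)

  # a strict-majority tree is one optimum for p = 2 as well
  r2 <- rfMedian(lapply(c("((...))", "(.....)"), parseDotBracket))
  expect_equal(writeDotBracket(r2$median), "(.....)")
  expect_equal(r2$cost, 1)

  same <- lapply(rep("(.(.).)", 4), parseDotBracket)
  r3 <- rfMedian(same)
  expect_equal(writeDotBracket(r3$median), "(.(.).)")
  expect_equal(r3$cost, 0)
})

test_that("descendant leafsets at exactly half occurrence are excluded", {
  trees <- lapply(c("((...))", "(.....)"), parseDotBracket)
  r <- rfMedian(trees)
  # the pair (2,6) occurs in exactly p/2 trees and must not be displayed
  expect_false("2,6" %in% apply(basePairs(r$median), 1, paste, collapse = ","))
})

test_that("internal-leafset block costs count occurrences", {
  trees <- toyTrees()
  expect_equal(ilCost(c(0, 8), trees), -3L)
  expect_equal(ilCost(c(1, 7), trees), -1L)
  expect_equal(ilCost(c(1, 2, 3), trees), 3L)
})

test_that("the block-cost identity links partition cost and median cost", {
  set.seed(31)
  for (rep in 1:10) {
    trees <- randomInstanceTrees(7, 3)
    sumIl <- sum(vapply(trees, function(t)
      length(internalLeafsets(structureToTree(t))), integer(1)))
    for (r in 1:5) {
      cand <- oracleRandomStructure(7, 0L)
      blocks <- internalLeafsets(structureToTree(cand))
      lhs <- sum(vapply(blocks, function(b) ilCost(b, trees), numeric(1)))
      expect_equal(lhs + sumIl, medianCost(cand, trees, "IL"))
    }
  }
})

test_that("constrained internal-leafset median solves the toy instances", {
  r <- ilIlcMedian(toyTrees())
  expect_equal(writeDotBracket(r$median), "((...))")
  expect_equal(r$partitionCost, -5)
  expect_equal(r$cost, 3)

  r2 <- ilIlcMedian(lapply(c("((...))", "(.....)"), parseDotBracket))
  expect_equal(r2$partitionCost, -2)
  expect_equal(r2$cost, 3)

  single <- list(parseDotBracket("(.(.).)"))
  r3 <- ilIlcMedian(single)
  expect_equal(writeDotBracket(r3$median), "(.(.).)")
  expect_equal(r3$cost, 0)
})

test_that("maximum-weight independent interval sets are found exactly", {
  r <- mwisIntervals(cbind(c(1, 2, 4), c(3, 5, 6), c(2, 3, 4)))
  expect_equal(r$value, 6)
  expect_equal(sort(r$chosen), c(1L, 3L))

  expect_equal(mwisIntervals(matrix(numeric(0), 0, 3))$value, 0)
  expect_equal(mwisIntervals(cbind(1, 2, -1))$chosen, integer(0))

  # brute-force cross-check over random interval families
  set.seed(32)
  for (rep in 1:25) {
    m <- sample(1:7, 1)
    lo <- sample(1:15, m, replace = TRUE)
    len <- sample(0:5, m, replace = TRUE)
    w <- sample(-3:6, m, replace = TRUE)
    iv <- cbind(lo, lo + len, w)
    got <- mwisIntervals(iv)
    best <- 0
    for (mask in 0:(2^m - 1L)) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) > 0L)
      if (length(sel) > 1L) {
        ok <- TRUE
        for (a in seq_len(length(sel) - 1L)) for (b in seq(a + 1L, length(sel))) {
          if (max(iv[sel[a], 1L], iv[sel[b], 1L]) <=
              min(iv[sel[a], 2L], iv[sel[b], 2L])) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      best <- max(best, sum(iv[sel, 3L]))
    }
    expect_equal(got$value, best)
    # chosen set is disjoint and attains the value
    if (length(got$chosen) > 1L) {
      ch <- iv[got$chosen, , drop = FALSE]
      ch <- ch[order(ch[, 1L]), , drop = FALSE]
      expect_true(all(ch[-1L, 1L] > ch[-nrow(ch), 2L]))
    }
    expect_equal(sum(iv[got$chosen, 3L]), got$value)
  }
})

test_that("constrained median DPs equal exhaustive partition search", {
  set.seed(33)
  for (rep in 1:12) {
    n <- sample(5:8, 1); p <- sample(2:4, 1)
    trees <- randomInstanceTrees(n, p)
    expect_equal(ilIlcMedian(trees)$cost, oracleIlcMedian(trees, "IL"))
    expect_equal(rfIlcMedian(trees)$cost, oracleIlcMedian(trees, "RF"))
  }
})

test_that("unconstrained solvers equal exhaustive search over all trees", {
  set.seed(34)
  for (rep in 1:12) {
    n <- sample(5:8, 1); p <- sample(2:4, 1)
    trees <- randomInstanceTrees(n, p)
    expect_equal(rfMedian(trees)$cost, oracleMedianOverAllTrees(trees, "RF")$cost)
    expect_equal(ilNcMedian(trees)$cost, oracleMedianOverAllTrees(trees, "IL")$cost)
  }
})

test_that("relaxing the leafset constraint never increases the optimum", {
  set.seed(35)
  for (rep in 1:10) {
    trees <- randomInstanceTrees(7, 3)
    expect_lte(ilNcMedian(trees)$cost, ilIlcMedian(trees)$cost)
    expect_lte(rfMedian(trees)$cost, rfIlcMedian(trees)$cost)
  }
})

test_that("duplicating every input doubles the optimal cost", {
  set.seed(36)
  for (rep in 1:5) {
    trees <- randomInstanceTrees(6, 3)
    doubled <- c(trees, trees)
    expect_equal(ilIlcMedian(doubled)$cost, 2 * ilIlcMedian(trees)$cost)
    expect_equal(ilNcMedian(doubled)$cost, 2 * ilNcMedian(trees)$cost)
  }
})

test_that("median costs are evaluated against the requested metric", {
  trees <- toyTrees()
  cand <- parseDotBracket("((...))")
  expect_equal(medianCost(cand, trees, "RF"), 1)
  expect_equal(medianCost(cand, trees, "IL"), 3)
  expect_equal(medianCost(trees[[1L]], lapply(rep("((...))", 3), parseDotBracket),
                          "RE"), 0)
})
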