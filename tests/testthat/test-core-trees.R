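test_that("dot-bracket parsing matches brackets and reports offending positions", {
  s <- parseDotBracket("((...))")
  expect_equal(seqLength(s), 7L)
  expect_equal(basePairs(s), rbind(c(1L, 7L), c(2L, 6L)))

  expect_equal(nrow(basePairs(parseDotBracket("......."))), 0L)

  expect_error(parseDotBracket("((...)"), "unbalanced '\\('")
  expect_error(parseDotBracket(".)."), "position 2")
  expect_error(parseDotBracket("(x)"), "invalid character")
})

test_that("structure-to-tree conversion adds the fictive root and orders children", {
  t <- structureToTree(RNAStructure(7, rbind(c(1, 7), c(2, 6))))
  expect_equal(internalNodes(t), rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L)))
  expect_equal(internalLeafsets(t)[[3L]], 2:6)

  flat <- structureToTree(RNAStructure(3))
  expect_equal(internalNodes(flat), rbind(c(0L, 4L)))
  expect_equal(internalLeafsets(flat)[[1L]], 0:4)

  # sibling pairs ordered left-to-right under the root
  t2 <- structureToTree(RNAStructure(9, rbind(c(1, 5), c(6, 9))))
  expect_equal(internalNodes(t2), rbind(c(0L, 10L), c(1L, 5L), c(6L, 9L)))
})

test_that("descendant and internal leafsets read off the node structure", {
  expect_equal(descendantLeafsets(parseDotBracket("((...))")),
               rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L)))
  expect_equal(descendantLeafsets(parseDotBracket("(.....)")),
               rbind(c(0L, 8L), c(1L, 7L)))

  ils <- internalLeafsets(parseDotBracket("(.(.).)"))
  expect_equal(ils, list(c(0L, 8L), c(1L, 2L, 6L, 7L), 3:5))
  expect_equal(internalLeafsets(parseDotBracket("(.....)"))[[2L]], 1:7)
})

test_that("leafset conflict predicates follow the interval/interleaving rules", {
  expect_true(dlConflict(c(1, 5), c(3, 8)))
  expect_false(dlConflict(c(1, 5), c(2, 4)))
  expect_false(dlConflict(c(1, 5), c(6, 9)))

  expect_false(ilConflict(c(1, 7), c(2, 6)))
  expect_true(ilConflict(c(1, 4), c(2, 6)))
  expect_true(ilConflict(c(1, 4), c(4, 6)))
  expect_false(ilConflict(c(1, 2), c(3, 4)))
  expect_false(ilConflict(c(1, 3, 9), c(4, 6)))  # inside one gap
  expect_true(ilConflict(c(1, 5, 9), c(4, 6)))   # straddles a member
})

test_that("gaps are the maximal uncovered intervals between members", {
  expect_equal(ilGaps(c(1, 7)), rbind(c(2L, 6L)))
  expect_equal(ilGaps(c(1, 2, 6, 7)), rbind(c(3L, 5L)))
  expect_equal(ilGaps(c(0, 3, 8)), rbind(c(1L, 2L), c(4L, 7L)))
  expect_equal(nrow(ilGaps(c(4, 5))), 0L)
})

test_that("trees rebuild from conflict-free descendant leafsets, and only those", {
  t <- treeFromDLs(rbind(c(0, 8), c(1, 7), c(2, 6)), 7)
  expect_equal(writeDotBracket(t), "((...))")
  expect_equal(writeDotBracket(treeFromDLs(rbind(c(0, 8)), 7)), ".......")

  expect_error(treeFromDLs(rbind(c(0, 8), c(1, 5), c(3, 8)), 7), "conflict")
  expect_error(treeFromDLs(rbind(c(1, 7)), 7), "full interval")
  # endpoint sharing is impossible in an RNA tree even though the intervals
  # are nested
  expect_error(treeFromDLs(rbind(c(0, 8), c(1, 5), c(1, 3)), 7), "")
})

test_that("trees rebuild from structural partitions, and invalid partitions fail", {
  t <- treeFromStructuralPartition(list(c(0, 8), c(1, 7), 2:6), 7)
  expect_equal(writeDotBracket(t), "((...))")
  expect_equal(writeDotBracket(treeFromStructuralPartition(list(c(0, 8), 1:7), 7)),
               "(.....)")

  expect_error(treeFromStructuralPartition(list(c(0, 8), c(1, 7)), 7),
               "partition")
  expect_error(treeFromStructuralPartition(list(c(0, 8), c(1, 7), 2:6, 9), 7),
               "size at least 2|partition")
  expect_error(treeFromStructuralPartition(list(c(0, 1), c(2, 8), 3:7), 7),
               "same block")
})

test_that("structure <-> tree and leafset round trips hold on the full universe", {
  for (n in 3:7) {
    for (s in oracleAllStructures(n, 0L)) {
      db <- writeDotBracket(s)
      expect_identical(writeDotBracket(parseDotBracket(db)), db)
      t <- structureToTree(s)
      expect_equal(basePairs(treeToStructure(t)), basePairs(s))
      # DL collection is conflict-free and rebuilds the same tree
      rebuilt <- treeFromDLs(descendantLeafsets(t), n)
      expect_equal(internalNodes(rebuilt), internalNodes(t))
      # IL collection is a structural partition rebuilding the same tree
      ils <- internalLeafsets(t)
      expect_identical(sort(unlist(ils)), 0:(n + 1L))
      rebuilt2 <- treeFromStructuralPartition(ils, n)
      expect_equal(internalNodes(rebuilt2), internalNodes(t))
      # each node's IL extremes are its pair endpoints
      nd <- internalNodes(t)
      for (v in seq_along(ils))
        expect_equal(range(ils[[v]]), nd[v, ])
    }
  }
})

test_that("round trips hold for long random structures", {
  set.seed(11)
  for (rep in 1:25) {
    s <- sampleStructure(100, 3)
    db <- writeDotBracket(s)
    expect_identical(writeDotBracket(parseDotBracket(db)), db)
    t <- structureToTree(s)
    expect_equal(internalNodes(treeFromDLs(descendantLeafsets(t), 100)),
                 internalNodes(t))
    expect_equal(internalNodes(treeFromStructuralPartition(internalLeafsets(t), 100)),
                 internalNodes(t))
  }
})

test_that("internal leafsets agree with the direct containment oracle", {
  set.seed(12)
  for (rep in 1:20) {
    s <- oracleRandomStructure(8, 0L)
    got <- sort(vapply(internalLeafsets(s), function(m)
      paste(m, collapse = ","), character(1)), method = "radix")
    expect_identical(got, oracleIlKeys(s))
  }
})

test_that("crossing pairs are rejected by validity", {
  expect_error(RNAStructure(8, rbind(c(1, 5), c(3, 7))), "nested or disjoint")
  expect_error(RNAStructure(8, rbind(c(1, 5), c(5, 8))), "two pairs")
  expect_error(RNAStructure(7, rbind(c(1, 7), c(2, 6)), "GGAAACC"),
               NA)
  expect_error(RNAStructure(7, rbind(c(1, 7), c(2, 6)), "GAAAACC"),
               "Watson-Crick or Wobble")
})
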