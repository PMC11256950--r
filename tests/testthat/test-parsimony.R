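quartet <- function() ape::read.tree(text = "((A,B),(C,D));")

toyLeaves <- function() {
  list(A = parseDotBracket("((...))"), B = parseDotBracket("((...))"),
       C = parseDotBracket("(.....)"), D = parseDotBracket("(.....)"))
}

test_that("Fitch-Hartigan reconstruction solves the quartet toy instance", {
  fh <- fitchHartiganRF(quartet(), toyLeaves())
  anc <- lapply(ancestralTrees(fh), writeDotBracket)
  expect_equal(parsimonyCost(fh), 1)
  # node 5 is the root, 6 the (A,B) ancestor, 7 the (C,D) ancestor
  expect_equal(anc[["6"]], "((...))")
  expect_equal(anc[["7"]], "(.....)")
  # root tie on the inner pair resolves to absence
  expect_equal(anc[["5"]], "(.....)")
})

test_that("root ties resolve to absence on a cherry", {
  phy <- ape::read.tree(text = "(A,B);")
  lt <- list(A = parseDotBracket("((...))"), B = parseDotBracket("(.....)"))
  fh <- fitchHartiganRF(phy, lt)
  expect_equal(writeDotBracket(ancestralTrees(fh)[["3"]]), "(.....)")
  expect_equal(parsimonyCost(fh), 1)
})

test_that("identical leaves reconstruct identically at zero cost", {
  lt <- lapply(setNames(rep("(.(.).)", 4), c("A", "B", "C", "D")), parseDotBracket)
  fh <- fitchHartiganRF(quartet(), lt)
  expect_equal(parsimonyCost(fh), 0)
  for (t in ancestralTrees(fh))
    expect_equal(writeDotBracket(t), "(.(.).)")
})

test_that("Fitch-Hartigan equals brute-force assignment enumeration", {
  set.seed(41)
  universe5 <- oracleAllStructures(5, 0L)
  for (rep in 1:8) {
    phy <- quartet()
    lt <- setNames(replicate(4, oracleRandomStructure(5, 0L), simplify = FALSE),
                   c("A", "B", "C", "D"))
    fh <- fitchHartiganRF(phy, lt)
    brute <- oracleSmallParsimony(phy, lt, universe5, oracleRfDistance)
    expect_equal(parsimonyCost(fh), brute)
  }
})

test_that("Fitch-Hartigan equals an exact Sankoff over the complete universe", {
  set.seed(42)
  for (rep in 1:6) {
    phy <- if (rep %% 2) quartet() else ape::read.tree(text = "((A,B,C),D);")
    lt <- setNames(replicate(4, oracleRandomStructure(7, 0L), simplify = FALSE),
                   c("A", "B", "C", "D"))
    fh <- fitchHartiganRF(phy, lt)
    expect_equal(parsimonyCost(fh), oracleExactSankoffAllTrees(phy, lt, "RF"))
    # every reconstructed leafset occurs in some input tree
    inKeys <- unique(unlist(lapply(lt, function(t)
      apply(internalNodes(structureToTree(t)), 1, paste, collapse = ","))))
    for (t in ancestralTrees(fh)) {
      ks <- apply(internalNodes(t), 1, paste, collapse = ",")
      expect_true(all(ks %in% inKeys))
    }
  }
})

test_that("restricted assignment equals exhaustive leaf-label enumeration", {
  set.seed(43)
  for (rep in 1:6) {
    phy <- if (rep %% 2) ape::read.tree(text = "(((A,B),C),(D,E));")
           else ape::read.tree(text = "((A,B),(C,(D,E)));")
    lt <- setNames(replicate(5, oracleRandomStructure(6, 0L), simplify = FALSE),
                   c("A", "B", "C", "D", "E"))
    db <- vapply(lt, writeDotBracket, character(1))
    cands <- lt[!duplicated(db)]
    for (metric in c("RF", "IL", "RE")) {
      fn <- switch(metric, RF = oracleRfDistance, IL = oracleIlDistance,
                   RE = function(a, b) reDistance(a, b)$distance)
      ra <- restrictedAssignment(phy, lt, metric)
      expect_equal(parsimonyCost(ra),
                   oracleSmallParsimony(phy, lt, cands, fn))
      # every assigned tree is one of the leaf trees
      for (t in ancestralTrees(ra))
        expect_true(writeDotBracket(t) %in% db)
    }
  }
})

test_that("restricted assignment on two distinct leaf trees costs one distance", {
  phy <- quartet()
  lt <- toyLeaves()
  ra <- restrictedAssignment(phy, lt, "RF")
  expect_equal(parsimonyCost(ra), 1)
  anc <- lapply(ancestralTrees(ra), writeDotBracket)
  expect_equal(anc[["6"]], "((...))")
  expect_equal(anc[["7"]], "(.....)")

  re <- restrictedAssignment(phy, lt, "RE")
  expect_equal(parsimonyCost(re),
               reDistance(lt$A, lt$C)$distance)
})

test_that("median local search never increases the cost and terminates", {
  set.seed(44)
  for (rep in 1:6) {
    phy <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
    lt <- setNames(replicate(6, oracleRandomStructure(7, 0L), simplify = FALSE),
                   c("A", "B", "C", "D", "E", "F"))
    init <- restrictedAssignment(phy, lt, "IL")
    ls <- medianLocalSearch(phy, lt, "IL", "ILC")
    expect_lte(parsimonyCost(ls), parsimonyCost(init))
    # recomputing the cost from the assignment agrees
    expect_equal(parsimonyCost(ls),
                 spCost(phy, lt, ls, "IL"))
  }
})

test_that("a locally optimal initialisation is a fixed point", {
  phy <- quartet()
  lt <- lapply(setNames(rep("((...))", 4), c("A", "B", "C", "D")), parseDotBracket)
  ls <- medianLocalSearch(phy, lt, "IL", "ILC")
  expect_equal(parsimonyCost(ls), 0)
  for (t in ancestralTrees(ls)) expect_equal(writeDotBracket(t), "((...))")
})

test_that("exact Robinson-Foulds solver never exceeds the restricted baseline", {
  set.seed(45)
  for (rep in 1:8) {
    phy <- quartet()
    lt <- setNames(replicate(4, oracleRandomStructure(7, 0L), simplify = FALSE),
                   c("A", "B", "C", "D"))
    expect_lte(parsimonyCost(fitchHartiganRF(phy, lt)),
               parsimonyCost(restrictedAssignment(phy, lt, "RF")))
  }
})

test_that("sp cost sums the chosen distance over phylogeny edges", {
  phy <- ape::read.tree(text = "(A,B);")
  lt <- list(A = parseDotBracket("((...))"), B = parseDotBracket("(.....)"))
  asg <- list(`3` = parseDotBracket("(.....)"))
  expect_equal(spCost(phy, lt, asg, "RF"), 1)
  expect_equal(spCost(phy, lt, asg, "IL"), 3)
  expect_error(spCost(phy, lt, list(), "RF"), "no tree assigned")
})

test_that("multifurcating phylogenies are handled throughout", {
  phy <- ape::read.tree(text = "(A,B,C,D);")
  lt <- toyLeaves()
  fh <- fitchHartiganRF(phy, lt)
  expect_equal(length(ancestralTrees(fh)), 1L)
  expect_equal(parsimonyCost(fh),
               oracleSmallParsimony(phy, lt, oracleAllStructures(7, 0L),
                                    oracleRfDistance))
})

test_that("missing leaf structures are reported by name", {
  phy <- quartet()
  lt <- toyLeaves()[1:3]
  expect_error(fitchHartiganRF(phy, lt), "D")
})
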