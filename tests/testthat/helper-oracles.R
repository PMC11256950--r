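# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's dynamic programs: enumeration,
# closed recursions and exhaustive search only.

# all pair sets of structures of length n with every pair enclosing at least
# theta positions, by exhaustive recursive decomposition
oracleEnumeratePairSets <- function(n, theta = 0L) {
  rec <- function(lo, hi) {
    if (hi < lo) return(list(matrix(integer(0), 0, 2)))
    out <- lapply(rec(lo + 1L, hi), identity)      # lo unpaired
    j <- lo + theta + 1L
    while (j <= hi) {
      inner <- rec(lo + 1L, j - 1L)
      rest <- rec(j + 1L, hi)
      for (a in inner) for (b in rest)
        out[[length(out) + 1L]] <- rbind(c(lo, j), a, b)
      j <- j + 1L
    }
    out
  }
  rec(1L, n)
}

# memoised per-session tree universes
.oracleUniverse <- local({
  cache <- list()
  function(n, theta = 0L) {
    key <- paste(n, theta)
    if (is.null(cache[[key]])) {
      ps <- oracleEnumeratePairSets(n, theta)
      cache[[key]] <<- lapply(ps, function(p) RNAStructure(n, p))
    }
    cache[[key]]
  }
})

oracleAllStructures <- function(n, theta = 0L) .oracleUniverse(n, theta)

# uniform random structure drawn by enumeration (independent of the
# package's stochastic-backtrack sampler)
oracleRandomStructure <- function(n, theta = 0L) {
  u <- oracleAllStructures(n, theta)
  u[[sample.int(length(u), 1L)]]
}

# postorder-sorted internal nodes of a tree: ordered by closing endpoint
.oraclePost <- function(tree) {
  nd <- internalNodes(tree)
  nd[order(nd[, 2L]), , drop = FALSE]
}

# brute-force tree edit distance: every order-preserving bijection between
# equal-size node subsets is the sorted pairing; check nesting preservation
oracleTreeEdit <- function(t1, t2, cost) {
  n1 <- .oraclePost(structureToTree(t1))
  n2 <- .oraclePost(structureToTree(t2))
  k1 <- nrow(n1); k2 <- nrow(n2)
  nests <- function(a, b) a[1L] < b[1L] && b[2L] < a[2L]
  best <- k1 + k2      # empty mapping
  bestMap <- matrix(integer(0), 0, 4)
  for (m1 in 0:(2^k1 - 1L)) {
    s1 <- which(bitwAnd(m1, bitwShiftL(1L, 0:(k1 - 1L))) > 0L)
    for (m2 in 0:(2^k2 - 1L)) {
      s2 <- which(bitwAnd(m2, bitwShiftL(1L, 0:(k2 - 1L))) > 0L)
      if (length(s1) != length(s2)) next
      ok <- TRUE
      if (length(s1) > 1L) {
        for (a in seq_len(length(s1) - 1L)) for (b in seq(a + 1L, length(s1))) {
          x1 <- n1[s1[a], ]; y1 <- n1[s1[b], ]
          x2 <- n2[s2[a], ]; y2 <- n2[s2[b], ]
          if (nests(x1, y1) != nests(x2, y2) || nests(y1, x1) != nests(y2, x2)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
      }
      v <- k1 + k2 - 2L * length(s1)
      if (length(s1)) for (a in seq_along(s1))
        v <- v + cost(n1[s1[a], ], n2[s2[a], ])
      if (v < best) {
        best <- v
        bestMap <- if (length(s1))
          cbind(n1[s1, , drop = FALSE], n2[s2, , drop = FALSE])
        else matrix(integer(0), 0, 4)
      }
    }
  }
  list(distance = best, mapping = bestMap)
}

# IL key sets computed without the package's stack sweep: position ownership
# by direct interval containment
oracleIlKeys <- function(struct) {
  tree <- structureToTree(struct)
  nd <- internalNodes(tree)
  n <- seqLength(tree)
  owner <- vapply(0:(n + 1L), function(pos) {
    if (any(nd[, 1L] == pos)) return(which(nd[, 1L] == pos))
    if (any(nd[, 2L] == pos)) return(which(nd[, 2L] == pos))
    inside <- which(nd[, 1L] < pos & pos < nd[, 2L])
    inside[which.max(nd[inside, 1L])]   # innermost enclosing node
  }, integer(1))
  sets <- split(0:(n + 1L), owner)
  unname(sort(vapply(sets, function(s) paste(sort(s), collapse = ","),
                     character(1)), method = "radix"))
}

oracleIlDistance <- function(a, b) {
  ka <- oracleIlKeys(a); kb <- oracleIlKeys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

oracleBpKeys <- function(struct) {
  p <- basePairs(struct)
  if (!nrow(p)) character(0) else paste(p[, 1L], p[, 2L], sep = ",")
}

oracleRfDistance <- function(a, b) {
  # base-pair symmetric difference; the fictive root cancels
  ka <- oracleBpKeys(a); kb <- oracleBpKeys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# exhaustive median over the full tree universe of length n (theta = 0)
oracleMedianOverAllTrees <- function(inputs, metric = c("RF", "IL")) {
  metric <- match.arg(metric)
  n <- seqLength(inputs[[1L]])
  universe <- oracleAllStructures(n, 0L)
  dist <- if (metric == "RF") oracleRfDistance else oracleIlDistance
  costs <- vapply(universe, function(cand)
    sum(vapply(inputs, function(t) dist(t, cand), numeric(1))), numeric(1))
  list(cost = min(costs), medians = universe[costs == min(costs)])
}

# all structural partitions of [0, n+1] restricted to the given blocks,
# with 0 and n+1 in one block (i.e. realisable as RNA trees)
oraclePartitions <- function(blocks, n) {
  keys <- vapply(blocks, function(b) paste(sort(b), collapse = ","), character(1))
  blocks <- blocks[!duplicated(keys)]
  res <- list()
  rec <- function(remaining, used) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- used
      return(invisible())
    }
    x <- remaining[1L]
    for (b in blocks) {
      if (min(b) != x) next
      if (!all(b %in% remaining)) next
      if (length(used) &&
          any(vapply(used, function(u) ilConflict(u, b), logical(1)))) next
      rec(setdiff(remaining, b), c(used, list(b)))
    }
    invisible()
  }
  rec(0:(n + 1L), list())
  Filter(function(p) {
    rb <- p[[which(vapply(p, function(b) 0L %in% b, logical(1)))]]
    (n + 1L) %in% rb
  }, res)
}

# exhaustive constrained median: best realisable structural partition drawn
# from the input internal leafsets, scored by true summed distance
oracleIlcMedian <- function(inputs, metric = c("IL", "RF")) {
  metric <- match.arg(metric)
  n <- seqLength(inputs[[1L]])
  ils <- unlist(lapply(inputs, function(t)
    internalLeafsets(structureToTree(t))), recursive = FALSE)
  parts <- oraclePartitions(ils, n)
  dist <- if (metric == "IL") oracleIlDistance else oracleRfDistance
  best <- Inf
  for (p in parts) {
    cand <- treeFromStructuralPartition(p, n)
    v <- sum(vapply(inputs, function(t) dist(t, cand), numeric(1)))
    if (v < best) best <- v
  }
  best
}

# exhaustive small parsimony over a candidate set: every assignment of a
# candidate to every internal node is scored through a precomputed distance
# table (brute force, no dynamic programming)
oracleSmallParsimony <- function(phy, leafTrees, candidates, dist) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  nc <- length(candidates)
  all <- c(leafTrees[phy$tip.label], candidates)
  na <- length(all)
  D <- matrix(0, na, na)
  for (a in seq_len(na - 1L)) for (b in seq(a + 1L, na))
    D[a, b] <- D[b, a] <- dist(all[[a]], all[[b]])
  nodeIdx <- function(v, assign) if (v <= nt) v else nt + assign[v - nt]
  grid <- as.matrix(expand.grid(rep(list(seq_len(nc)), nn)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    v <- 0
    for (e in seq_len(nrow(phy$edge))) {
      v <- v + D[nodeIdx(phy$edge[e, 1L], assign), nodeIdx(phy$edge[e, 2L], assign)]
      if (v >= best) break
    }
    if (v < best) best <- v
  }
  best
}

# pairwise distance matrix over the full universe, cached per (n, metric)
.oracleUniverseD <- local({
  cache <- list()
  function(n, metric) {
    key <- paste(n, metric)
    if (is.null(cache[[key]])) {
      universe <- oracleAllStructures(n, 0L)
      keysFor <- if (metric == "RF") oracleBpKeys else oracleIlKeys
      uk <- lapply(universe, keysFor)
      nc <- length(universe)
      D <- matrix(0, nc, nc)
      for (a in seq_len(nc - 1L)) for (b in seq(a + 1L, nc)) {
        D[a, b] <- D[b, a] <-
          length(setdiff(uk[[a]], uk[[b]])) + length(setdiff(uk[[b]], uk[[a]]))
      }
      cache[[key]] <<- list(D = D, keys = uk)
    }
    cache[[key]]
  }
})

# exact unconstrained small parsimony by Sankoff over the COMPLETE structure
# universe of length n (theta = 0): exact because the universe is complete;
# written independently of the package's solvers
oracleExactSankoffAllTrees <- function(phy, leafTrees, metric = "RF") {
  n <- seqLength(leafTrees[[1L]])
  ud <- .oracleUniverseD(n, metric)
  D <- ud$D
  nc <- nrow(D)
  keysFor <- if (metric == "RF") oracleBpKeys else oracleIlKeys
  keyOf <- function(t) paste(keysFor(t), collapse = ";")
  ukeys <- vapply(oracleAllStructures(n, 0L), keyOf, character(1))
  nt <- length(phy$tip.label)
  children <- vector("list", nt + phy$Nnode)
  for (e in seq_len(nrow(phy$edge)))
    children[[phy$edge[e, 1L]]] <- c(children[[phy$edge[e, 1L]]], phy$edge[e, 2L])
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])
  tipIdx <- vapply(phy$tip.label, function(l)
    match(keyOf(leafTrees[[l]]), ukeys), integer(1))
  costFor <- function(v) {      # cost vector over candidates, internal v
    acc <- numeric(nc)
    for (ch in children[[v]]) {
      if (ch <= nt) {
        acc <- acc + D[, tipIdx[ch]]
      } else {
        cc <- costFor(ch)
        acc <- acc + apply(D + matrix(cc, nc, nc, byrow = TRUE), 1L, min)
      }
    }
    acc
  }
  min(costFor(root))
}
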