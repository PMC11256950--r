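#' @include trees.R distances.R
NULL

# coerce + check a list of inputs to trees on one leafset
.treeList <- function(trees) {
  if (is(trees, "RNATree") || is(trees, "RNAStructure")) trees <- list(trees)
  trees <- lapply(trees, .asTree)
  if (!length(trees)) stop("at least one input tree is required")
  ns <- vapply(trees, seqLength, integer(1))
  if (length(unique(ns)) > 1L)
    stop("input trees are not on a common leafset")
  trees
}

#' Sum of distances from a candidate to a set of trees
#'
#' The objective of the median problem: \eqn{\sum_i D(T_i, M)} for the chosen
#' distance.
#'
#' @param candidate An [RNATree-class] or [RNAStructure-class].
#' @param trees List of trees/structures on the same leafset.
#' @param metric One of \code{"RF"}, \code{"IL"}, \code{"RE"}.
#' @return Numeric scalar.
#' @export
medianCost <- function(candidate, trees, metric = c("RF", "IL", "RE")) {
  metric <- match.arg(toupper(metric[1L]), c("RF", "IL", "RE"))
  fn <- .metricFun(metric)
  candidate <- .asTree(candidate)
  trees <- .treeList(trees)
  sum(vapply(trees, function(t) fn(t, candidate), numeric(1)))
}

#' Majority-rule consensus median under the Robinson-Foulds distance
#'
#' The tree whose descendant leafsets are exactly those displayed by strictly
#' more than half of the input trees (the full interval \eqn{[0, n+1]} is
#' displayed by all of them).  This tree is an optimal unconstrained median
#' for the Robinson-Foulds distance, and all of its descendant leafsets come
#' from the input, so it also satisfies the descendant-leafset constraint.
#' Descendant leafsets displayed by exactly half of the trees (even \eqn{p})
#' are excluded.
#'
#' @param trees List of [RNATree-class] or [RNAStructure-class] objects on a
#'   common leafset.
#' @return List with elements \code{median} (an [RNATree-class]) and
#'   \code{cost} (the attained sum of Robinson-Foulds distances).
#' @examples
#' trees <- lapply(c("((...))", "((...))", "(.....)"), parseDotBracket)
#' rfMedian(trees)
#' @export
rfMedian <- function(trees) {
  trees <- .treeList(trees)
  p <- length(trees)
  n <- trees[[1L]]@n
  keys <- unlist(lapply(trees, function(t) .pairKeys(t@nodes)))
  tab <- table(keys)
  maj <- names(tab)[tab > p / 2]
  dls <- do.call(rbind, lapply(strsplit(maj, ","), as.integer))
  med <- treeFromDLs(dls, n)
  list(median = med, cost = medianCost(med, trees, "RF"))
}

#' Cost of an internal leafset with respect to input trees
#'
#' The rewritten per-leafset median cost
#' \eqn{\#\{k : I \notin IL(T_k)\} - \#\{k : I \in IL(T_k)\}}: a leafset
#' absent from all \eqn{p} trees costs \eqn{p}; one present in all of them
#' costs \eqn{-p}.  Summed over the blocks of a candidate's internal-leafset
#' partition this equals its median cost up to the constant
#' \eqn{\sum_k |IL(T_k)|}.
#'
#' @param members Integer vector, the leafset.
#' @param trees List of trees/structures.
#' @return Integer scalar (possibly negative).
#' @export
ilCost <- function(members, trees) {
  trees <- .treeList(trees)
  key <- .ilKey(sort(as.integer(members)))
  occ <- sum(vapply(trees, function(t)
    key %in% vapply(internalLeafsets(t), .ilKey, character(1)), logical(1)))
  length(trees) - 2L * occ
}

# index the distinct ILs occurring in the input trees
.ilIndex <- function(trees) {
  p <- length(trees)
  allKeys <- character(0); allMembers <- list()
  counts <- integer(0)
  for (t in trees) {
    ils <- internalLeafsets(t)
    ks <- vapply(ils, .ilKey, character(1))
    new <- !(ks %in% allKeys)
    allKeys <- c(allKeys, ks[new])
    allMembers <- c(allMembers, ils[new])
    counts <- c(counts, integer(sum(new)))
    counts[match(ks, allKeys)] <- counts[match(ks, allKeys)] + 1L
  }
  list(keys = allKeys, members = allMembers, occ = counts, p = p)
}

# canonical order of candidate ILs: by min element, then lexicographic
.canonicalOrder <- function(members) {
  pad <- vapply(members, function(m)
    paste(formatC(m, width = 6, flag = "0"), collapse = ","), character(1))
  order(pad)
}

# shared dynamic program over structural partitions restricted to input ILs.
# blockCost(members) gives the cost of using one block; returns the optimal
# partition of [0, n+1] and its total block cost.
.ilcPartitionDP <- function(trees, blockCost) {
  n <- trees[[1L]]@n
  idx <- .ilIndex(trees)
  ord <- .canonicalOrder(idx$members)
  members <- idx$members[ord]
  ncand <- length(members)
  cmin <- vapply(members, min, integer(1))
  cmax <- vapply(members, max, integer(1))
  cgaps <- lapply(members, ilGaps)
  ccost <- vapply(members, blockCost, numeric(1))
  byMin <- split(seq_len(ncand), cmin)

  N <- n + 2L
  cval <- matrix(Inf, N, N)        # cval[i+1, j+1], i <= j; j < i handled as 0
  choice <- matrix(0L, N, N)
  cg <- function(i, j) if (j < i) 0 else cval[i + 1L, j + 1L]

  for (w in seq_len(n + 1L)) {
    for (i in 0:(n + 1L - w)) {
      j <- i + w
      cands <- byMin[[as.character(i)]]
      if (is.null(cands)) next
      best <- Inf; bestc <- 0L
      for (ci in cands) {
        if (cmax[ci] > j) next
        v <- ccost[ci] + cg(cmax[ci] + 1L, j)
        g <- cgaps[[ci]]
        if (nrow(g)) for (r in seq_len(nrow(g))) v <- v + cg(g[r, 1L], g[r, 2L])
        if (v < best) { best <- v; bestc <- ci }
      }
      cval[i + 1L, j + 1L] <- best
      choice[i + 1L, j + 1L] <- bestc
    }
  }
  total <- cval[1L, n + 2L]
  if (!is.finite(total))
    stop("no structural partition of [0, n+1] restricted to the input leafsets")

  blocks <- list()
  collect <- function(i, j) {
    if (j < i) return(invisible())
    ci <- choice[i + 1L, j + 1L]
    if (ci == 0L) stop("internal error: infeasible interval in backtrace")
    blocks[[length(blocks) + 1L]] <<- members[[ci]]
    g <- cgaps[[ci]]
    if (nrow(g)) for (r in seq_len(nrow(g))) collect(g[r, 1L], g[r, 2L])
    if (cmax[ci] < j) collect(cmax[ci] + 1L, j)
    invisible()
  }
  collect(0L, n + 1L)
  list(blocks = blocks, value = total, n = n)
}

#' Internal-Leafset median constrained to input leafsets
#'
#' Exact dynamic program for the median under the Internal-Leafset distance
#' when every leafset of the output must occur in at least one input tree.
#' The table entry for interval \eqn{[i, j]} is the minimum total block cost
#' of a structural partition of \eqn{[i, j]} drawn from the input leafsets;
#' intervals are filled in increasing width, decomposing on the block that
#' contains \eqn{i} (its gaps and the remainder after its maximum are
#' optimised independently).  Ties are broken towards the canonically
#' smallest block (by minimum element, then lexicographically), making the
#' output deterministic.
#'
#' @param trees List of [RNATree-class] or [RNAStructure-class] objects on a
#'   common leafset.
#' @return List with elements \code{median} (an [RNATree-class]),
#'   \code{cost} (the attained sum of Internal-Leafset distances) and
#'   \code{partitionCost} (the total block cost of the optimal partition;
#'   \code{cost} equals it plus \eqn{\sum_k |IL(T_k)|}).
#' @examples
#' trees <- lapply(c("((...))", "((...))", "(.....)"), parseDotBracket)
#' ilIlcMedian(trees)
#' @export
ilIlcMedian <- function(trees) {
  trees <- .treeList(trees)
  dp <- .ilcPartitionDP(trees, function(m) ilCost(m, trees))
  med <- treeFromStructuralPartition(dp$blocks, dp$n)
  list(median = med, cost = medianCost(med, trees, "IL"),
       partitionCost = dp$value)
}

#' Robinson-Foulds median constrained to input leafsets
#'
#' Same dynamic program as [ilIlcMedian()] with the block cost replaced by
#' the base-pair analogue
#' \eqn{\#\{k : (\min I, \max I) \notin I(T_k)\} - \#\{k : \in\}}: a block's
#' extremes form the base pair it contributes, so minimising the summed block
#' costs minimises the total Robinson-Foulds distance over trees whose
#' leafsets all come from the input.
#'
#' @inheritParams ilIlcMedian
#' @return List with \code{median}, \code{cost} (sum of Robinson-Foulds
#'   distances) and \code{partitionCost}.
#' @export
rfIlcMedian <- function(trees) {
  trees <- .treeList(trees)
  p <- length(trees)
  nodeKeys <- lapply(trees, function(t) .pairKeys(t@nodes))
  bpCost <- function(m) {
    key <- paste(min(m), max(m), sep = ",")
    occ <- sum(vapply(nodeKeys, function(ks) key %in% ks, logical(1)))
    p - 2L * occ
  }
  dp <- .ilcPartitionDP(trees, bpCost)
  med <- treeFromStructuralPartition(dp$blocks, dp$n)
  list(median = med, cost = medianCost(med, trees, "RF"),
       partitionCost = dp$value)
}

#' Maximum-weight independent set of intervals
#'
#' Given weighted closed intervals, finds a set of pairwise disjoint
#' intervals of maximum total weight (the empty set is allowed, so the value
#' is never negative; non-positive-weight intervals are never forced in).
#' Solved by the classical right-endpoint-sorted dynamic program.
#'
#' @param intervals Three-column matrix (or data.frame) with columns
#'   \code{lo}, \code{hi}, \code{weight}; zero rows allowed.
#' @return List with \code{value} (numeric) and \code{chosen} (integer vector
#'   of selected row indices of \code{intervals}, possibly empty).
#' @examples
#' mwisIntervals(cbind(c(1, 2, 4), c(3, 5, 6), c(2, 3, 4)))
#' @export
mwisIntervals <- function(intervals) {
  intervals <- as.matrix(intervals)
  m <- nrow(intervals)
  if (!m) return(list(value = 0, chosen = integer(0)))
  ord <- order(intervals[, 2L], intervals[, 1L])
  lo <- intervals[ord, 1L]; hi <- intervals[ord, 2L]; w <- intervals[ord, 3L]
  best <- numeric(m + 1L)     # best[t+1]: best value using first t intervals
  take <- logical(m)
  prev <- integer(m)
  for (t in seq_len(m)) {
    # last interval (in sorted order, before t) ending strictly before lo[t]
    cand <- which(hi[seq_len(t - 1L)] < lo[t])
    pt <- if (length(cand)) max(cand) else 0L
    prev[t] <- pt
    with_t <- w[t] + best[pt + 1L]
    if (with_t > best[t]) {
      best[t + 1L] <- with_t; take[t] <- TRUE
    } else {
      best[t + 1L] <- best[t]
    }
  }
  chosen <- integer(0)
  t <- m
  while (t > 0L) {
    if (take[t]) { chosen <- c(ord[t], chosen); t <- prev[t] } else t <- t - 1L
  }
  list(value = max(0, best[m + 1L]), chosen = chosen)
}

#' Unconstrained Internal-Leafset median
#'
#' Dynamic program for the median under the Internal-Leafset distance with no
#' constraint on the output.  For interval \eqn{[i, j]} the block containing
#' \eqn{i} either occurs in the input (handled as in [ilIlcMedian()]) or is a
#' new leafset of cost \eqn{p}; in the latter case only the smallest other
#' member \eqn{k} of the block is enumerated, the stretch between \eqn{i} and
#' \eqn{k} is optimised recursively, and the optimal set of gaps to the right
#' of \eqn{k} is found as a maximum-weight independent set of sub-intervals
#' of \eqn{[k+1, j-1]} weighted by minus their optimal partition cost.
#' Boundary conditions: single positions are infeasible (blocks have size at
#' least 2) and empty intervals cost 0.
#'
#' @inheritParams ilIlcMedian
#' @return List with \code{median}, \code{cost} (sum of Internal-Leafset
#'   distances) and \code{partitionCost}.
#' @export
ilNcMedian <- function(trees) {
  trees <- .treeList(trees)
  p <- length(trees)
  n <- trees[[1L]]@n
  idx <- .ilIndex(trees)
  ord <- .canonicalOrder(idx$members)
  members <- idx$members[ord]
  occ <- idx$occ[ord]
  cmin <- vapply(members, min, integer(1))
  cmax <- vapply(members, max, integer(1))
  cgaps <- lapply(members, ilGaps)
  ccost <- p - 2 * occ
  byMin <- split(seq_along(members), cmin)

  N <- n + 2L
  chat <- matrix(Inf, N, N)
  ch1cand <- matrix(0L, N, N)   # chosen input IL for case 1
  ch2k <- matrix(0L, N, N)      # chosen k for case 2 (0 = case 1 used)
  cg <- function(i, j) if (j < i) 0 else chat[i + 1L, j + 1L]

  # independent-set values over gap candidates within [lo, hi]:
  # A[s] (s in lo..hi+2) = best total of -chat over disjoint [u, v],
  # s <= u < v <= hi
  gapAlpha <- function(lo, hi) {
    len <- hi - lo + 3L
    A <- numeric(len)           # A[s - lo + 1], zero beyond hi - 1
    if (hi - lo < 1L) return(A)
    for (s in seq(hi - 1L, lo)) {
      bestv <- A[s - lo + 2L]
      for (v in seq(s + 1L, hi)) {
        cuv <- chat[s + 1L, v + 1L]
        if (is.finite(cuv) && cuv < 0) {
          cand <- -cuv + A[v + 2L - lo]
          if (cand > bestv) bestv <- cand
        }
      }
      A[s - lo + 1L] <- bestv
    }
    A
  }

  for (w in seq_len(n + 1L)) {
    for (i in 0:(n + 1L - w)) {
      j <- i + w
      # case 1: block containing i occurs in the input
      c1 <- Inf; c1cand <- 0L
      cands <- byMin[[as.character(i)]]
      if (!is.null(cands)) for (ci in cands) {
        if (cmax[ci] > j) next
        v <- ccost[ci] + cg(cmax[ci] + 1L, j)
        g <- cgaps[[ci]]
        if (nrow(g)) for (r in seq_len(nrow(g))) v <- v + cg(g[r, 1L], g[r, 2L])
        if (v < c1) { c1 <- v; c1cand <- ci }
      }
      # case 2: new block {i, k, ...} of cost p
      A <- gapAlpha(i + 2L, j - 1L)           # A[s - (i+2) + 1]
      alpha <- function(s) if (s > j - 1L) 0 else A[s - i - 1L]
      c2 <- Inf; c2k <- 0L
      for (k in seq(i + 1L, j)) {
        v <- p + cg(i + 1L, k - 1L) - alpha(k + 1L)
        if (v < c2) { c2 <- v; c2k <- k }
      }
      if (c1 <= c2) {
        chat[i + 1L, j + 1L] <- c1
        ch1cand[i + 1L, j + 1L] <- c1cand
      } else {
        chat[i + 1L, j + 1L] <- c2
        ch2k[i + 1L, j + 1L] <- c2k
      }
    }
  }
  total <- chat[1L, n + 2L]
  if (!is.finite(total)) stop("internal error: infeasible unconstrained median")

  blocks <- list()
  collect <- function(i, j) {
    if (j < i) return(invisible())
    ci <- ch1cand[i + 1L, j + 1L]
    if (ci > 0L) {
      blocks[[length(blocks) + 1L]] <<- members[[ci]]
      g <- cgaps[[ci]]
      if (nrow(g)) for (r in seq_len(nrow(g))) collect(g[r, 1L], g[r, 2L])
      if (cmax[ci] < j) collect(cmax[ci] + 1L, j)
      return(invisible())
    }
    k <- ch2k[i + 1L, j + 1L]
    if (k == 0L) stop("internal error: no recorded choice in backtrace")
    A <- gapAlpha(i + 2L, j - 1L)
    alpha <- function(s) if (s > j - 1L) 0 else A[s - i - 1L]
    # recover the chosen disjoint gap intervals within [k+1, j-1]
    gaps <- list()
    s <- k + 1L
    while (s <= j - 2L) {
      if (alpha(s) == alpha(s + 1L)) { s <- s + 1L; next }
      found <- FALSE
      for (v in seq(s + 1L, j - 1L)) {
        cuv <- chat[s + 1L, v + 1L]
        if (is.finite(cuv) && cuv < 0 && -cuv + alpha(v + 1L) == alpha(s)) {
          gaps[[length(gaps) + 1L]] <- c(s, v)
          s <- v + 1L
          found <- TRUE
          break
        }
      }
      if (!found) s <- s + 1L
    }
    covered <- unlist(lapply(gaps, function(g) seq(g[1L], g[2L])))
    rest <- if (k < j) setdiff((k + 1L):j, covered) else integer(0)
    block <- sort(c(i, k, rest))
    blocks[[length(blocks) + 1L]] <<- as.integer(block)
    collect(i + 1L, k - 1L)
    for (g in gaps) collect(g[1L], g[2L])
    invisible()
  }
  collect(0L, n + 1L)
  med <- treeFromStructuralPartition(blocks, n)
  list(median = med, cost = medianCost(med, trees, "IL"),
       partitionCost = total)
}
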