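#' @include trees.R
NULL

#' Base-pair distance between two structures
#'
#' The size of the symmetric difference of the two base-pair sets: the
#' minimum number of base-pair breaking/creation events turning one structure
#' into the other (both structures must come from a common gap-free
#' alignment, i.e. share one length).
#'
#' @param x,y [RNAStructure-class] or [RNATree-class] objects of equal
#'   length.
#' @return Non-negative integer.
#' @examples
#' bpDistance(parseDotBracket("((...))"), parseDotBracket("(.....)"))
#' @export
bpDistance <- function(x, y) {
  x <- treeToStructure(.asTree(x)); y <- treeToStructure(.asTree(y))
  if (x@n != y@n) stop("structures have different lengths (", x@n, " vs ", y@n, ")")
  a <- .pairKeys(x@pairs); b <- .pairKeys(y@pairs)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Robinson-Foulds distance between two RNA trees
#'
#' The size of the symmetric difference of the two collections of descendant
#' leafsets.  On RNA trees this equals the base-pair distance of the
#' underlying structures, since the fictive root interval is shared and every
#' other descendant leafset is a base pair.
#'
#' @param x,y [RNATree-class] (or [RNAStructure-class]) objects on a common
#'   leafset.
#' @return Non-negative integer.
#' @export
rfDistance <- function(x, y) {
  x <- .asTree(x); y <- .asTree(y)
  if (x@n != y@n) stop("trees are not on a common leafset")
  a <- .pairKeys(x@nodes); b <- .pairKeys(y@nodes)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Internal-Leafset distance between two RNA trees
#'
#' The size of the symmetric difference of the two collections of internal
#' leafsets (sets of leaf-children of internal nodes).  Whereas the
#' Robinson-Foulds distance counts base-pair differences, this distance
#' counts differences in loops.
#'
#' @param x,y [RNATree-class] (or [RNAStructure-class]) objects on a common
#'   leafset.
#' @return Non-negative integer.
#' @examples
#' ilDistance(parseDotBracket("((...))"), parseDotBracket("(.....)"))
#' @export
ilDistance <- function(x, y) {
  x <- .asTree(x); y <- .asTree(y)
  if (x@n != y@n) stop("trees are not on a common leafset")
  a <- vapply(internalLeafsets(x), .ilKey, character(1))
  b <- vapply(internalLeafsets(y), .ilKey, character(1))
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Rename-cost functions for the tree edit distance
#'
#' \code{prohibitiveCost(n)} returns a cost under which two internal nodes
#' can only be mapped when they are the identical pair: unequal pairs cost
#' \eqn{2(n+2)+1}, strictly more than deleting and re-inserting every node,
#' so such a mapping is never chosen.  Under this cost the tree edit distance
#' equals the base-pair distance.  \code{relaxedCost} is the relaxed rename
#' cost \eqn{|i_1-i_2| + |j_1-j_2|}, allowing imperfectly aligned pairs to be
#' mapped.
#'
#' @param n Sequence length (for the prohibitive bound).
#' @return A function of two length-2 integer vectors returning a
#'   non-negative cost.
#' @export
prohibitiveCost <- function(n) {
  big <- 2 * (n + 2) + 1
  function(p1, p2) if (p1[1L] == p2[1L] && p1[2L] == p2[2L]) 0 else big
}

#' @rdname prohibitiveCost
#' @export
relaxedCost <- function(p1, p2) {
  abs(p1[1L] - p2[1L]) + abs(p1[2L] - p2[2L])
}

# internal-node tree topology: preorder nodes matrix -> children lists
.tedTopology <- function(tree) {
  nd <- tree@nodes
  k <- nrow(nd)
  parent <- integer(k)
  children <- vector("list", k)
  stack <- integer(k); top <- 0L
  for (v in seq_len(k)) {
    while (top > 0L) {
      u <- stack[top]
      if (nd[u, 1L] <= nd[v, 1L] && nd[v, 2L] <= nd[u, 2L]) break
      top <- top - 1L
    }
    if (top > 0L) {
      parent[v] <- stack[top]
      children[[stack[top]]] <- c(children[[stack[top]]], v)
    }
    top <- top + 1L; stack[top] <- v
  }
  size <- rep(1L, k)
  for (v in rev(seq_len(k))) if (parent[v] > 0L)
    size[parent[v]] <- size[parent[v]] + size[v]
  root <- which(parent == 0L)
  list(nodes = nd, children = children, size = size, root = root)
}

#' Tree edit distance between two RNA trees
#'
#' Minimum cost over all valid mappings (order- and nesting-preserving
#' partial bijections between internal-node sets).  A mapping costs the sum
#' of the rename costs of its couples plus 1 for every unmapped internal node
#' of either tree.  Computed by an ordered-forest edit dynamic program with a
#' backtrace yielding one optimal mapping (match preferred over deletion over
#' insertion on ties, applied bottom-up from the rightmost subtrees).
#'
#' @param x,y [RNATree-class] (or [RNAStructure-class]) objects on a common
#'   leafset.
#' @param cost Rename cost: a function of two pairs (length-2 integer
#'   vectors) that is zero exactly on equal pairs.  See [prohibitiveCost()]
#'   and [relaxedCost()].
#' @return List with elements \code{distance} (numeric) and \code{mapping}
#'   (a [TreeMapping-class]).
#' @examples
#' t1 <- parseDotBracket("((...))"); t2 <- parseDotBracket(".((..))")
#' treeEditDistance(t1, t2, relaxedCost)$distance
#' @export
treeEditDistance <- function(x, y, cost) {
  x <- .asTree(x); y <- .asTree(y)
  if (x@n != y@n) stop("trees are not on a common leafset")
  a <- .tedTopology(x); b <- .tedTopology(y)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  fsize <- function(topo, f) if (length(f)) sum(topo$size[f]) else 0L

  solve <- function(f1, f2) {
    if (!length(f1) && !length(f2)) return(list(v = 0, ch = 0L))
    key <- paste(paste(f1, collapse = "."), paste(f2, collapse = "."), sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (!length(f1)) {
      res <- list(v = fsize(b, f2), ch = 3L)
    } else if (!length(f2)) {
      res <- list(v = fsize(a, f1), ch = 2L)
    } else {
      r1 <- f1[length(f1)]; p1 <- f1[-length(f1)]; s1 <- a$children[[r1]]
      r2 <- f2[length(f2)]; p2 <- f2[-length(f2)]; s2 <- b$children[[r2]]
      vmatch <- solve(p1, p2)$v + solve(s1, s2)$v +
        cost(a$nodes[r1, ], b$nodes[r2, ])
      vdel <- solve(c(p1, s1), f2)$v + 1
      vins <- solve(f1, c(p2, s2))$v + 1
      v <- min(vmatch, vdel, vins)
      ch <- if (vmatch <= vdel && vmatch <= vins) 1L else if (vdel <= vins) 2L else 3L
      res <- list(v = v, ch = ch)
    }
    memo[[key]] <- res
    res
  }

  collect <- function(f1, f2) {
    if (!length(f1) && !length(f2)) return(NULL)
    ch <- solve(f1, f2)$ch
    if (!length(f1) || !length(f2)) return(NULL)
    r1 <- f1[length(f1)]; p1 <- f1[-length(f1)]; s1 <- a$children[[r1]]
    r2 <- f2[length(f2)]; p2 <- f2[-length(f2)]; s2 <- b$children[[r2]]
    if (ch == 1L) {
      rbind(collect(p1, p2), collect(s1, s2),
            c(a$nodes[r1, ], b$nodes[r2, ]))
    } else if (ch == 2L) {
      collect(c(p1, s1), f2)
    } else {
      collect(f1, c(p2, s2))
    }
  }

  val <- solve(a$root, b$root)$v
  mp <- collect(a$root, b$root)
  if (is.null(mp)) mp <- matrix(integer(0), 0, 4)
  storage.mode(mp) <- "integer"
  dimnames(mp) <- NULL
  list(distance = val, mapping = new("TreeMapping", pairs = mp, cost = val))
}

#' Relaxed edit distance between two RNA trees
#'
#' The tree edit distance under the relaxed rename cost
#' \eqn{|i_1-i_2| + |j_1-j_2|}: base pairs that are not perfectly aligned may
#' still be mapped, at a cost equal to their endpoint displacement.
#'
#' @inheritParams treeEditDistance
#' @return List with elements \code{distance} and \code{mapping}.
#' @examples
#' reDistance(parseDotBracket("((...))"), parseDotBracket(".((..))"))$distance
#' @export
reDistance <- function(x, y) {
  treeEditDistance(x, y, relaxedCost)
}

# metric name -> numeric distance function on trees
.metricFun <- function(metric) {
  metric <- toupper(metric)
  switch(metric,
         RF = rfDistance,
         IL = ilDistance,
         RE = function(x, y) reDistance(x, y)$distance,
         BP = bpDistance,
         stop("unknown metric '", metric, "' (use RF, IL or RE)"))
}

#' Pairwise distance matrix between structures
#'
#' @param structures Named list of [RNAStructure-class] or [RNATree-class]
#'   objects of one common length.
#' @param metric One of \code{"RF"}, \code{"IL"}, \code{"RE"}.
#' @return Symmetric numeric matrix with dimnames from \code{structures}.
#' @export
distanceMatrix <- function(structures, metric = c("RF", "IL", "RE")) {
  metric <- match.arg(toupper(metric[1L]), c("RF", "IL", "RE"))
  fn <- .metricFun(metric)
  trees <- lapply(structures, .asTree)
  p <- length(trees)
  d <- matrix(0, p, p, dimnames = list(names(structures), names(structures)))
  if (p > 1L) for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    d[i, j] <- d[j, i] <- fn(trees[[i]], trees[[j]])
  }
  d
}
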