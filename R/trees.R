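#' @include AllClasses.R dotbracket.R
NULL

#' Convert a structure to its RNA tree
#'
#' The ordered rooted tree whose internal nodes are the base pairs plus the
#' fictive root \eqn{(0, n+1)} and whose leaves are the positions
#' \eqn{[0, n+1]}; the descendant leaves of internal node \eqn{(i, j)} are
#' exactly the interval \eqn{[i, j]}.
#'
#' @param x An [RNAStructure-class].
#' @return An [RNATree-class] on leafset \eqn{[0, n+1]}.
#' @seealso [treeToStructure()], the inverse.
#' @examples
#' structureToTree(parseDotBracket("((...))"))
#' @export
setGeneric("structureToTree", function(x) standardGeneric("structureToTree"))

#' @rdname structureToTree
#' @export
setMethod("structureToTree", "RNAStructure", function(x) {
  RNATree(x@n, x@pairs)
})

#' @rdname structureToTree
#' @export
setMethod("structureToTree", "RNATree", function(x) x)

#' Convert an RNA tree back to a structure
#'
#' Strips the fictive root pair; the remaining internal nodes are the base
#' pairs.  No sequence is attached (any sequence whose paired positions are
#' canonical is compatible).
#'
#' @param x An [RNATree-class].
#' @return An [RNAStructure-class].
#' @export
setGeneric("treeToStructure", function(x) standardGeneric("treeToStructure"))

#' @rdname treeToStructure
#' @export
setMethod("treeToStructure", "RNATree", function(x) {
  RNAStructure(x@n, basePairs(x))
})

#' @rdname treeToStructure
#' @export
setMethod("treeToStructure", "RNAStructure", function(x) x)

# coerce structures to trees where a tree is expected
.asTree <- function(x) {
  if (is(x, "RNATree")) x else structureToTree(x)
}

# canonical string keys
.pairKeys <- function(mat) paste(mat[, 1L], mat[, 2L], sep = ",")
.ilKey <- function(members) paste(members, collapse = ",")

#' Descendant leafsets of an RNA tree
#'
#' The descendant leafset (DL) of internal node \eqn{(i, j)} is the interval
#' \eqn{[i, j]} of leaves below it -- the RNA-tree analogue of a clade.
#'
#' @param x An [RNATree-class] (or [RNAStructure-class], converted first).
#' @return Two-column integer matrix of intervals \code{(lo, hi)}, one row per
#'   internal node, in preorder.
#' @export
setGeneric("descendantLeafsets", function(x) standardGeneric("descendantLeafsets"))

#' @rdname descendantLeafsets
#' @export
setMethod("descendantLeafsets", "RNATree", function(x) x@nodes)

#' @rdname descendantLeafsets
#' @export
setMethod("descendantLeafsets", "RNAStructure",
          function(x) descendantLeafsets(structureToTree(x)))

#' Internal leafsets of an RNA tree
#'
#' The internal leafset (IL) of internal node \eqn{(i, j)} is the set of its
#' leaf-children: the paired endpoints \eqn{i, j} plus every unpaired position
#' lying directly in its loop.  ILs describe the loops of the structure.
#'
#' @param x An [RNATree-class] (or [RNAStructure-class], converted first).
#' @return List of sorted integer vectors, one per internal node, in preorder
#'   (the first element is the root's IL, which contains 0 and \eqn{n+1}).
#' @export
setGeneric("internalLeafsets", function(x) standardGeneric("internalLeafsets"))

#' @rdname internalLeafsets
#' @export
setMethod("internalLeafsets", "RNATree", function(x) {
  nd <- x@nodes
  n <- x@n
  k <- nrow(nd)
  owner <- integer(n + 2L)  # owner[pos + 1] = node index owning leaf pos
  opens <- integer(n + 2L); closes <- integer(n + 2L)
  root <- which(nd[, 1L] == 0L & nd[, 2L] == n + 1L)
  for (v in seq_len(k)) {
    if (v == root) next
    opens[nd[v, 1L] + 1L] <- v
    closes[nd[v, 2L] + 1L] <- v
  }
  stack <- integer(k); stack[1L] <- root; top <- 1L
  owner[1L] <- root; owner[n + 2L] <- root
  for (pos in seq_len(n)) {
    idx <- pos + 1L
    if (opens[idx] > 0L) {
      owner[idx] <- opens[idx]
      top <- top + 1L; stack[top] <- opens[idx]
    } else if (closes[idx] > 0L) {
      owner[idx] <- closes[idx]
      top <- top - 1L
    } else {
      owner[idx] <- stack[top]
    }
  }
  ils <- vector("list", k)
  members <- split(0:(n + 1L), owner)
  for (nm in names(members)) ils[[as.integer(nm)]] <- as.integer(members[[nm]])
  ils
})

#' @rdname internalLeafsets
#' @export
setMethod("internalLeafsets", "RNAStructure",
          function(x) internalLeafsets(structureToTree(x)))

#' Conflict between two descendant leafsets
#'
#' Two DLs (closed intervals) conflict when they overlap but neither contains
#' the other; conflicting DLs cannot both appear in one RNA tree.
#'
#' @param x,y Length-2 integer vectors \code{(lo, hi)}.
#' @return Logical scalar.
#' @examples
#' dlConflict(c(1, 5), c(3, 8))  # TRUE
#' dlConflict(c(1, 5), c(2, 4))  # FALSE, nested
#' @export
dlConflict <- function(x, y) {
  lo <- max(x[1L], y[1L]); hi <- min(x[2L], y[2L])
  if (lo > hi) return(FALSE)                              # disjoint
  !((x[1L] <= y[1L] && y[2L] <= x[2L]) || (y[1L] <= x[1L] && x[2L] <= y[2L]))
}

#' Conflict between two internal leafsets
#'
#' Two distinct ILs conflict when they intersect, or when members of one
#' interleave with members of the other (\eqn{i < k < j < l} with
#' \eqn{i, j} in one set and \eqn{k, l} in the other).  Non-conflicting ILs
#' are either side by side or one lies entirely inside a single gap of the
#' other.
#'
#' @param x,y Integer vectors of leaf positions (each of size at least 2).
#' @return Logical scalar.
#' @examples
#' ilConflict(c(1, 7), c(2, 6))  # FALSE: {2,6} sits in the gap of {1,7}
#' ilConflict(c(1, 4), c(2, 6))  # TRUE: interleaving
#' @export
ilConflict <- function(x, y) {
  if (length(intersect(x, y))) return(TRUE)
  # interleaving test on sorted members: some element of y strictly between
  # two elements of x AND some element of y outside [min(x), max(x)] side of it
  # (and symmetrically); equivalent to: neither "y within one gap of x or
  # disjoint spans" -- do it directly.
  .interleaves(x, y) || .interleaves(y, x)
}

# exists i < k < j < l with i, j in a and k, l in b
.interleaves <- function(a, b) {
  for (k in b) {
    if (any(a < k) && any(a > k)) {
      # k is strictly inside span of a, between two members; need l in b with
      # l > some a-member that is > k
      jcand <- a[a > k]
      if (any(b > min(jcand))) {
        # verify a true pattern i < k < j < l
        i <- max(a[a < k]); j <- min(jcand)
        if (any(b > j)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Gaps of an internal leafset
#'
#' The maximal intervals of positions between consecutive members of the IL.
#'
#' @param members Sorted integer vector of IL members (size at least 2).
#' @return Two-column integer matrix of gap intervals \code{(lo, hi)}
#'   (possibly zero rows).
#' @examples
#' ilGaps(c(1, 2, 6, 7))  # one gap [3, 5]
#' @export
ilGaps <- function(members) {
  members <- sort(as.integer(members))
  stopifnot(length(members) >= 2L)
  d <- diff(members)
  idx <- which(d > 1L)
  if (!length(idx)) return(matrix(integer(0), 0, 2))
  cbind(members[idx] + 1L, members[idx + 1L] - 1L)
}

#' Rebuild an RNA tree from its descendant leafsets
#'
#' Inverse of [descendantLeafsets()]: given a conflict-free collection of
#' intervals of \eqn{[0, n+1]} containing the full interval, returns the
#' unique RNA tree whose internal nodes are exactly those intervals.
#'
#' @param dls Two-column integer matrix (or list of length-2 vectors) of
#'   intervals.
#' @param n Underlying sequence length.
#' @return An [RNATree-class].
#' @examples
#' treeFromDLs(rbind(c(0, 8), c(1, 7), c(2, 6)), 7)
#' @export
treeFromDLs <- function(dls, n) {
  dls <- .asPairMatrix(dls)
  n <- as.integer(n)
  if (!any(dls[, 1L] == 0L & dls[, 2L] == n + 1L))
    stop("the full interval [0, n+1] must be part of the collection")
  if (anyDuplicated(.pairKeys(dls)))
    stop("duplicate interval in the collection")
  k <- nrow(dls)
  if (k > 1L) {
    m <- dls[order(dls[, 1L], -dls[, 2L]), , drop = FALSE]
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
      if (dlConflict(m[a, ], m[b, ]))
        stop(sprintf("conflicting intervals [%d,%d] and [%d,%d]",
                     m[a, 1L], m[a, 2L], m[b, 1L], m[b, 2L]))
    }
  }
  # RNATree validity additionally rejects endpoint-sharing interval families,
  # which cannot be the node set of an RNA tree
  tryCatch(RNATree(n, dls[!(dls[, 1L] == 0L & dls[, 2L] == n + 1L), ,
                          drop = FALSE]),
           error = function(e)
             stop("collection is not the descendant-leafset set of any RNA tree: ",
                  conditionMessage(e)))
}

#' Rebuild an RNA tree from a structural partition
#'
#' A structural partition of \eqn{[0, n+1]} is a partition into
#' non-conflicting blocks of size at least 2; when 0 and \eqn{n+1} share a
#' block there is exactly one RNA tree whose internal leafsets are the blocks
#' (each block \eqn{I} becomes the internal node
#' \eqn{(\min I, \max I)}).
#'
#' @param blocks List of integer vectors partitioning \eqn{[0, n+1]}.
#' @param n Underlying sequence length.
#' @return An [RNATree-class] with \code{internalLeafsets} equal to
#'   \code{blocks}.
#' @examples
#' treeFromStructuralPartition(list(c(0, 8), c(1, 7), 2:6), 7)
#' @export
treeFromStructuralPartition <- function(blocks, n) {
  n <- as.integer(n)
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  sizes <- lengths(blocks)
  if (any(sizes < 2L))
    stop("every block of a structural partition has size at least 2")
  all_members <- sort(unlist(blocks))
  if (!identical(all_members, 0:(n + 1L)))
    stop("blocks must partition [0, n+1] exactly")
  root <- which(vapply(blocks, function(b) 0L %in% b, logical(1)))
  if (!((n + 1L) %in% blocks[[root]]))
    stop("0 and n+1 must belong to the same block")
  nb <- length(blocks)
  if (nb > 1L) for (a in seq_len(nb - 1L)) for (b in seq(a + 1L, nb)) {
    if (ilConflict(blocks[[a]], blocks[[b]]))
      stop("blocks {", .ilKey(blocks[[a]]), "} and {", .ilKey(blocks[[b]]),
           "} are conflicting")
  }
  nodes <- t(vapply(blocks, function(b) c(min(b), max(b)), integer(2)))
  tr <- RNATree(n, nodes[-root, , drop = FALSE])
  # the partition must be realised exactly (blocks nested into gaps)
  got <- internalLeafsets(tr)
  want <- sort(vapply(blocks, .ilKey, character(1)))
  if (!identical(sort(vapply(got, .ilKey, character(1))), want))
    stop("blocks do not form a structural partition realisable by an RNA tree")
  tr
}
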