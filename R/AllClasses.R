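#' @import methods
NULL

#' RNA secondary structure
#'
#' An RNA secondary structure of length \code{n} is a set of base pairs
#' \eqn{(i, j)}, \eqn{1 \le i < j \le n}, such that any two pairs are either
#' strictly nested or disjoint (no pseudoknots) and no position belongs to two
#' pairs.  The nucleotide sequence is optional; when present, every pair must
#' join Watson-Crick (AU, UA, CG, GC) or Wobble (GU, UG) bases.
#'
#' @slot n Integer scalar, the sequence length.
#' @slot pairs Two-column integer matrix of base pairs, one row per pair,
#'   first column strictly smaller than the second.
#' @slot sequence Character scalar over \code{A,C,G,U}, or \code{character(0)}
#'   when no sequence is attached.
#'
#' @seealso [RNAStructure()] for the user constructor,
#'   [parseDotBracket()] and [writeDotBracket()].
#' @exportClass RNAStructure
setClass("RNAStructure",
         slots = c(n = "integer", pairs = "matrix", sequence = "character"))

#' RNA tree
#'
#' The ordered rooted tree of an RNA structure of length \code{n}: its leaves
#' are the positions \eqn{[0, n+1]} (two fictive flanking positions added),
#' and its internal nodes are the base pairs plus the fictive root pair
#' \eqn{(0, n+1)}.  Each internal node \eqn{(i, j)} has the leaves \eqn{i} and
#' \eqn{j} as leftmost and rightmost children; children are ordered
#' left-to-right by the positions below them.
#'
#' @slot n Integer scalar, the underlying sequence length (the leafset is
#'   \eqn{[0, n+1]}).
#' @slot nodes Two-column integer matrix of internal nodes, always containing
#'   the row \code{c(0, n+1)}; rows are stored in preorder (increasing left
#'   endpoint, decreasing right endpoint on ties).
#'
#' @seealso [RNATree()], [structureToTree()], [treeToStructure()],
#'   [descendantLeafsets()], [internalLeafsets()].
#' @exportClass RNATree
setClass("RNATree", slots = c(n = "integer", nodes = "matrix"))

#' Mapping between two RNA trees
#'
#' An order- and nesting-preserving partial bijection between the internal
#' nodes of two RNA trees, as produced by [treeEditDistance()] and
#' [reDistance()].  Unmapped internal nodes of either tree each contribute 1
#' to the cost; mapped couples contribute their rename cost.
#'
#' @slot pairs Four-column integer matrix; each row \code{(i1, j1, i2, j2)}
#'   maps node \code{(i1, j1)} of the first tree to \code{(i2, j2)} of the
#'   second.
#' @slot cost Numeric scalar, the total cost of the mapping.
#'
#' @exportClass TreeMapping
setClass("TreeMapping", slots = c(pairs = "matrix", cost = "numeric"))

#' Aligned RNA family
#'
#' A set of aligned sequences (equal length, possibly gapped) together with a
#' consensus secondary structure in alignment coordinates, as read from a
#' Stockholm file, plus optional per-sequence structures and a phylogeny.
#'
#' @slot sequences Named character vector of aligned sequences.
#' @slot consensus Character scalar, the consensus structure in dot-bracket
#'   (alignment coordinates), or \code{character(0)}.
#' @slot structures List of [RNAStructure-class] objects in alignment
#'   coordinates (no sequence attached), parallel to \code{sequences}; may be
#'   empty until [perSequenceStructure()] is applied.
#' @slot phylo A rooted \code{ape::phylo} phylogeny whose tips name the
#'   sequences, or \code{NULL}.
#'
#' @seealso [readStockholm()], [projectGapless()].
#' @exportClass AlignedFamily
setClass("AlignedFamily",
         slots = c(sequences = "character", consensus = "character",
                   structures = "list", phylo = "ANY"))

#' Small parsimony assignment
#'
#' An assignment of RNA trees to the internal nodes of a phylogeny, with its
#' parsimony cost (the sum, over phylogeny edges, of the chosen distance
#' between the trees at the two endpoints).
#'
#' @slot assignments Named list of [RNATree-class] objects; names are the
#'   internal node numbers of the \code{ape::phylo} object as characters.
#' @slot cost Numeric scalar, the total cost over all edges.
#' @slot metric Character scalar, one of \code{"RF"}, \code{"IL"},
#'   \code{"RE"}.
#'
#' @seealso [fitchHartiganRF()], [restrictedAssignment()],
#'   [medianLocalSearch()], [spCost()].
#' @exportClass SPAssignment
setClass("SPAssignment",
         slots = c(assignments = "list", cost = "numeric", metric = "character"))

.validRNAStructure <- function(object) {
  n <- object@n
  p <- object@pairs
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("n must be a positive integer scalar")
  if (!is.numeric(p) || ncol(p) != 2L)
    return("pairs must be a two-column integer matrix")
  if (nrow(p) > 0L) {
    if (any(p[, 1L] < 1L) || any(p[, 2L] > n))
      return("pair positions must lie in [1, n]")
    if (any(p[, 1L] >= p[, 2L]))
      return("each pair (i, j) must satisfy i < j")
    pos <- c(p[, 1L], p[, 2L])
    if (anyDuplicated(pos))
      return("a position occurs in two pairs")
    if (!.pairsNested(p))
      return("pairs must be pairwise nested or disjoint (no pseudoknots)")
  }
  if (length(object@sequence)) {
    s <- object@sequence
    if (length(s) != 1L || nchar(s) != n)
      return("sequence must be a single string of length n")
    chars <- strsplit(s, "")[[1L]]
    if (!all(chars %in% c("A", "C", "G", "U")))
      return("sequence must be over the alphabet {A, C, G, U}")
    if (nrow(p) > 0L) {
      bp <- paste0(chars[p[, 1L]], chars[p[, 2L]])
      ok <- bp %in% c("AU", "UA", "CG", "GC", "GU", "UG")
      if (!all(ok))
        return(sprintf("pair (%d, %d) is not a Watson-Crick or Wobble pair",
                       p[which(!ok)[1L], 1L], p[which(!ok)[1L], 2L]))
    }
  }
  TRUE
}
setValidity("RNAStructure", .validRNAStructure)

.validRNATree <- function(object) {
  n <- object@n
  nd <- object@nodes
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("n must be a positive integer scalar")
  if (!is.numeric(nd) || ncol(nd) != 2L || nrow(nd) < 1L)
    return("nodes must be a non-empty two-column integer matrix")
  if (!any(nd[, 1L] == 0L & nd[, 2L] == n + 1L))
    return("nodes must contain the fictive root pair (0, n+1)")
  if (any(nd[, 1L] < 0L) || any(nd[, 2L] > n + 1L) || any(nd[, 1L] >= nd[, 2L]))
    return("nodes must be pairs (i, j) with 0 <= i < j <= n+1")
  inner <- nd[!(nd[, 1L] == 0L & nd[, 2L] == n + 1L), , drop = FALSE]
  if (nrow(inner) > 0L) {
    pos <- c(inner[, 1L], inner[, 2L])
    if (anyDuplicated(pos))
      return("two internal nodes share a leaf endpoint")
    if (any(pos < 1L) || any(pos > n))
      return("non-root nodes must lie within [1, n]")
    if (!.pairsNested(inner))
      return("nodes must be pairwise strictly nested or disjoint")
  }
  TRUE
}
setValidity("RNATree", .validRNATree)

# linear-time crossing check on a set of (i, j) pairs with distinct endpoints
.pairsNested <- function(p) {
  if (nrow(p) <= 1L) return(TRUE)
  m <- max(p[, 2L])
  opens <- integer(m); closes <- integer(m)
  opens[p[, 1L]] <- p[, 2L]
  closes[p[, 2L]] <- p[, 1L]
  stack <- integer(nrow(p)); top <- 0L
  for (k in seq_len(m)) {
    if (opens[k] > 0L) {
      top <- top + 1L; stack[top] <- opens[k]
    } else if (closes[k] > 0L) {
      if (top == 0L || stack[top] != k) return(FALSE)
      top <- top - 1L
    }
  }
  top == 0L
}

#' Construct an RNA secondary structure
#'
#' @param n Sequence length (positive integer).
#' @param pairs Two-column matrix (or empty) of base pairs \code{(i, j)} with
#'   \code{i < j}.
#' @param sequence Optional nucleotide string of length \code{n} over
#'   \code{A,C,G,U}; when given, each pair must be canonical (Watson-Crick or
#'   Wobble).
#' @return An [RNAStructure-class] object.
#' @examples
#' RNAStructure(7, rbind(c(1, 7), c(2, 6)))
#' @export
RNAStructure <- function(n, pairs = matrix(integer(0), 0, 2), sequence = NULL) {
  pairs <- .asPairMatrix(pairs)
  if (nrow(pairs) > 1L)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  new("RNAStructure", n = as.integer(n), pairs = pairs,
      sequence = if (is.null(sequence)) character(0) else as.character(sequence))
}

#' Construct an RNA tree
#'
#' @param n Underlying sequence length; the leafset is \eqn{[0, n+1]}.
#' @param nodes Two-column matrix of internal nodes.  The fictive root pair
#'   \code{(0, n+1)} is added if absent.
#' @return An [RNATree-class] object.
#' @examples
#' RNATree(7, rbind(c(1, 7), c(2, 6)))
#' @export
RNATree <- function(n, nodes = matrix(integer(0), 0, 2)) {
  n <- as.integer(n)
  nodes <- .asPairMatrix(nodes)
  if (!any(nodes[, 1L] == 0L & nodes[, 2L] == n + 1L))
    nodes <- rbind(c(0L, n + 1L), nodes)
  # preorder: by left endpoint, enclosing before enclosed
  nodes <- nodes[order(nodes[, 1L], -nodes[, 2L]), , drop = FALSE]
  new("RNATree", n = n, nodes = nodes)
}

.asPairMatrix <- function(x) {
  if (is.null(x) || length(x) == 0L) return(matrix(integer(0), 0, 2))
  if (is.list(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  dimnames(x) <- NULL
  x
}

#' @describeIn RNAStructure-class Number of base pairs.
#' @param x,object An object of the documented class.
#' @export
setMethod("length", "RNAStructure", function(x) nrow(x@pairs))

#' Base pairs of a structure or tree
#'
#' For an [RNAStructure-class], the stored pair matrix; for an
#' [RNATree-class], its internal nodes without the fictive root (the induced
#' base pairs).
#'
#' @param x An [RNAStructure-class] or [RNATree-class].
#' @return Two-column integer matrix.
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname basePairs
#' @export
setMethod("basePairs", "RNAStructure", function(x) x@pairs)

#' @rdname basePairs
#' @export
setMethod("basePairs", "RNATree", function(x) {
  x@nodes[!(x@nodes[, 1L] == 0L & x@nodes[, 2L] == x@n + 1L), , drop = FALSE]
})

#' Structure/tree length
#'
#' @param x An [RNAStructure-class] or [RNATree-class].
#' @return The underlying sequence length \code{n}.
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname seqLength
#' @export
setMethod("seqLength", "RNAStructure", function(x) x@n)

#' @rdname seqLength
#' @export
setMethod("seqLength", "RNATree", function(x) x@n)

#' Internal nodes of an RNA tree
#'
#' @param x An [RNATree-class].
#' @return Two-column integer matrix including the fictive root
#'   \code{(0, n+1)}, in preorder.
#' @export
internalNodes <- function(x) {
  stopifnot(is(x, "RNATree"))
  x@nodes
}

#' @describeIn RNAStructure-class Display the structure in dot-bracket.
#' @export
setMethod("show", "RNAStructure", function(object) {
  cat(sprintf("RNAStructure of length %d with %d base pair(s)\n",
              object@n, nrow(object@pairs)))
  if (length(object@sequence)) cat(" ", object@sequence, "\n")
  cat(" ", writeDotBracket(object), "\n")
  invisible(object)
})

#' @describeIn RNATree-class Display the tree as dot-bracket plus node count.
#' @export
setMethod("show", "RNATree", function(object) {
  cat(sprintf("RNATree on leafset [0, %d] with %d internal node(s)\n",
              object@n + 1L, nrow(object@nodes)))
  cat(" ", writeDotBracket(treeToStructure(object)), "\n")
  invisible(object)
})

#' @describeIn TreeMapping-class Display the mapping.
#' @export
setMethod("show", "TreeMapping", function(object) {
  cat(sprintf("TreeMapping of %d node couple(s), cost %g\n",
              nrow(object@pairs), object@cost))
  if (nrow(object@pairs))
    apply(object@pairs, 1L, function(r)
      cat(sprintf("  (%d,%d) -> (%d,%d)\n", r[1], r[2], r[3], r[4])))
  invisible(object)
})

#' @describeIn SPAssignment-class Display the assignment summary.
#' @export
setMethod("show", "SPAssignment", function(object) {
  cat(sprintf("SPAssignment under %s: %d ancestral tree(s), SP cost %g\n",
              object@metric, length(object@assignments), object@cost))
  invisible(object)
})

#' @describeIn AlignedFamily-class Display a summary of the family.
#' @export
setMethod("show", "AlignedFamily", function(object) {
  cat(sprintf("AlignedFamily: %d sequence(s), alignment width %d\n",
              length(object@sequences),
              if (length(object@sequences)) nchar(object@sequences[[1L]]) else 0L))
  if (length(object@consensus)) cat("  consensus:", object@consensus, "\n")
  if (!is.null(object@phylo)) cat("  with phylogeny\n")
  invisible(object)
})

#' Accessors for small parsimony assignments
#'
#' @param x An [SPAssignment-class].
#' @return \code{ancestralTrees} returns the named list of [RNATree-class]
#'   assignments; \code{parsimonyCost} the total cost over edges.
#' @export
ancestralTrees <- function(x) {
  stopifnot(is(x, "SPAssignment"))
  x@assignments
}

#' @rdname ancestralTrees
#' @export
parsimonyCost <- function(x) {
  stopifnot(is(x, "SPAssignment"))
  x@cost
}
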