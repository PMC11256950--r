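#' @include trees.R
NULL

.GAP_CHARS <- c("-", ".", "_", "~")
.CANONICAL <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Construct an aligned family
#'
#' @param sequences Named character vector of equal-length aligned sequences
#'   (gaps allowed).
#' @param consensus Optional consensus structure string (dot-bracket or WUSS
#'   brackets) in alignment coordinates.
#' @param structures Optional list of per-sequence [RNAStructure-class]
#'   objects in alignment coordinates.
#' @param phylo Optional rooted \code{ape::phylo} whose tips name the
#'   sequences.
#' @return An [AlignedFamily-class].
#' @export
AlignedFamily <- function(sequences, consensus = character(0),
                          structures = list(), phylo = NULL) {
  sequences <- vapply(sequences, as.character, character(1))
  widths <- nchar(sequences)
  if (length(unique(widths)) > 1L)
    stop("aligned sequences must all have the same length")
  if (length(consensus) && nchar(consensus[[1L]]) != widths[[1L]])
    stop("consensus structure length does not match the alignment width")
  new("AlignedFamily", sequences = sequences,
      consensus = as.character(consensus), structures = structures,
      phylo = phylo)
}

# WUSS-style annotation -> base-pair matrix; the four bracket families are
# treated as nested pairs, pseudoknot letters and all other symbols as
# unpaired; crossing pairs after normalisation are an error
.wussPairs <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  openers <- c("<" = ">", "(" = ")", "[" = "]", "{" = "}")
  pairs <- matrix(integer(0), 0, 2)
  for (o in names(openers)) {
    cl <- openers[[o]]
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == o) stack <- c(stack, k)
      else if (chars[k] == cl) {
        if (!length(stack))
          stop(sprintf("unbalanced '%s' at column %d of the consensus", cl, k))
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop(sprintf("unbalanced '%s' at column %d of the consensus", o,
                   stack[length(stack)]))
  }
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    storage.mode(pairs) <- "integer"
    if (!.pairsNested(pairs))
      stop("consensus structure contains crossing base pairs")
  }
  pairs
}

#' Read a Stockholm 1.0 alignment with consensus structure
#'
#' Parses the sequences and the \code{#=GC SS_cons} consensus-structure line
#' (multi-block files are concatenated).  The WUSS bracket families
#' \code{<>}, \code{()}, \code{[]}, \code{\{\}} are all read as nested base
#' pairs; pseudoknot letters and every other symbol are treated as unpaired.
#'
#' @param path Path to a Stockholm file.
#' @return An [AlignedFamily-class] with \code{sequences} and
#'   \code{consensus} filled in.
#' @export
readStockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[[1L]]))
    warning("file does not start with a '# STOCKHOLM' header")
  seqs <- character(0)
  cons <- ""
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || identical(trimws(ln), "//")) next
    if (startsWith(ln, "#=GC")) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) >= 3L && f[2L] == "SS_cons")
        cons <- paste0(cons, f[3L])
      next
    }
    if (startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) != 2L) next
    nm <- f[1L]
    if (nm %in% names(seqs)) seqs[[nm]] <- paste0(seqs[[nm]], f[2L])
    else seqs[[nm]] <- f[2L]
  }
  if (!length(seqs)) stop("no sequences found in ", path)
  if (!nzchar(cons))
    stop("no '#=GC SS_cons' consensus-structure line found in ", path)
  .wussPairs(cons)  # validate early: balanced, non-crossing
  AlignedFamily(sequences = seqs, consensus = cons)
}

#' Project a consensus structure onto one aligned sequence
#'
#' Keeps only the consensus base pairs that are valid for the sequence: both
#' positions must carry nucleotides (not gaps) forming a Watson-Crick
#' (AU, UA, CG, GC) or Wobble (GU, UG) pair.  All other consensus pairs are
#' dropped.
#'
#' @param consensus Consensus structure (dot-bracket/WUSS string, or a
#'   two-column pair matrix) in alignment coordinates.
#' @param sequence Aligned sequence string of the same length (gap characters
#'   \code{-}, \code{.}, \code{_}, \code{~}; \code{T} read as \code{U}).
#' @return An [RNAStructure-class] in alignment coordinates (no sequence
#'   attached, since the row may contain gaps).
#' @examples
#' writeDotBracket(perSequenceStructure("((...))", "GGAAACC"))
#' @export
perSequenceStructure <- function(consensus, sequence) {
  if (is.character(consensus)) {
    pairs <- .wussPairs(consensus)
    width <- nchar(consensus)
  } else {
    pairs <- .asPairMatrix(consensus)
    width <- nchar(sequence)
  }
  if (nchar(sequence) != width)
    stop("sequence and consensus lengths differ (", nchar(sequence),
         " vs ", width, ")")
  chars <- toupper(strsplit(sequence, "")[[1L]])
  chars[chars == "T"] <- "U"
  keep <- logical(nrow(pairs))
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- chars[pairs[r, 1L]]; b <- chars[pairs[r, 2L]]
    keep[r] <- !(a %in% .GAP_CHARS) && !(b %in% .GAP_CHARS) &&
      paste0(a, b) %in% .CANONICAL
  }
  RNAStructure(width, pairs[keep, , drop = FALSE])
}

#' Project an aligned family to gap-free structures
#'
#' Applies the gap-removal rule for obtaining equal-length structures: every
#' alignment column containing a gap in any sequence is deleted, surviving
#' positions are renumbered, and a pair losing exactly one endpoint leaves
#' its surviving partner unpaired.  Per-sequence structures are first derived
#' from the consensus with [perSequenceStructure()] when not already present.
#'
#' @param family An [AlignedFamily-class].
#' @return Named list of gap-free [RNAStructure-class] objects of one common
#'   length, with their (ungapped) sequences attached.
#' @export
projectGapless <- function(family) {
  stopifnot(is(family, "AlignedFamily"))
  seqs <- family@sequences
  width <- nchar(seqs[[1L]])
  rows <- lapply(seqs, function(s) {
    ch <- toupper(strsplit(s, "")[[1L]])
    ch[ch == "T"] <- "U"
    ch
  })
  structures <- family@structures
  if (!length(structures)) {
    if (!length(family@consensus))
      stop("family has neither per-sequence structures nor a consensus")
    structures <- lapply(seqs, function(s)
      perSequenceStructure(family@consensus, s))
  }
  gapped <- Reduce(`|`, lapply(rows, function(ch) ch %in% .GAP_CHARS))
  keep <- which(!gapped)
  if (!length(keep)) stop("every alignment column contains a gap")
  newPos <- integer(width)
  newPos[keep] <- seq_along(keep)
  out <- vector("list", length(seqs))
  names(out) <- names(seqs)
  for (s in seq_along(seqs)) {
    p <- basePairs(structures[[s]])
    if (nrow(p)) {
      both <- newPos[p[, 1L]] > 0L & newPos[p[, 2L]] > 0L
      p <- cbind(newPos[p[both, 1L]], newPos[p[both, 2L]])
    }
    out[[s]] <- RNAStructure(length(keep), p,
                             paste(rows[[s]][keep], collapse = ""))
  }
  out
}

#' Read a rooted phylogeny from a Newick file
#'
#' A thin wrapper over \code{ape::read.tree} that enforces unique leaf
#' names.  The tree is interpreted as rooted at its outermost node, so a
#' basal polytomy is read as a multifurcating root rather than as an
#' unrooted tree; branch lengths are parsed but ignored by the parsimony
#' algorithms.
#'
#' @param path Path to a Newick file (or use \code{text =} via \code{...}).
#' @param ... Passed to \code{ape::read.tree}.
#' @return A rooted \code{ape::phylo} object (possibly multifurcating).
#' @export
readNewickPhylogeny <- function(path = NULL, ...) {
  phy <- if (is.null(path)) ape::read.tree(...) else ape::read.tree(path, ...)
  if (is.null(phy)) stop("malformed Newick input")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy
}

#' Write a phylogeny and its ancestral assignment
#'
#' Labels every internal node \code{N<number>}, writes the Newick tree and a
#' tab-separated table mapping node labels to dot-bracket structures (leaves
#' included).
#'
#' @param phylo A rooted \code{ape::phylo}.
#' @param leafTrees Named list of leaf trees/structures.
#' @param assignment An [SPAssignment-class] for \code{phylo}.
#' @param newickPath,tablePath Output paths; either may be \code{NULL} to
#'   skip.
#' @return Invisibly, the annotation table (data.frame with columns
#'   \code{node} and \code{structure}).
#' @export
writeAncestralNewick <- function(phylo, leafTrees, assignment,
                                 newickPath = NULL, tablePath = NULL) {
  info <- .phyloInfo(phylo)
  phy <- phylo
  phy$node.label <- paste0("N", seq(info$ntip + 1L, info$total))
  amap <- if (is(assignment, "SPAssignment")) assignment@assignments else assignment
  nodes <- c(phylo$tip.label, phy$node.label)
  structs <- character(info$total)
  for (v in seq_len(info$ntip))
    structs[v] <- writeDotBracket(.asTree(leafTrees[[phylo$tip.label[v]]]))
  for (v in seq(info$ntip + 1L, info$total))
    structs[v] <- writeDotBracket(amap[[as.character(v)]])
  tab <- data.frame(node = nodes, structure = structs,
                    stringsAsFactors = FALSE)
  if (!is.null(newickPath)) ape::write.tree(phy, file = newickPath)
  if (!is.null(tablePath))
    utils::write.table(tab, tablePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
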