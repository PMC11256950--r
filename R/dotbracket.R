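#' @include AllClasses.R
NULL

#' Parse a dot-bracket string
#'
#' Converts a string over \code{(}, \code{)}, \code{.} into an
#' [RNAStructure-class] by matched-parenthesis pairing.  Crossing structures
#' cannot be written in single-bracket dot-bracket, so the output is always
#' pseudoknot-free.
#'
#' @param s Dot-bracket string.
#' @param sequence Optional nucleotide string of the same length.
#' @return An [RNAStructure-class] of length \code{nchar(s)}.
#' @examples
#' parseDotBracket("((...))")
#' @export
parseDotBracket <- function(s, sequence = NULL) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "")[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1L]], bad[1L]))
  n <- length(chars)
  stack <- integer(n); top <- 0L
  pairs <- matrix(integer(0), 0, 2)
  open <- integer(0); close <- integer(0)
  for (k in seq_len(n)) {
    if (chars[k] == "(") {
      top <- top + 1L; stack[top] <- k
    } else if (chars[k] == ")") {
      if (top == 0L)
        stop(sprintf("unbalanced ')' at position %d", k))
      open <- c(open, stack[top]); close <- c(close, k)
      top <- top - 1L
    }
  }
  if (top > 0L)
    stop(sprintf("unbalanced '(' at position %d (end of string reached)", stack[top]))
  if (length(open)) pairs <- cbind(open, close)
  RNAStructure(n, pairs, sequence)
}

#' Write a structure or tree as dot-bracket
#'
#' The inverse of [parseDotBracket()].  The fictive root pair \code{(0, n+1)}
#' of an [RNATree-class] is never emitted.
#'
#' @param x An [RNAStructure-class] or [RNATree-class].
#' @return A dot-bracket string of length \code{n}.
#' @examples
#' writeDotBracket(parseDotBracket("(.(...).)"))
#' @export
writeDotBracket <- function(x) {
  if (is(x, "RNATree")) x <- treeToStructure(x)
  stopifnot(is(x, "RNAStructure"))
  chars <- rep(".", x@n)
  if (nrow(x@pairs)) {
    chars[x@pairs[, 1L]] <- "("
    chars[x@pairs[, 2L]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Read dot-bracket structures from a file
#'
#' Accepts either one structure per line or FASTA-like records
#' (\code{">id"} lines followed by one dot-bracket line each).  Blank lines
#' are skipped.
#'
#' @param path Path to a text file.
#' @return Named list of [RNAStructure-class] objects (names are record ids,
#'   or \code{"S1"}, \code{"S2"}, ... for bare lines).
#' @export
readDotBracket <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no structures found in ", path)
  if (any(startsWith(lines, ">"))) {
    idx <- which(startsWith(lines, ">"))
    if (any(idx + 1L > length(lines)) || any((idx + 1L) %in% idx))
      stop("malformed FASTA-like dot-bracket file: record without structure line")
    ids <- sub("^>\\s*", "", lines[idx])
    structs <- lapply(lines[idx + 1L], parseDotBracket)
    names(structs) <- ids
  } else {
    structs <- lapply(lines, parseDotBracket)
    names(structs) <- paste0("S", seq_along(structs))
  }
  lens <- vapply(structs, seqLength, integer(1))
  if (length(unique(lens)) > 1L)
    warning("structures in ", path, " do not all share one length")
  structs
}

#' Write dot-bracket structures to a file
#'
#' @param structures Named list of [RNAStructure-class] or [RNATree-class]
#'   objects.
#' @param path Output path.
#' @param fasta Emit FASTA-like records (default) or bare lines.
#' @return Invisibly, \code{path}.
#' @export
writeDotBracketFile <- function(structures, path, fasta = TRUE) {
  db <- vapply(structures, writeDotBracket, character(1))
  if (fasta) {
    ids <- names(structures)
    if (is.null(ids)) ids <- paste0("S", seq_along(db))
    writeLines(as.vector(rbind(paste0(">", ids), db)), path)
  } else {
    writeLines(db, path)
  }
  invisible(path)
}
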