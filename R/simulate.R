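#' @include AllClasses.R
NULL

# S[m+1] = number of admissible structures of length m (offset-1 table);
# a pair (i, j) must enclose at least theta positions (j - i - 1 >= theta)
.countTable <- function(m, theta) {
  S <- numeric(m + 1L)
  S[1L] <- 1
  if (m >= 1L) for (k in seq_len(m)) {
    tot <- S[k]                       # first position unpaired
    jlo <- theta + 2L
    if (jlo <= k) for (j in jlo:k)    # first position paired to j
      tot <- tot + S[j - 1L] * S[k - j + 1L]
    S[k + 1L] <- tot
  }
  S
}

#' Count secondary structures of a given length
#'
#' The number of well-formed dot-bracket strings of length \code{m} in which
#' every pair \eqn{(i, j)} encloses at least \code{theta} positions
#' (\eqn{j - i - 1 \ge \theta}).  Computed by the standard decomposition on
#' the first position (unpaired, or paired to some \eqn{j \ge \theta + 2});
#' with \code{theta = 0} these are the Motzkin numbers.  Counts are exact as
#' long as they stay below \eqn{2^{53}} (double-precision integers); beyond
#' that they are correct to about 15 significant digits, which leaves the
#' sampler uniform to the same relative accuracy.
#'
#' @param m Structure length (non-negative integer).
#' @param theta Minimum number of enclosed positions per pair (default 3,
#'   the standard minimum hairpin size).
#' @return Numeric scalar count.
#' @examples
#' countStructures(5, 3)   # 2: all-unpaired or the single pair (1, 5)
#' countStructures(4, 0)   # 9, the Motzkin number M4
#' @export
countStructures <- function(m, theta = 3L) {
  stopifnot(m >= 0L, theta >= 0L)
  .countTable(as.integer(m), as.integer(theta))[m + 1L]
}

#' Sample a secondary structure uniformly
#'
#' Draws one structure from the uniform distribution over all admissible
#' structures of length \code{n} with minimum enclosed size \code{theta}, by
#' stochastic backtracking over the counting decomposition: every admissible
#' structure has probability exactly \eqn{1/S(n, \theta)} (uniform sampling
#' is the zero-temperature case of Boltzmann sampling).  Uses R's global
#' random number generator; call \code{set.seed} for reproducibility.
#'
#' @param n Structure length.
#' @param theta Minimum number of enclosed positions per pair (default 3).
#' @return An [RNAStructure-class].
#' @examples
#' set.seed(1)
#' writeDotBracket(sampleStructure(20))
#' @export
sampleStructure <- function(n, theta = 3L) {
  n <- as.integer(n); theta <- as.integer(theta)
  S <- .countTable(n, theta)
  pairs <- matrix(integer(0), 0, 2)
  rec <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m <= 0L) return(invisible())
    u <- stats::runif(1) * S[m + 1L]
    if (u < S[m] || m < theta + 2L) {
      rec(lo + 1L, hi)
      return(invisible())
    }
    acc <- S[m]
    for (j in (theta + 2L):m) {
      w <- S[j - 1L] * S[m - j + 1L]
      if (u < acc + w) {
        pairs <<- rbind(pairs, c(lo, lo + j - 1L))
        rec(lo + 1L, lo + j - 2L)
        rec(lo + j, hi)
        return(invisible())
      }
      acc <- acc + w
    }
    # numerical guard: fall back on the last decomposition term
    pairs <<- rbind(pairs, c(lo, hi))
    rec(lo + 1L, hi - 1L)
    invisible()
  }
  rec(1L, n)
  RNAStructure(n, pairs)
}

#' Simulate a random instance: complete binary phylogeny with uniform leaves
#'
#' Builds a complete binary phylogeny of height \code{H} (hence \eqn{2^H}
#' leaves) with unit edges and annotates every leaf with an independent
#' uniform structure of length \code{n} and minimum enclosed size
#' \code{theta}.  The defaults (\code{H = 5}, \code{n = 100},
#' \code{theta = 3}) give 32 leaves of length 100.
#'
#' @param H Height of the complete binary phylogeny (at least 1).
#' @param n Structure length.
#' @param theta Minimum number of enclosed positions per pair.
#' @return List with elements \code{phylo} (an \code{ape::phylo}) and
#'   \code{structures} (named list of [RNAStructure-class], names matching
#'   the tip labels).
#' @examples
#' set.seed(7)
#' inst <- randomInstance(H = 2, n = 30)
#' @export
randomInstance <- function(H = 5L, n = 100L, theta = 3L) {
  stopifnot(H >= 1L)
  ntips <- 2L^as.integer(H)
  phy <- ape::stree(ntips, type = "balanced")
  phy$edge.length <- rep(1, nrow(phy$edge))
  structs <- replicate(ntips, sampleStructure(n, theta), simplify = FALSE)
  names(structs) <- phy$tip.label
  list(phylo = phy, structures = structs)
}
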