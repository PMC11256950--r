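#' @include medians.R
NULL

# basic rooted-phylogeny bookkeeping on an ape::phylo object
.phyloInfo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("phylogeny must be an ape 'phylo' object")
  nt <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf names in the phylogeny")
  nn <- phy$Nnode
  total <- nt + nn
  children <- vector("list", total)
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    children[[u]] <- c(children[[u]], v)
  }
  parent <- integer(total)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])
  if (length(root) != 1L) stop("phylogeny must be rooted")
  # postorder over all nodes
  post <- integer(0)
  stack <- root; seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    ch <- children[[v]]
    if (!length(ch) || v %in% seen) {
      post <- c(post, v)
      stack <- stack[-length(stack)]
    } else {
      seen <- c(seen, v)
      stack <- c(stack, rev(ch))
    }
  }
  list(ntip = nt, nnode = nn, total = total, children = children,
       parent = parent, root = root, postorder = post,
       internal = post[post > nt])
}

# match leaf trees to tips; returns list indexed by node number (tips only)
.leafTreesByTip <- function(phy, leafTrees, info) {
  if (is.null(names(leafTrees)))
    stop("leaf trees must be a named list matching the phylogeny tip labels")
  miss <- setdiff(phy$tip.label, names(leafTrees))
  if (length(miss))
    stop("no structure supplied for leaf label(s): ", paste(miss, collapse = ", "))
  trees <- .treeList(leafTrees[phy$tip.label])
  trees
}

#' Small parsimony cost of an assignment
#'
#' The sum, over the edges of the phylogeny, of the chosen distance between
#' the trees at the two endpoints (leaves carry their fixed input trees).
#'
#' @param phylo A rooted \code{ape::phylo} phylogeny (multifurcations
#'   allowed).
#' @param leafTrees Named list of [RNATree-class]/[RNAStructure-class]
#'   objects, names matching \code{phylo$tip.label}.
#' @param assignments An [SPAssignment-class], or a named list of trees keyed
#'   by internal node number (as character).
#' @param metric One of \code{"RF"}, \code{"IL"}, \code{"RE"}.
#' @return Numeric scalar.
#' @export
spCost <- function(phylo, leafTrees, assignments, metric = c("RF", "IL", "RE")) {
  metric <- match.arg(toupper(metric[1L]), c("RF", "IL", "RE"))
  fn <- .metricFun(metric)
  info <- .phyloInfo(phylo)
  tips <- .leafTreesByTip(phylo, leafTrees, info)
  if (is(assignments, "SPAssignment")) assignments <- assignments@assignments
  atNode <- function(v) {
    if (v <= info$ntip) return(tips[[v]])
    t <- assignments[[as.character(v)]]
    if (is.null(t)) stop("no tree assigned to internal node ", v)
    .asTree(t)
  }
  total <- 0
  for (e in seq_len(nrow(phylo$edge)))
    total <- total + fn(atNode(phylo$edge[e, 1L]), atNode(phylo$edge[e, 2L]))
  total
}

#' Exact small parsimony under the Robinson-Foulds distance
#'
#' Solves the unconstrained small parsimony problem exactly: every candidate
#' descendant leafset occurring in some leaf tree is treated as an
#' independent presence/absence character and reconstructed over the
#' phylogeny with the two-pass Fitch-Hartigan algorithm (Hartigan's
#' generalisation, so multifurcating nodes are handled); ties at the root are
#' resolved to absence.  The leafsets selected at each internal node are
#' always conflict-free and are assembled into an RNA tree.  Leafsets absent
#' from every leaf can never be selected and are not enumerated.  The
#' resulting assignment attains the optimal cost and, since every selected
#' leafset occurs in some input tree, also satisfies the descendant-leafset
#' constraint.
#'
#' @param phylo A rooted \code{ape::phylo} phylogeny (multifurcations
#'   allowed).
#' @param leafTrees Named list of trees/structures, names matching
#'   \code{phylo$tip.label}.
#' @return An [SPAssignment-class] with \code{metric = "RF"}.
#' @examples
#' phy <- ape::read.tree(text = "((A,B),(C,D));")
#' lt <- list(A = parseDotBracket("((...))"), B = parseDotBracket("((...))"),
#'            C = parseDotBracket("(.....)"), D = parseDotBracket("(.....)"))
#' fitchHartiganRF(phy, lt)
#' @export
fitchHartiganRF <- function(phylo, leafTrees) {
  info <- .phyloInfo(phylo)
  tips <- .leafTreesByTip(phylo, leafTrees, info)
  n <- tips[[1L]]@n
  keys <- unique(unlist(lapply(tips, function(t) .pairKeys(t@nodes))))
  ncand <- length(keys)
  tipKeys <- lapply(tips, function(t) .pairKeys(t@nodes))

  # bottom-up state sets per node: 0 absent, 1 present, 2 either
  K <- matrix(0L, ncand, info$total)
  for (v in seq_len(info$ntip))
    K[, v] <- as.integer(keys %in% tipKeys[[v]])
  for (v in info$postorder) {
    ch <- info$children[[v]]
    if (!length(ch)) next
    cnt1 <- integer(ncand); cnt0 <- integer(ncand)
    for (c in ch) {
      cnt1 <- cnt1 + (K[, c] != 0L)   # 1 or 2
      cnt0 <- cnt0 + (K[, c] != 1L)   # 0 or 2
    }
    K[, v] <- ifelse(cnt1 > cnt0, 1L, ifelse(cnt0 > cnt1, 0L, 2L))
  }

  # top-down resolution, ties at the root resolved to absence
  state <- matrix(0L, ncand, info$total)
  for (v in seq_len(info$ntip)) state[, v] <- K[, v]
  for (v in rev(info$postorder)) {
    if (v <= info$ntip) next
    if (v == info$root) {
      state[, v] <- as.integer(K[, v] == 1L)
    } else {
      ps <- state[, info$parent[v]]
      state[, v] <- ifelse(K[, v] == 2L, ps,
                           ifelse(K[, v] == ps, ps, K[, v]))
    }
  }

  dls <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  assignments <- list()
  for (v in info$internal) {
    sel <- dls[state[, v] == 1L, , drop = FALSE]
    # the selected leafsets are guaranteed conflict-free; treeFromDLs throws
    # if that invariant were ever violated
    assignments[[as.character(v)]] <- treeFromDLs(sel, n)
  }
  cost <- spCost(phylo, leafTrees, assignments, "RF")
  new("SPAssignment", assignments = assignments, cost = cost, metric = "RF")
}

#' Restricted-assignment small parsimony (Sankoff)
#'
#' Minimum-cost assignment subject to every internal node carrying one of
#' the distinct trees observed at the leaves: the classical bottom-up
#' dynamic program over (node, candidate) costs with a precomputed pairwise
#' distance matrix, followed by a top-down choice pass.  Ties are broken
#' towards the lowest candidate index (candidates in order of first
#' appearance at the leaves), making the output deterministic.  This is both
#' a baseline solver for any of the three distances and the initialiser of
#' [medianLocalSearch()].
#'
#' @inheritParams spCost
#' @param metric One of \code{"RF"}, \code{"IL"}, \code{"RE"}.
#' @return An [SPAssignment-class].
#' @export
restrictedAssignment <- function(phylo, leafTrees, metric = c("RF", "IL", "RE")) {
  metric <- match.arg(toupper(metric[1L]), c("RF", "IL", "RE"))
  fn <- .metricFun(metric)
  info <- .phyloInfo(phylo)
  tips <- .leafTreesByTip(phylo, leafTrees, info)

  db <- vapply(tips, function(t) writeDotBracket(t), character(1))
  cand <- tips[!duplicated(db)]
  candDb <- db[!duplicated(db)]
  nc <- length(cand)
  tipCand <- match(db, candDb)

  D <- matrix(0, nc, nc)
  if (nc > 1L) for (a in seq_len(nc - 1L)) for (b in seq(a + 1L, nc))
    D[a, b] <- D[b, a] <- fn(cand[[a]], cand[[b]])

  cost <- matrix(Inf, info$total, nc)
  for (v in seq_len(info$ntip)) cost[v, tipCand[v]] <- 0
  for (v in info$postorder) {
    ch <- info$children[[v]]
    if (!length(ch)) next
    acc <- numeric(nc)
    for (c in ch) {
      # for each candidate at v, the cheapest completion of child c
      m <- vapply(seq_len(nc), function(a) min(D[a, ] + cost[c, ]), numeric(1))
      acc <- acc + m
    }
    cost[v, ] <- acc
  }

  choice <- integer(info$total)
  choice[info$root] <- which.min(cost[info$root, ])
  for (v in rev(info$postorder)) {
    ch <- info$children[[v]]
    for (c in ch) {
      if (c <= info$ntip) { choice[c] <- tipCand[c]; next }
      choice[c] <- which.min(D[choice[v], ] + cost[c, ])
    }
  }

  assignments <- list()
  for (v in info$internal) assignments[[as.character(v)]] <- cand[[choice[v]]]
  total <- spCost(phylo, leafTrees, assignments, metric)
  new("SPAssignment", assignments = assignments, cost = total, metric = metric)
}

# solver registry for (metric, constraint) median subproblems
.medianSolver <- function(metric, constraint) {
  metric <- toupper(metric); constraint <- toupper(constraint)
  if (metric == "RF" && constraint %in% c("NC", "DLC")) return(rfMedian)
  if (metric == "RF" && constraint == "ILC") return(rfIlcMedian)
  if (metric == "IL" && constraint == "ILC") return(ilIlcMedian)
  if (metric == "IL" && constraint == "NC") return(ilNcMedian)
  stop("no median solver for metric ", metric, " with constraint ", constraint)
}

#' Median-based local search for small parsimony
#'
#' Starts from the restricted assignment ([restrictedAssignment()]) and
#' repeatedly sweeps the non-root internal nodes in postorder: for each node
#' the median of the trees currently assigned at its neighbours (parent plus
#' children, hence at least three trees) is computed with the exact median
#' solver for the requested metric and constraint, and the node is
#' re-assigned only when this strictly decreases the total cost.  Sweeps
#' repeat until a full sweep makes no change; strict acceptance on
#' integer-bounded costs guarantees termination.  The root is never updated
#' by the median step.
#'
#' @inheritParams spCost
#' @param metric \code{"RF"} or \code{"IL"}.
#' @param constraint \code{"NC"} or \code{"ILC"} (for \code{"RF"},
#'   \code{"DLC"} is also accepted and handled by the consensus solver).
#' @return An [SPAssignment-class]; its cost never exceeds that of the
#'   restricted initialisation.
#' @export
medianLocalSearch <- function(phylo, leafTrees, metric = c("RF", "IL"),
                              constraint = c("ILC", "NC", "DLC")) {
  metric <- match.arg(toupper(metric[1L]), c("RF", "IL"))
  constraint <- match.arg(toupper(constraint[1L]), c("ILC", "NC", "DLC"))
  solver <- .medianSolver(metric, constraint)
  fn <- .metricFun(metric)
  info <- .phyloInfo(phylo)
  tips <- .leafTreesByTip(phylo, leafTrees, info)

  init <- restrictedAssignment(phylo, leafTrees, metric)
  current <- vector("list", info$total)
  for (v in seq_len(info$ntip)) current[[v]] <- tips[[v]]
  for (v in info$internal) current[[v]] <- init@assignments[[as.character(v)]]

  sweepNodes <- setdiff(info$internal, info$root)
  repeat {
    changed <- FALSE
    for (u in sweepNodes) {
      nbr <- c(info$parent[u], info$children[[u]])
      nbrTrees <- current[nbr]
      med <- solver(nbrTrees)$median
      old <- sum(vapply(nbrTrees, function(t) fn(current[[u]], t), numeric(1)))
      newc <- sum(vapply(nbrTrees, function(t) fn(med, t), numeric(1)))
      if (newc < old) {
        current[[u]] <- med
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  assignments <- list()
  for (v in info$internal) assignments[[as.character(v)]] <- current[[v]]
  total <- spCost(phylo, leafTrees, assignments, metric)
  new("SPAssignment", assignments = assignments, cost = total, metric = metric)
}
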