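---
title: "Ancestral RNA secondary structures by maximum parsimony"
author: "RNAparsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral RNA secondary structures by maximum parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAparsimony)
```

## The model: structures as leaf-labeled ordered trees

Within a non-coding RNA family the secondary structure is usually better
conserved than the sequence, so comparing and reconstructing *structures*
along a phylogeny is a natural route to ancestral inference.  This package
works in the gap-free setting: all structures live on a common coordinate
system of length $n$ (either because the family alignment has been projected
to its gap-free columns, or because the data are simulated), and evolution is
modelled as base-pair gain and loss only — no indels.

A structure is a set $P$ of base pairs $(i, j)$, $1 \le i < j \le n$,
pairwise nested or disjoint (pseudoknots are excluded).  Its *RNA tree* is
the ordered rooted tree whose leaves are the positions $0, 1, \dots, n+1$
(two fictive flanking positions are added) and whose internal nodes are the
pairs of $P$ plus a fictive root pair $(0, n+1)$; the node $(i, j)$ has the
leaves $i$ and $j$ as leftmost and rightmost children.  Two views of a tree
drive everything else:

* the **descendant leafset** (DL) of a node $(i, j)$ is the interval
  $[i, j]$ — the analogue of a clade, and in bijection with the base pair;
* the **internal leafset** (IL) of a node is the set of its leaf-children —
  the *loop* closed by that pair.

`parseDotBracket()`, `structureToTree()`, `descendantLeafsets()` and
`internalLeafsets()` implement this data model; `treeFromDLs()` and
`treeFromStructuralPartition()` invert it.  A collection of intervals is the
DL set of a tree exactly when it is conflict-free (no partial overlaps, and —
a point worth making explicit — no two intervals sharing an endpoint, since a
position cannot sit in two pairs; `treeFromDLs()` enforces both).  A
collection of ILs is realisable exactly when it is a *structural partition*:
a partition of $[0, n+1]$ into non-conflicting blocks of size at least two,
with $0$ and $n+1$ sharing a block.

## Three distances

For trees $T_1, T_2$ on one leafset, with $I(\cdot)$ the internal node sets:

* $d_{BP} = |P_1 \,\Delta\, P_2|$, the base-pair distance;
* $d_{RF} = |DL(T_1) \,\Delta\, DL(T_2)|$, the Robinson–Foulds distance,
  which on RNA trees **equals** $d_{BP}$ (the root interval always cancels);
* $d_{IL} = |IL(T_1) \,\Delta\, IL(T_2)|$, which compares loops: a loop
  survives only if *all* pairs delimiting it survive, so this distance is
  sensitive to structural elements rather than individual pairs;
* the tree edit distance
  $d_{TE}^c = \min_M \sum_{(x_1,x_2)\in M} c(x_1,x_2) + |I(T_1)| + |I(T_2)| - 2|M|$
  over order- and nesting-preserving partial bijections $M$.  With a
  prohibitive rename cost it collapses to $d_{BP}$; with the relaxed cost
  $c^*((i_1,j_1),(i_2,j_2)) = |i_1-i_2| + |j_1-j_2|$ it becomes the
  **relaxed edit distance** `reDistance()`, which can match imperfectly
  aligned pairs.

The edit distance is computed by a memoised ordered-forest edit dynamic
program on the internal-node trees (deletion/insertion cost 1, pluggable
rename cost), with a deterministic backtrace (match preferred over deletion
over insertion) returning one optimal mapping.  "Prohibitive" is implemented
as the finite bound $2(n+2)+1$, strictly larger than deleting and
re-inserting every node, so it is provably never chosen and no infinities
enter the arithmetic.

## Medians

The *median* of trees $T_1,\dots,T_p$ minimises $\sum_i D(T_i, T)$.  Three
constraint regimes matter: NC (none), DLC (every output DL occurs in some
input) and ILC (every output IL occurs in some input).  The solvers:

* **`rfMedian()`** — majority rule: the DLs displayed by strictly more than
  $p/2$ inputs are automatically conflict-free and form an optimal
  unconstrained RF median that also satisfies DLC.  DLs at exactly $p/2$
  (even $p$) are excluded.  (Pigeonhole also rules out endpoint-sharing:
  two majority DLs must co-occur in some input tree.)
* **`ilIlcMedian()`** — the IL median cost decomposes over the blocks of the
  output's structural partition with block cost
  $cost_{IL}(I) = \#\{k : I \notin IL(T_k)\} - \#\{k : I \in IL(T_k)\}$
  (possibly negative); summed block costs differ from the true median cost
  by the constant $\sum_k |IL(T_k)|$.  A table $c[i,j]$ over intervals,
  filled in increasing width, decomposes on the block containing $i$: its
  gaps and the remainder after its maximum are optimised independently.
* **`ilNcMedian()`** — without the ILC constraint the block containing $i$
  may be new, at cost $p$; only its second-smallest member $k$ is
  enumerated, the stretch strictly between $i$ and $k$ is optimised
  recursively, and the best family of disjoint gaps inside $[k+1, j-1]$ is a
  maximum-weight independent set of intervals weighted by minus their
  optimal partition cost (`mwisIntervals()`, the classical right-endpoint
  dynamic program).  Two numerical details: the candidate gap window is
  $k+1 \le u < v \le j-1$ (a gap may start immediately after $k$ and must
  end before $j$, since $j$ belongs to the block), and the independent set
  may select *adjacent* intervals — the realised block simply merges them,
  and because partition costs are subadditive over adjacent intervals the
  optimum is unaffected.
* **`rfIlcMedian()`** — the same partition program scores a block by its
  extreme pair: $\#\{k : (\min I, \max I) \notin I(T_k)\} - \#\{k : \in\}$.
  This is the unique block cost whose sum equals the RF median cost up to
  the constant $\sum_k |I(T_k)|$ over ILC-feasible trees; we validate it
  against brute force rather than against any printed formula.

Boundary conditions: single-position intervals are infeasible (blocks have
size $\ge 2$) and are carried as `Inf`; empty intervals cost 0.  Ties among
equal-cost blocks are broken towards the canonically smallest candidate (by
minimum element, then lexicographically), so all solvers are deterministic.
The relaxed edit distance admits no analogous decomposition — different
median pairs can map to different input pairs — and RE medians are left
unimplemented as an open problem, as is the IL median under DLC.

```{r medians}
trees <- lapply(c("((...))", "((...))", "(.....)"), parseDotBracket)
rfMedian(trees)$cost          # 1, attained by "((...))"
ilIlcMedian(trees)$cost       # 3, same median, partition cost -5
```

## Small parsimony

Given a rooted (possibly multifurcating) phylogeny with structures at the
leaves, *small parsimony* assigns a tree to every internal node minimising
the summed distance over edges.

* **`fitchHartiganRF()`** — exact for RF (and automatically DLC-compliant):
  each candidate DL occurring at some leaf is an independent binary
  presence/absence character, reconstructed by Hartigan's two-pass
  generalisation of Fitch (so multifurcations are handled); ties at the root
  resolve to absence, which keeps the selected DL sets conflict-free (the
  package still asserts this at runtime by rebuilding each ancestor through
  `treeFromDLs()`).  DLs absent from every leaf can never win a vote and are
  not enumerated.
* **`restrictedAssignment()`** — the classical Sankoff dynamic program with
  the candidate set restricted to the distinct leaf trees; works for all
  three distances (it is the only solver offered for RE, whose exact small
  parsimony is open).  Ties go to the lowest candidate index.
* **`medianLocalSearch()`** — initialises with the restricted assignment,
  then sweeps the non-root internal nodes in postorder, re-assigning a node
  to the median of its neighbours' current trees (parent plus children)
  whenever that *strictly* decreases the cost, until a sweep changes
  nothing.  Strict acceptance on integer-bounded costs guarantees
  termination.  Following the definition of the heuristic, the root is never
  updated by the median step; whether updating it would help is left open,
  and the restricted initialisation already places a sensible tree there.

## The simulator and what it does (not) show

`randomInstance()` reproduces the simulated study design: a complete binary
phylogeny of height $H = 5$ (32 leaves, unit edges) whose leaves carry
independent structures drawn *uniformly* from all well-formed dot-bracket
strings of length $N = 100$ in which every pair $(i, j)$ encloses at least
$\theta = 3$ positions ($j - i - 1 \ge \theta$).  We read the minimum
hairpin parameter as constraining *every* pair, the standard RNA convention;
under the counting decomposition the innermost pairs are exactly the ones
enclosing only unpaired positions, so the two readings coincide where it
matters.  `countStructures()` evaluates the recursion
$S_m = S_{m-1} + \sum_{j \ge \theta+2} S_{j-2}\,S_{m-j}$ and
`sampleStructure()` backtracks through it stochastically, so every structure
has probability exactly $1/S_N$ — uniform sampling being the
zero-temperature case of Boltzmann sampling.  Counts are kept in double
precision: exact up to $2^{53}$, and at $N = 100$ correct to about 15
significant digits, which perturbs sampling probabilities by a relative
$10^{-15}$ — far below anything a goodness-of-fit test at realistic sample
sizes could detect.

Leaves are i.i.d. uniform: the generator emulates maximal structural
divergence, not descent with modification, and real RFAM families are far
more self-similar.  Passing tests on this generator therefore demonstrate
algorithmic correctness and the qualitative behaviour of the
metric/constraint combinations under high divergence; they say nothing about
reconstruction accuracy on real families, for which no ground-truth
ancestors exist anyway.  The alignment side (`readStockholm()`,
`perSequenceStructure()`, `projectGapless()`) applies the preprocessing
rules — keep only Watson-Crick/Wobble-valid consensus pairs per sequence,
delete every column containing a gap in *any* row ("any" read literally),
unpair the surviving partner of a half-deleted pair — but thermodynamic
re-folding of per-sequence structures is out of scope; pre-computed
structures can be supplied instead.

## Problem sizes used by the test suite

The suite validates every solver against independent brute-force oracles:
exhaustive enumeration of all structures up to length 8 ($\theta = 0$; 323
structures at $n = 8$) for the median solvers, exhaustive assignment
enumeration and a complete-universe Sankoff program for small parsimony,
subset enumeration for edit-distance mappings (trees with at most 6 internal
nodes), and exhaustive interval-set enumeration for the independent-set
subroutine.  Distance identities are checked on 500 random pairs at
$n = 60$; uniformity of the sampler by a $\chi^2$ test on $10^4$ draws at
$m = 8$; and the simulated experiment runs 20 replicates at $H = 5$,
$N = 100$, asserting the observed resolution ordering (the unconstrained RF
reconstruction leaves deep ancestors nearly empty while the ILC-constrained
methods retain base pairs at the root — the constraint, not the metric, is
the deciding factor).

## Known limitations

* Pseudoknots are a parse error throughout; crossing consensus annotations
  are rejected rather than repaired.
* No indel model: all inputs must share one length, and gapped alignments
  lose every gapped column.
* RE medians, exact IL/RE small parsimony, and IL medians under DLC are
  open problems and deliberately absent; the command-line tool refuses those
  combinations with exit status 2.
* Branch lengths are ignored; every edge counts equally.
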