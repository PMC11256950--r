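# RNAparsimony

Maximum-parsimony reconstruction of ancestral RNA secondary structures.

Within a non-coding RNA family, secondary structure is typically more
conserved than sequence, so the evolution of a family (or of a clan of
related families) is naturally studied at the level of structures.  Given a
set of gap-free aligned secondary structures — and optionally a phylogeny
whose leaves carry them — this package solves two problems:

* the **median problem**: find one structure minimising the sum of distances
  to the inputs, `Mcost(T) = Σᵢ D(Tᵢ, T)`;
* the **small parsimony problem**: assign a structure to every internal node
  of the phylogeny minimising the summed distance over edges,
  `SPcost = Σ₍ᵤ,ᵥ₎∈E D(Tᵤ, Tᵥ)`.

Structures of common length *n* are represented as ordered rooted trees:
leaves are the positions `[0, n+1]` (two fictive flanking positions), and
internal nodes are the base pairs plus a fictive root pair `(0, n+1)`.  On
these trees the package implements three distances:

* `rfDistance` / `bpDistance` — the Robinson–Foulds distance on descendant
  leafsets, which on RNA trees equals the base-pair distance |P₁ Δ P₂|;
* `ilDistance` — the Internal-Leafset distance, comparing the collections of
  *loops* (leaf-children sets) instead of individual pairs;
* `treeEditDistance` / `reDistance` — the ordered tree edit distance under a
  pluggable rename cost; the relaxed cost `|i₁−i₂| + |j₁−j₂|` lets
  imperfectly aligned pairs be matched.

Median solvers (`rfMedian`, `ilIlcMedian`, `ilNcMedian`, `rfIlcMedian`) are
exact polynomial algorithms: majority-rule consensus for Robinson–Foulds,
and dynamic programming over *structural partitions* (partitions of
`[0, n+1]` into non-conflicting loops) for the Internal-Leafset distance,
with a maximum-weight-independent-set subroutine on interval graphs
(`mwisIntervals`) in the unconstrained case.  Small parsimony solvers are
`fitchHartiganRF` (exact under Robinson–Foulds, via per-leafset
Fitch–Hartigan reconstruction), `restrictedAssignment` (Sankoff restricted
to leaf trees; the only solver available for the relaxed edit distance), and
`medianLocalSearch` (median-based hill climbing).  Constraint regimes NC /
DLC / ILC restrict the output's descendant or internal leafsets to those of
the inputs.

The package also provides Stockholm/WUSS and Newick readers, the gap-column
projection producing equal-length structures (`projectGapless`,
`perSequenceStructure`), an exact uniform sampler of secondary structures
with a minimum hairpin size (`countStructures`, `sampleStructure`,
`randomInstance`), and a command-line tool (`exec/rnaparsimony`) with
subcommands `distance`, `median`, `smallparsimony`, `simulate` and
`preprocess`.

## Worked example

```r
library(RNAparsimony)

trees <- lapply(c("((...))", "((...))", "(.....)"), parseDotBracket)

med <- rfMedian(trees)
med$median
#> RNATree on leafset [0, 8] with 3 internal node(s)
#>   ((...))
med$cost
#> [1] 1

ilIlcMedian(trees)$cost
#> [1] 3
```

The majority-rule median keeps both base pairs (each occurs in at least two
of the three inputs) and pays a single pair difference to the third
structure, for an optimal `Mcost` of 1; under the Internal-Leafset distance
the same structure is optimal with `Mcost` 3 (its two loops each differ from
the loop set of the third input, which contributes one more mismatched
loop).

On a phylogeny:

```r
phy <- readNewickPhylogeny(text = "((A,B),(C,D));")
lt <- list(A = parseDotBracket("((...))"), B = parseDotBracket("((...))"),
           C = parseDotBracket("(.....)"), D = parseDotBracket("(.....)"))
fh <- fitchHartiganRF(phy, lt)
fh
#> SPAssignment under RF: 3 ancestral tree(s), SP cost 1
vapply(ancestralTrees(fh), writeDotBracket, character(1))
#>         6         7         5
#> "((...))" "(.....)" "(.....)"
```

The two cherries reconstruct their leaf structures exactly; the inner pair
is present/absent in a tie at the root, which resolves to absence, and the
single change is charged to the edge into the `(A,B)` ancestor.  The list
names are the internal node numbers of the `ape::phylo` object (node 5 is
the root).

The same machinery from the shell:

```sh
exec/rnaparsimony simulate --height 5 --length 100 --theta 3 --seed 7 \
    --out-structures leaves.db --out-newick tree.nwk
exec/rnaparsimony smallparsimony -i leaves.db -t tree.nwk \
    --metric il --constraint ilc --solver local-search --out-table anc.tsv
```

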