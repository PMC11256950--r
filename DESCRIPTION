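Package: RNAparsimony
Title: Median and Small Parsimony Reconstruction of Ancestral RNA
    Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents gap-free aligned RNA secondary structures as
    leaf-labeled ordered trees and reconstructs ancestral structures by
    maximum parsimony. Implements three tree distances (the base-pair /
    Robinson-Foulds distance, the Internal-Leafset distance comparing
    loops, and a relaxed tree edit distance), exact polynomial median
    solvers (majority-rule consensus for Robinson-Foulds, dynamic
    programming over structural partitions for the Internal-Leafset
    distance, with and without the input-leafset constraint), exact
    Fitch-Hartigan small parsimony under the Robinson-Foulds distance,
    Sankoff-style restricted assignment, and a median-based local-search
    heuristic. Includes Stockholm/WUSS and Newick readers, the
    gap-column projection used to obtain equal-length structures, and an
    exact uniform sampler of secondary structures for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RNAparsimony-package.R'
    'dotbracket.R'
    'trees.R'
    'distances.R'
    'io.R'
    'medians.R'
    'parsimony.R'
    'simulate.R'
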