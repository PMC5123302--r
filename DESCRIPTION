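Package: multires
Title: Ancestral Gene-Order Reconstruction with Duplications Guided by
    Synteny-Level Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the gene order of an ancestral genome in the
    presence of gene duplications, guided by a synteny-block-level
    ancestral reconstruction (contiguous ancestral regions, CARs).
    Gene families are partitioned into localizations using windows on
    the CARs, parsimoniously conserved gene adjacencies are weighted by
    their phylogenetic conservation pattern, and a maximum-weight
    degree-constrained adjacency selection is solved independently on
    overlapping CAR segments before a consensus traversal produces a
    linear order of gene-level fragments along each CAR.  Includes a
    genome-evolution simulator (inversions, duplications, insertions,
    deletions along a species tree) and an evaluator reporting
    adjacency true/false positive rates, common-interval recovery,
    gene content and fragmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
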