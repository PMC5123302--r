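---
title: "Reconstructing ancestral gene orders with duplications: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral gene orders with duplications: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multires)
```

## The problem

Given extant gene orders for a set of descendant species, a rooted binary
species tree with a marked internal node, and a synteny-block-level
reconstruction of that ancestor (a set of *contiguous ancestral regions*,
CARs — signed sequences of synteny blocks produced by tools such as ANGES
or MGRA and consumed here as input), `multires` reconstructs the *gene
order* of the ancestor while allowing gene families to have several
ancestral copies.

Duplications are what make this hard: when a family occurs several times,
an adjacency observed next to "the family" in one species and a different
adjacency in another species may belong to different ancestral copies.
The key idea is to use the coarse synteny-level reconstruction to split
each family into *localizations* — subfamilies tied to distinct
neighbourhoods of the ancestral block order — and to solve a
maximum-weight adjacency selection locally on overlapping stretches of
the CARs, so that copies far apart on the ancestor never compete.

## Representation

Genes and synteny blocks are *doubled*: a gene with positive orientation
becomes the marker pair (tail, head), a negative gene (head, tail), and a
chromosome of $n$ genes a sequence of $2n$ markers with markers $2k-1,
2k$ paired.  Adjacencies are unordered pairs of markers of *consecutive
genes*; tandem duplications legitimately produce adjacencies between the
head and tail of the same family.  Block extremities define *regions*:
either the two ends of one block, or the facing ends of two neighbouring
blocks (a gap).  A CAR of $k$ blocks is a sequence of $2k$ extremities,
equivalently $2k-1$ regions.  Coordinates are 0-based half-open
internally; the gene-order TSV dialect on disk is 1-based inclusive and
the block dialect is BED-like.

An adjacency $\{x, y\}$ is *parsimoniously conserved* if two species
exhibit it whose tree path passes through the marked ancestor.  Each
conserved adjacency gets a weight from its conservation pattern; two
schemes are provided:

* **pair-count** (default): the number of distinct straddling species
  pairs supporting the adjacency divided by the total number of
  straddling leaf pairs — a conservation breadth in $(0, 1]$;
* **branch-decay**: $\max \exp(-d)$ over supporting pairs, $d$ the
  patristic distance — emphasising support from closely related pairs.

The weights only need to be comparable within one run; the optimizer is
scheme-agnostic.  Both are deliberately simple, documented
approximations: the conservation-weight literature offers several
variants and the method's behaviour does not hinge on the choice.

Ancestral copy numbers $\mu$ are inferred per family by exact integer
small parsimony (Sankoff recursion with cost $|\Delta| \times$ branch
length, ties towards the smaller count), computed at the marked ancestor
by message passing on the unrooted view of the tree.  Families with
$\mu = 0$ are dropped, and families with $\mu > 15$ (configurable cap,
strict inequality) are discarded as unreliable homology calls.

## Stage 1: extant containments

For every species the tracked extremities are the ends of its block
occurrences (a block on the minus strand exposes its head at its genomic
start), and every pair of *consecutive* extremities bounds an extant
region occurrence with loci $l_a < l_b$.  A gene occurrence with marker
loci $x, y$ and length $\ell = |y - x|$ is contained in the region if it
lies entirely inside, or if it straddles one boundary with at least
$\ell / 2$ of its length inside.  Two numerical guards apply:

* the straddle conditions additionally require positive overlap with the
  region interior, so the zero-length gap between two abutting blocks
  contains nothing;
* a gene overlapping two flanking regions by exactly $\ell/2$ each is
  assigned to the leftmost region only, making the assignment unique in
  the tie case (and symmetric under coordinate reflection up to this
  documented convention).

## Stage 2: localizations

A *window* of length $\ell_w$ (in extremities; default 25) slides at
stride 1 along each CAR.  A window qualifies for family $g$ when it spans
regions $r, r'$ (possibly equal) containing $g$ in two species whose path
crosses the ancestor, with $r, r'$ spanned by no other selected window.
The defining property admits many window subsets; we select one by a
deterministic greedy left-to-right scan that accepts a window whenever
its supporting regions are unclaimed, which favours leftmost windows and
is order-stable.  Each selected window becomes one localization; the map
$\psi$ assigns each region where the family is observed to exactly one
localization (its spanning window, else the nearest selected window on
the same CAR), keeping $\psi$ sets disjoint within a family.  Families
with no qualifying window keep a single localization carrying all their
regions.

Conserved marker adjacencies are then re-attached: every extant adjacency
instance maps its two gene occurrences to localizations through the
containing regions, species evidence is re-collected per localized edge,
and edges without straddling support are dropped.  Localization copy
numbers start from small parsimony restricted to the occurrences
supporting that localization, then a two-step heuristic reconciles them
with the family total: localizations with no incident adjacency are
deleted first, then the largest copy number is decremented until the sum
matches (ties: the localization whose leftmost region lies rightmost on
the CAR loses, biasing copies toward earlier, better-supported windows).
When restriction leaves the sum short, the smallest is incremented
symmetrically — the family total is authoritative in both directions.  A
family whose localizations are all deleted is dropped with a warning.

## Stage 3: per-segment optimization

*Segments* of $L$ extremities (default 65; $L \ge \ell_w$ required) slide
along each CAR at stride $\lfloor L/2 \rfloor$ with the last segment
anchored at the CAR end.  The stride is a design choice: the literature
behind this decomposition states that segments overlap but not by how
much, and half-length strides guarantee every interior region is covered
by at least two segments, which the consensus weighting needs to be
informative.  Each segment induces the subgraph on
$V' = \bigcup \psi^{-1}([b_i, b_{i+1}])$ over its regions.

On each induced subgraph we select a maximum-weight set of adjacencies
such that each marker end (head and tail separately) of localization $v$
is incident to at most $\mu(v)$ selected adjacencies — a maximum-weight
b-matching on the marker-end graph, matching the intuition that a gene
copy has exactly two ends.  The solver is exact: connected components
without any capacity conflict are taken whole, and conflicted components
are solved by branch-and-bound over edges in decreasing weight order with
a suffix-sum bound.  Among equal-weight optima the solution preferring
lexicographically earlier edge identifiers is returned, so results are
independent of input order and of positive weight scaling.  Full
linear/circular realizability beyond degree feasibility is *not* enforced
here; degenerate cycles are instead broken by the consensus traversal,
and the segment decomposition itself keeps large circular structures from
forming.

## Stage 4: consensus

Per-segment solutions are merged: each adjacency kept anywhere receives
$w_{gt} = P/T$ with $P$ the number of segments keeping it and $T$ the
number of segments whose vertex set contained both endpoints.  The merged
graph is pruned greedily — while any marker end exceeds its copy number,
delete the lowest-$w_{gt}$ incident edge (ties: remove the
lexicographically larger edge key) — considering only edges incident to a
violating end, never others.

Localizations are ranked by the leftmost CAR position of their $\psi$
regions (then rightmost span, then key).  The traversal starts at the
highest-ranked localization with remaining copies, follows unique
neighbours, picks the highest-ranked neighbour with unused copies at
branch points, and on rank ties closes the current path and builds each
tied branch as its own path, appending them in order of the rank of their
ending vertices.  A copy is consumed on every arrival, so a closing edge
back into an exhausted localization is simply never traversed — emitted
paths are acyclic by construction, which realises the "delete the last
edge of a cycle" rule without a separate check.  Localizations never
placed on any path are emitted as singleton fragments (one per remaining
copy), so inferred ancestral content is preserved even where no adjacency
evidence orders it; paths from different CARs are never concatenated.
Marker-level paths collapse back to signed family sequences
(tail-before-head is $+$).

## The simulator

`sim_genomes()` evolves a root genome along the species tree (default:
ten mammals with the primate–rodent ancestor marked, unit branch
lengths).  The root has 730 genes in 630 families (the excess are
pre-existing duplicates) grouped into 150 contiguous blocks — the scale
of a mammalian X chromosome data set.  Per branch, event counts are
Poisson(rate × length): inversions (geometric length, mean 5 genes),
duplications (mean 2; 40% tandem), insertions of novel singleton
families, and deletions (mean 2).  Two presets are provided and fixed:
**low** (inversion 3, duplication 1.2, insertion 0.6, deletion 0.6 per
unit branch) and **high** (three times each).  They produce mean pairwise
ingroup breakpoint counts of roughly 40 and 110 on the 730-gene genome —
a mildly and a heavily rearranged history bracketing what gene-order
comparisons of mammalian X chromosomes typically show.
`calibrate_rates()` exposes the underlying bisection should a user want
to target a different breakpoint regime.

Choices worth knowing about:

* duplicated copies do not inherit the block tag of their source — a
  duplicated segment is not part of the syntenic occurrence of its block
  — which preserves the at-most-one-occurrence-per-species block
  invariant; a duplication covering every remaining gene of a block is
  resampled;
* block occurrences at each node are recomputed from gene memberships as
  the largest maximal run of genes sharing the tag (untagged genes do not
  break runs); orientation comes from the within-block positions of the
  run's genes;
* CARs are emitted from the *true* ancestral block order (optionally
  split into fragments to mimic an imperfect synteny-level
  reconstruction), removing any dependence on an external reconstruction
  tool while letting users substitute real tool output;
* leaf genomes are laid out with fixed 1 kb genes and 100 bp gaps, so
  containment at the leaves is exact.

The last two points matter for interpreting accuracy: the generator hands
the pipeline *noise-free* synteny input — exact CARs, complete and exact
block homology, clean containments.  Real applications have none of
these luxuries (synteny-level reconstructions are imperfect, blocks come
from whole-genome alignment, genes straddle block boundaries), and
published experience with this family of methods shows that most
reconstruction loss comes precisely from such input imperfections.
Passing accuracy checks on this simulator therefore demonstrates the
correctness of the combinatorial machinery under the stated conditions,
not field performance on alignment-derived data.  Adjacency recovery
here is accordingly higher than what should be expected in practice, and
at these accuracy levels short-interval recovery sits slightly *below*
adjacency recovery (fragmentation costs intervals more than it costs
adjacencies); on noisy inputs with substantially lower adjacency
recovery the relation inverts, since intervals are robust to local order
errors.

## Evaluation

`evaluate_reconstruction()` scores fragments against the true ancestor:
adjacency TP/FP/FN on family-level marker-pair *multisets* (min-matching,
so repeated adjacencies are neither over- nor under-credited; TP rate is
TP over the truth count, FP rate is FP over the reconstruction count),
gene content as a family-copy multiset intersection, fragment counts, and
common-interval recovery — for each $k \ge 3$, the fraction of the
truth's $k$-gene windows whose family multiset occurs as a consecutive
window anywhere in the reconstruction, never spanning fragment
boundaries.  The interval check is a deliberate brute-force sliding
enumeration (the definition *is* the algorithm); the output table indexes
intervals both by genes ($k$) and by markers ($2k$), since either
convention appears in practice.

## Problem sizes used by the test suite

The shipped tests pin the optimizer and the copy-number parsimony against
exhaustive brute-force oracles (500 random graphs of up to 12 edges with
copies up to 3; random leaf-count vectors on 4-, 10- and 12-leaf trees),
check the conservation and feasibility invariants on 100 simulated
replicates of a 40-gene genome, and run the two presets at full scale
(730 genes, 10 replicates each with the default window 25 / segment 65)
— the same computation `scripts/acceptance.R` performs.  The small
replicate scale keeps the property battery exhaustive-checkable; nothing
in the method depends on genome size beyond runtime.

## Known limitations

* Realizability of the selected adjacency set as linear/circular
  chromosomes is only enforced through per-end degree bounds plus
  traversal-time cycle avoidance, not through the full combinatorial
  characterization.
* Localization is greedy and never revisited after optimization; a poor
  early window choice cannot be repaired downstream.
* The weight schemes ignore adjacency *absence* evidence and treat all
  straddling pairs alike (pair-count) or only the closest pair
  (branch-decay).
* The simulator has no translocations or fissions beyond what inversion
  composition yields on one chromosome, no sequence evolution, and no
  model of block-boundary noise — see the interpretation note above.
* Gap-filling between fragments and re-insertion of pruned edges are out
  of scope; fragments are only ordered along their CAR.
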