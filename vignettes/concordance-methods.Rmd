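---
title: "Backbone concordance, threshold consensus and motif conservation: methods"
author: "concord package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone concordance, threshold consensus and motif conservation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
```

This vignette records the models, conventions and design choices behind
the package, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open decisions were made.

## The backbone concordance model

Early cyanobacterial evolution is summarized here as an ordered ladder
of lineages — by default Gloeobacterales (GLOEO), then Thermostichales
(THERMO), then the higher crown (HIGHER), with an optional OUTGROUP
label. A rooted tree is concordant with the ladder when, for every
suffix of the order past the first lineage, the union of the remaining
lineages is monophyletic. Two conventions matter:

* **The earliest lineage may be a grade.** Only unions of *later*
  lineages must be clades. A root falling inside a paraphyletic
  Gloeobacterales grade is therefore concordant, which matches how
  basal grades are interpreted in rooted single-gene trees.
* **AMBIGUOUS and OUTGROUP taxa are removed first** and listed in the
  report rather than counted for or against any constraint. This
  mirrors the practice of refusing to assign taxa (such as
  *Synechococcus* sp. PCC 7336) whose placement is genuinely unstable
  across analyses: an unassignable taxon should not be allowed to
  break a constraint it was never confidently inside.

Constraints whose taxon union is empty, or spans every retained leaf,
are flagged *inapplicable* rather than failed — with heavily incomplete
MAG panels this happens routinely and is information, not error.

Rooting scenarios are specified as a taxon bipartition ("the root lies
between X and everything else") and are resolved to an edge **only when
the bipartition is exactly an edge of the tree**. Approximate matching
is refused by design: silently snapping a near-miss bipartition onto a
nearby edge would fabricate concordance results. An inapplicable
scenario is reported as such — that a proposed root placement is
incompatible with a tree is itself a finding. The root subdivides the
chosen edge at half its length; the position is irrelevant to every
topological test in the package but keeps path lengths sensible.

`enumerate_concordant_rootings()` systematizes two-scenario comparisons
by brute force: every edge of the unrooted topology (pendant edges
included) is tried and checked. Edges are identified by a canonical
split key — the leaf set on the side *not* containing the
lexicographically smallest leaf, sorted and space-joined — which gives
a stable, implementation-independent edge naming across rerootings.

## Threshold meta-consensus across incomplete gene trees

Single-protein trees rarely share a complete taxon set; the consensus
machinery therefore works on *per-clade agreement fractions* rather
than split counts over a fixed leaf set. For a candidate clade and one
gene tree:

* the tree is **evaluable** when it contains at least two clade members
  and at least one outside leaf — the weakest condition under which
  monophyly is non-vacuous. This rule is a deliberate, configurable
  stance: with a single member present, any position is consistent
  with monophyly and counting such trees would inflate support;
* the tree **supports** the clade when the members present are
  monophyletic (projection onto the tree's taxa).

`fraction = n_supporting / n_evaluable`. Candidate clades are all
internal-node leaf sets appearing in any gene tree. They are ranked by
fraction (descending), number of evaluable trees (descending), clade
size (descending), then lexicographically — a fixed, documented order
so that ties resolve reproducibly — and accepted greedily when
compatible (nested or disjoint) with everything already accepted.
Clades below fraction 0.5 are never placed; accepted clades in
[0.5, threshold) are drawn dashed; at or above the display threshold
(default 0.70, boundary inclusive, i.e. 7 of 10 evaluable trees is
solid) they are drawn solid. Because one gene may contribute several
trees (isoform pairs), each tree is counted separately in
`n_evaluable`. Candidates evaluable in fewer than `min_evaluable`
trees are flagged `insufficient_data` and left out of the topology —
the analogue of reporting alternative topologies when two assemblies
overlap in only six proteins.

With equal taxon sets and threshold 0.5 this reduces exactly to
majority-rule consensus (the test suite asserts it against a
brute-force split counter), and raising the threshold can only demote
solid edges, never create them.

## Ortholog/paralog discrimination from identity breadth

The classifier encodes a qualitative pattern: orthologs of a
single-domain protein keep close relatives across a broad panel of
assemblies, while paralogs born by ancient duplication and accelerated
divergence have close relatives in few. Identities come from global
Needleman–Wunsch alignment under BLOSUM62 with affine gaps (open 11,
extend 1), computed over aligned residue-pair columns only. Global
rather than local alignment is a documented divergence from BLAST-style
identities: the homologs of interest are single-domain, full-length
proteins, and full-length identity is the quantity the breadth argument
actually needs. One best hit per assembly; no HSP tiling.

The numeric defaults — close relative at ≥ 30 % identity, ortholog-like
at breadth ≥ 0.6, paralog-like below 0.2, hit coverage ≥ 0.5 — are
configurable and echoed in every classification, because the underlying
qualitative reasoning ("a pattern similar to that of a known paralog")
has no canonical cutoffs. The monotonicity property (raising the
identity threshold can only lower breadth) is asserted in tests.

## Motif conservation scoring

Motif positions are defined in ungapped 1-based coordinates of a
reference sequence and mapped through the alignment (column c maps
position p when the reference has exactly p non-gap characters in
columns 1..c). The default specification scores the four informative
residues of the LxNxLR bilin-binding motif — the two `x` wildcards are
not scored — with per-position conservative sets (Ile/Val/Met for each
Leu, Asp for Asn, nothing for Arg) rather than a global similarity
matrix, because the biological statement being encoded is per-residue.
Whether Lys should count as conservative for Arg is left to user
configuration; the default follows the strict reading (no substitute).

Three conventions worth making explicit:

* **Gap and X score as `missing`, not `nonconservative`** — absence of
  data is not evidence of motif loss, and partial MAG-derived
  sequences would otherwise be miscounted as degraded. Consequently
  the headline "lacks ≥ 2 of 4" predicate counts only
  `nonconservative` positions.
* **Flags are independent of status.** Ser at the Asn position is
  nonconservative *and* flagged `ser_substituted`, because a serine
  there may be a functional state in its own right (a candidate
  adaptation to binding a different bilin) and must remain visible in
  summaries rather than disappearing into a generic "lost" count.
* Statuses are invariant to inserting all-gap columns (asserted as a
  property test).

## Supermatrix construction

`build_presence_matrix()` screens a length-filtered reference protein
set (default ≥ 128 aa, the conventional floor for length-stable
ribosomal proteins) against each assembly. A homolog is *detected*
when its global-alignment identity reaches `detect_identity` (default
30 %); a detected homolog is *complete* when it covers ≥ 90 % of the
**reference** length, else *partial*. Coverage is measured against the
reference deliberately: measured against the shorter sequence, a
half-length fragment would count as fully covered and completeness
would be meaningless. "Complete" as a 0.9 coverage fraction is an
operationalization of an otherwise informal notion and is
configurable.

Catenation plans are built around *required* assemblies: the plan's
proteins are those complete in every required assembly, ordered
greedily so that each step keeps as many further assemblies complete
as possible (ties: longer reference protein, then name). This greedy
objective is an explicit stand-in for manual two-catenation designs
built around poorly overlapping assemblies; the protein order is
user-overridable, since published catenations fix an explicit order.
Partition tables always tile `1..total` with no gaps or overlaps and
are emitted in RAxML-style `PROT, name = start-end` lines.

## The synthetic-data generator

The generator emulates the statistical structure of a genome/MAG panel
without reproducing any real dataset: a ladder species tree
`(outgroup,(GLOEO,(THERMO,HIGHER)))` with random within-clade labelled
histories and log-normal branch lengths (default meanlog log 0.1,
sdlog 0.5 substitutions/site — typical single-protein divergences for
a phylum-level panel); per-gene NNI topology noise; at most one HGT
event per gene, modelled as pruning a leaf of the recipient lineage
and regrafting it strictly inside the donor clade (recorded in the
truth table); duplication; i.i.d. per-(gene, taxon) missingness
emulating incomplete MAGs (default clade sizes 4/4/6 plus 2 outgroup
taxa, 10 genes, matching the scale of a 10-protein meta-analysis
panel). Everything is a pure function of the configuration and its
mandatory seed; regeneration is byte-identical.

**Duplication is modelled as ancient.** The copied cherry's branch
lengths are multiplied by the paralog rate multiplier (default 3), and
its stem is extended so that the copy's mean depth below the graft
point equals the multiplier times the host clade's mean depth there —
the paralog lineage has evolved at the accelerated rate for the whole
time since the duplication, not merely along the short history of the
copied cherry. Without this the paralogs would sit at ortholog-like
distances from the panel and the ortholog/paralog contrast the
generator exists to produce would vanish.

**Sequences evolve under the 20-state Poisson model** (equal exchange
rates and frequencies, scaled to mean rate 1): along a branch of
length *t* a site changes with probability (19/20)(1 − e^(−20t/19)),
uniformly to one of the other 19 residues; optional gamma site rates.
The model was chosen over an empirical matrix because nothing
downstream depends on realistic exchangeabilities, while the closed
form gives an analytic oracle for the simulator (observed divergence
of a two-taxon tree is checked against it within 3 standard errors at
10 kb). Motif sites are frozen at L, N, L, R on ortholog lineages; at
the paralog stem, a configured number (default 2, minimum 2) of the
four positions is switched to a residue outside the
identity-plus-conservative set and thereafter evolves within the
nonconservative residues only, so degraded positions cannot revert and
the generator's "lacks ≥ 2 of 4" guarantee is exact. Indels are not
simulated: alignments are true by construction, since alignment
inference is out of scope.

What passing tests on this generator do **not** show: robustness to
alignment error, to rate heterogeneity across lineages (only across
sites), to multiple transfers per gene, or to incomplete lineage
sorting — the generator's discordance sources are HGT and duplication
only, and its missingness is taxon-uniform rather than clustered by
assembly quality.

## Numerical and interface conventions

* Newick dialect: quoted labels accepted; square-bracket comments
  discarded; fully numeric internal labels are supports, normalized to
  [0, 1] on read (values above 1 divided by 100, covering both support
  conventions); other labels are node names. Duplicate leaves,
  unbalanced parentheses and negative branch lengths are parse errors
  naming the offending token. Zero-length and missing branch lengths
  are both allowed and kept distinct.
* Polytomies are first-class throughout; the consensus output is
  generally non-binary.
* Sequences are 1-based in ungapped reference numbering; alignment
  columns 1-based.
* Chronology windows are reported in My from dates in Gya, rounded at
  10⁻⁶ My to remove floating-point dust (the input dates carry 0.1 Gya
  resolution); a window in which acquisition postdates divergence is
  an error with an explanatory message, not a negative number.
* Fragmentary sequence trimming is left upstream: the package treats
  alignments and trees as given.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
data at deliberately modest sizes — 8–12-leaf trees for the
brute-force rooting comparisons (200 replicates), 8-leaf 5-tree sets
for the majority-rule comparison (100 replicates), 100-gene panels for
HGT detection, 10 kb two-taxon alignments for the saturation check —
sizes at which the brute-force oracles are exact and fast while still
exercising every code path. Nothing in the implementation is specific
to these scales.
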