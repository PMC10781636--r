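---
title: "Methods: reconstructing a gene family's birth-and-death history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing a gene family's birth-and-death history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefambd)
```

This vignette explains the models and procedures behind `genefambd`, the
choices that were genuinely open when the package was designed, and what the
simulation-based tests do and do not demonstrate. The running example is the
vertebrate taste receptor type 1 (T1R/TAS1R) family encoded in
`tas1r_fixture()`: a 21-taxon species tree with approximate node ages, an
11-clade family topology, and a species-by-clade state matrix in
{absent, intact, pseudogene}.

## Ortholog clades by species overlap

A rooted gene tree node is labelled a **duplication** when the species sets
of at least two of its children intersect, otherwise a **speciation**
(`label_duplications()`). The rule is purely topological: it needs no branch
lengths and no sequence data, and on polytomies it is applied to every pair
of children, which is the conservative reading (any overlapping pair is
evidence for a duplication).

**Clades are components, not subtrees.** `extract_clades()` cuts the gene
tree at every duplication node that *splits* at the requested level and
returns the connected components. The component view matters: when a
duplication is nested inside the family, the lineage that persists around it
(the "rest" of the parent clade) is spread over several subtrees of the gene
tree but is still a single ortholog clade. An early subtree-based
implementation fragmented exactly those lineages; the component definition
repaired it without changing any fixture result.

Which duplications split is controlled by a user-supplied taxon-group map
(species → group, e.g. "Chondrichthyes", "Amphibia"):

* duplications confined to a single **species** never split — they are
  within-species copies (the two zebrafish TAS1R2B genes stay one clade);
* at level `"clade"`, duplications confined to one **taxon group** do not
  split either (the three TAS1R6 subclades stay one clade);
* at level `"subclade"` they do, which is how TAS1R6-1/-2/-3 and the two
  amphibian TAS1R3B groups are separated.

The group map is a deliberate design decision: named subclades in this
domain are always described *within* a taxon group, so the group map is the
natural, explicit way to say which duplications are subclade-forming. The
fixture keeps the duplicated coelacanth TAS1R2A copies as within-species
copies, since nothing in the study system treats them as subclades.

## Dollo parsimony and LCA reconciliation

Both reconstructions assume **single origin**: a clade (or an adjacency) is
gained exactly once and can only be lost afterwards. That is the right
prior for characters whose parallel gain is essentially impossible, such as
a specific gene duplication or a specific gene neighbourhood.

`dollo_reconstruct()` uses the presence matrix alone. Each clade originates
at the MRCA of its carrier species; the clade is then present exactly on the
spanning subtree connecting the origin to the carriers, and a loss is
charged on every branch leaving that subtree. This placement is provably
minimal among single-origin histories (any history is a connected set
containing origin and carriers; the spanning subtree is the smallest such
set), and it is the rootward-most of all equal-cost placements, making the
output deterministic on polytomies. The test-suite confirms minimality
against exhaustive enumeration of all single-origin histories on small
trees (1,000 random instances on trees of up to 6 leaves, an enumeration of
at most 2^5 internal-state vectors per instance).

`reconcile()` additionally uses the family (clade) tree. Every clade-tree
node is mapped to the species-tree LCA of its descendant carriers; a node
is a **duplication** when the mappings of two children are comparable (one
an ancestor of the other, including equality), since incomparable mappings
are explained by speciation alone. A clade's origin is then the mapping of
its nearest ancestral duplication — never tipward of the matrix-only Dollo
origin, and typically rootward of it. Sister clades born of one duplication
originate on the same species branch (their order along the branch follows
the clade-tree topology and carries no time information). Losses below each
origin are placed exactly as in the matrix-only case. Pseudogene cells count
as carriers for origin placement — a pseudogene is evidence that the lineage
was present — and are reported as pseudogenization events on the terminal
branch of the carrier. Copy numbers above one within a species are ignored
by reconstruction and reported as within-species copies.

On the fixture this machinery reproduces, from the matrix and the clade
topology alone, the family's published history: five lineages in the
jawed-vertebrate ancestor, nine in the bony-vertebrate ancestor, TAS1R8
lost on the tetrapod stem, TAS1R3B and TAS1R5 on the amniote stem, TAS1R4
and TAS1R7 on the mammalian stem (the test-suite asserts each of these).

Degenerate and edge inputs: a clade with no carriers is an error (it cannot
be placed); unary clade-tree nodes are passed through; on a polytomic
speciation whose species children are not all covered by gene lineages the
uncovered children receive a loss of the ancestral lineage.

## Ancestral adjacencies and order assembly

An adjacency is an unordered pair of neighbouring gene symbols; strand and
orientation are ignored because neighbourhood data of this kind rarely
report orientation consistently across assemblies. The family cluster can be
collapsed to a single token (`collapse_family = TRUE`) so that flanking
adjacencies (e.g. DVL1–cluster–MXRA8) are comparable across species whose
internal cluster content differs. Each adjacency is reconstructed as a
single-gain Dollo character — chosen over Fitch parsimony because the
analysis reasons from conserved ancestral blocks, and configurable only in
the sense that the un-collapsed and collapsed analyses can both be run.

`assemble_order()` turns the adjacency set at a node into linear orders:
symbols are vertices, adjacencies edges; vertices of degree > 2 are reported
as conflicts and each of their incident edges starts its own path; paths are
oriented and sorted lexicographically so the output is independent of input
order; cycles are broken at their smallest symbol and flagged. Conflicts are
data, not errors — they are how a genuine disagreement between species
orders surfaces.

## Upstream windows and motifs

Windows cover the `L` bases (default 300, the window size used to survey
the family's upstream regions) immediately 5' of the start codon on the
coding strand, reverse-complemented for minus-strand genes, truncated at
scaffold edges and never padded. Offsets are reported relative to the A of
the start codon, so the last window base is −1 and a hit at offset *o* with
width *w* satisfies *o* + *w* ≤ 0.

`scan_word()` matches an IUPAC word (default ATGCAAAT, the canonical
Oct-family site) on both strands by default; the strand convention is
configurable because upstream alignments are usually displayed on the coding
strand only. Conservation is called when at least `min_species` species have
a hit inside a positional band (default the whole window); the MRCA of the
supporting species is reported as the spanning clade. De novo motif
discovery is deliberately out of scope — the module consumes a word or a
PWM.

PWMs use probabilities `(count + pc) / (N + 4 pc)` with pseudocount
`pc = 0.5` (half a count per base, the standard Laplace-style choice that
keeps single-site matrices non-degenerate). `compare_pwm()` scores the best
ungapped alignment over all offsets and both strands by the mean
column-wise Pearson correlation, requiring ≥ 6 overlapping columns; the
score is symmetric and invariant to reverse-complementing either input.
Zero-variance columns (possible at pseudocount 0) compare as 1 when
numerically identical and 0 otherwise. Since reference matrices from
curated databases cannot be redistributed here, the package builds a
synthetic Oct-like reference PWM from ATGCAAAT-centred sites in code where
one is needed.

## Assay statistics

The response of a well is the trapezoidal integral of the
baseline-subtracted luminescence curve from stimulus onset to the last
sample, in RLU; the baseline is the pre-onset mean, the value is signed
(negative excursions are informative and not floored), and the integral is
invariant to affine shifts of the time axis.

The positive-response rule is strict on both arms: mean AUC **> 10,000 RLU**
and BH-adjusted **q < 0.01** from a one-sided t-test against the buffer
control. Three design decisions sit behind `call_responders()`:

* the **independent experiment** is the unit of replication — duplicate
  wells are averaged per experiment before testing, which prevents
  pseudo-replication (the fixture plate follows the six-experiments ×
  duplicate-wells structure of the study);
* the t-test is **Welch** (unequal variances), the cautious reading of an
  unspecified "one-sided t-test";
* the **BH family** is all ligand rows of one receptor pair within one
  experiment set, with the buffer control taken per pair. The family
  definition is not dictated by the rule itself, so it is documented here
  and kept configurable through the table layout.

Rows with fewer than two experiments are flagged untestable rather than
silently dropped. Enrichment of essential amino acids among responders is
the hypergeometric upper tail (one-sided Fisher test); for the study margins
(6 of 6 responders essential, 9 essential among 17 tested) the exact value
is C(9,6)/C(17,6) = 84/12376 ≈ 0.0068. Dose–response curves are fitted by
Levenberg–Marquardt least squares on the three-parameter Hill equation with
positivity bounds; non-convergence is reported in the return value, never
raised, and flat data short-circuit to Rmax = 0.

## The simulators: what they emulate, and what they do not

`simulate_family()` runs a continuous-time duplication–loss (Gillespie)
process for gene copies along the dated species tree. Default rates are
λ = 5·10⁻⁴ duplications and μ = 10⁻⁴ losses per gene lineage per Ma, i.e.
roughly two to three duplications and under one loss per family across the
~5,100 Ma of total branch length of the fixture tree — the "handful of
events over half a billion years" regime in which a family like this one
evolves, and the regime in which parsimony reconstruction is consistent.
Duplications on internal branches split the current clade into two new
clades (cutting the genealogy at duplications is exactly the clade
definition); duplications on terminal branches create within-species copies;
when one daughter of a duplication leaves no descendants the survivor is
merged back into the parent clade, because that duplication is invisible to
any observer of modern genomes ("hidden" events, counted in the returned
truth). Concurrent duplications of one parent clade on parallel branches are
linearised into the genealogy in traversal order — a simplification that is
immaterial at the default rates. Node ages follow the fixture's anchor
intervals (the family's origin window on the jawed-vertebrate stem and the
bony-vertebrate stem dates); other ages are round interpolations and are
part of the fixture definition, not estimates.

At the default rates, the full inference chain (overlap labelling → clade
cutting → collapsed clade tree → LCA reconciliation) recovers ≥ 95% of true
origin branches over 500 seeded replicates; the residual misses are
dominated by root-founded clades whose carriers happen to vanish from one
side of the root, after which no parsimony method can see the true origin —
an inherent identifiability limit, not an implementation artefact.
Replaying reconstructed events from the root reproduces every simulated
matrix exactly.

`simulate_upstream()` plants a word into i.i.d. background sequence at a
given GC content (default 0.42, a typical vertebrate promoter-region
value); `simulate_assay()` draws well AUCs as Gaussians with σ = 5,000 RLU
and a responder shift of Δ = 30,000 RLU, matching the magnitudes of the
assay the rule was designed for; at n = 6 experiments this gives essentially
unit power, so recovering planted responders exactly is the expected
behaviour, and the interesting test is false-discovery control on null
plates.

What passing these tests shows: the algorithms implement their definitions
correctly and the statistical rules control what they claim to control
under the generating models. What it does not show: robustness to
real-data pathologies the generators deliberately omit — assembly gaps and
mis-annotation in the presence matrix, alignment error upstream of motif
scanning, non-Gaussian plate artefacts, or gene conversion and transfer,
which violate the single-origin assumption outright.

## Numerical choices and problem sizes

All randomised components take explicit seeds and restore the RNG state.
Test-suite problem sizes were chosen so that each property is exercised well
past its small-sample regime while the whole suite stays interactive:
1,000 read/write round-trips, 1,000 exhaustive Dollo comparisons, 500
simulation replicates for origin recovery, 100 null plates of 120 ligand
rows for FDR control, and 10,000 windows for the background hit rate of the
scanner (expected rate 2·(L−7)·4⁻⁸ per window at GC 0.5). Ties everywhere
are broken deterministically (rootward loss placement, lexicographic path
orientation, species-then-offset hit ordering), so every pipeline output is
byte-reproducible for a given configuration.

## Known limitations

* Losses between a reconciled origin and the first surviving carrier branch
  are inferred, but losses *above* the carriers' MRCA for root-founded
  clades are invisible (see above).
* The clade tree is taken as given (or collapsed from the gene tree); no
  attempt is made to resolve clade-tree topology from the matrix, and the
  relative order of origins that the data leave open (e.g. the branching
  order of the two single-lineage clades near the family root) is reported
  as given, not resolved.
* Adjacency reconstruction treats each adjacency independently; it does not
  enforce global consistency (that is what the conflict report in
  `assemble_order()` surfaces) and does not model rearrangement distances.
* The responder rule tests each ligand row against the control of its own
  receptor pair; cross-plate normalisation is out of scope.
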