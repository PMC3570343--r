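---
title: "Methods: phylogenomic analysis of fold-superfamily censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenomic analysis of fold-superfamily censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domcensus)
```

## The data and the model

The unit of observation is the *genomic abundance* `g` of a protein fold
superfamily (FSF, a SCOP level grouping fold families with structural and
functional evidence of common origin) in a proteome: how many domains of
that FSF the proteome encodes. A census is a proteomes-by-FSFs matrix of
non-negative integer counts, assembled from domain assignment tables keyed
by SCOP concise classification strings (`c.37.1` = class c, fold 37,
superfamily 1). Fold-family-level strings are truncated to FSF level and
summed; FSFs observed nowhere are pruned, and the retained width is the `N`
used by every downstream statistic.

Abundance carries phylogenetic signal under two assumptions. Old FSFs have
had more time to duplicate and spread, so abundance grows with age; and
proteomes accumulate domains over time, so richer state is derived. Both are
encoded in the character model: counts are compressed to 24 ordered states

    state = round( ln(g + 1) / ln(g_max + 1) * 23 )

with `g_max` the single largest count in the matrix, written with the
alphanumeric alphabet 0–9, A–N. Changing between states i and j costs
|i − j| steps (linearly ordered, Wagner, characters). Two orientations of
the same census are analysed:

* **ToD** (tree of domains): FSFs are taxa, proteomes are characters, and
  the ancestral state is declared to be N (23) — the most abundant
  condition is oldest.
* **ToP** (tree of proteomes): the transposed matrix, ancestral state 0 —
  the primordial proteome was simplest.

`round` is round-half-up (`floor(x + 0.5)`); natural logarithms are used;
`g_max` is global to the matrix, not per character. These three choices fix
every downstream step count exactly and are deliberately documented because
the alternatives (half-even rounding, per-character maxima) produce
different trees on ties.

## Parsimony engine

Tree length is computed by Sankoff dynamic programming with linear costs.
Cost vectors over the 24 states are propagated tip-to-root; because the
cost is |i − j|, the min-plus convolution at each edge reduces to a forward
and a backward running-minimum pass, and all characters are scored in one
vectorized sweep. Internal states are confined to 0–23.

Search is random-addition-sequence stepwise insertion followed by
best-improvement branch swapping (NNI, or SPR which subsumes it). Insertion
points are evaluated in O(1) per edge from precomputed "subtree" and
"rest-of-tree" cost vectors. All randomness derives from the single seed in
`search_config()`; ties (equal-length insertions, equally good swaps) break
toward the first candidate in a fixed traversal order, so runs are exactly
reproducible. All equally parsimonious topologies found are retained up to
`max_trees_held`; downstream age tables are computed on the first tree,
with a cross-tree standard deviation reported as a stability diagnostic
when several optima exist.

Rooting uses the outgroup-free Lundberg method: a hypothetical ancestor
bearing the declared ancestral state at every character is attached to the
edge minimizing total length, and the tree is rooted at that attachment.
The rooted length therefore includes any changes required on the ancestor
edge and can exceed the unrooted length. Ties across edges are flagged.

Per-character fit is summarized by the consistency and retention indices:
`m` is the state range (minimum conceivable steps), `g*` the optimum on a
completely unresolved star tree (maximum conceivable steps, minimized over
an integer center — attained at the state median), `s` the steps realized
on the tree; `ci = m/s`, `ri = (g* − s)/(g* − m)`, with ensemble versions
built from the summed quantities. `s` is computed without the root-state
constraint so that `m ≤ s ≤ g*` and `ri ∈ [0, 1]` hold identically;
parsimony-uninformative characters (`g* = m`) are flagged and excluded from
`ri`. Tree-length distribution skewness `g1` over uniformly sampled random
topologies (the standardized third central moment) is available as a signal
diagnostic; strongly structured data give `g1 < 0`.

Bootstrap support resamples characters with replacement, reruns a reduced
search per replicate (fewer addition sequences, NNI only), and annotates
the majority-rule consensus with bipartition frequencies. Replicate split
sets are returned so any support value can be recounted.

## Timeline

The relative age of an FSF is its node distance `nd` on the rooted ToD: the
number of internal nodes between root and leaf, rescaled so the shallowest
leaf has `nd = 0` (origin) and the deepest `nd = 1` (present). Whether the
root itself is counted is immaterial after rescaling. Depth-degenerate
trees (all leaves equal) are flagged rather than scaled.

`f_vs_nd()` joins ages with the distribution index `f` (the fraction of
proteomes in scope harboring the FSF) and summarizes the scatter by binned
medians (10 equal-width nd bins by default). The nd at the binned minimum
is reported as the empirical phase boundary; it is always computed, never
assumed, since it is a property of each data set.

## Enrichment

Taxonomic groups are the 15 non-empty subsets of {A, B, E, V} (Archaea,
Bacteria, Eukarya, viruses), canonically ordered A < B < E < V; an FSF
belongs to the group spelled by the supergroups in which it occurs. The
enrichment of group-with-letter versus group-without-letter (ABEV vs ABE,
BV vs B, ...) is tested with the hypergeometric distribution: `k` FSFs of
the with-letter category among the sample supergroup's `n` FSFs, against
`M` background FSFs out of `N` retained. Direction is over-representation
when `k/n > M/N`. Reported P-values are one-sided *cumulative* tails
(P(X ≥ k) or P(X ≤ k)), computed exactly in log space; the point mass
P(X = k) is exposed separately. Cumulative tails are the reported
statistic because the published comparisons they reproduce are tail
probabilities, not point masses. No multiple-testing correction is applied
to match the reference analysis; a Bonferroni column is trivial to add from
the returned table.

## Split networks

Presence/absence occurrence matrices are compared with uncorrected-P
distances (fraction of differing columns). NeighborNet agglomeration
produces a circular taxon ordering: components hold at most two active
nodes, pairs of components are chosen by the neighbor-joining criterion on
component-averaged distances, endpoints by the adjusted criterion, and
3-node chains are reduced to 2 with the standard 2/3–1/3 distance
update; reductions are expanded in reverse to yield the cycle. Ties break
toward the smallest node index, so the ordering is deterministic in the
input order (several rotations/reflections of one split system are equally
valid, so permutation invariance is asserted on the recovered splits, not
on the literal ordering). Weights for all interval splits of the circle are
estimated by non-negative least squares against the observed distances and
pruned below `epsilon = 1e-9`. For additive (tree) distances whose splits
are compatible with the circular order this recovers exactly the tree's
splits with weights equal to branch lengths — the identity used as the
module's acceptance check. Bootstrap supports come from column resampling
with full re-estimation per replicate.

## The synthetic proteome-evolution generator

No public accession reproduces the study data (the census rests on a
SUPERFAMILY database snapshot), so the package ships a generator whose
output has the statistical structure the analysis assumes, with recoverable
ground truth. Its mechanisms:

* A known organismal tree: a ladder backbone on which the viral clade
  diverges first, then Archaea, then Bacteria and Eukarya; each supergroup
  radiates as a random ultrametric clade of `n_per_group` tips at the end
  of a stem. Stems are stretched so all radiations start at the same epoch
  and all tips sit at the same depth. This global ultrametricity is
  deliberate: with unequal root-to-tip paths, shared characters act as a
  path-length clock that attracts shallow tips of different clades to one
  another, a distortion of the census signal rather than a feature of it.
* A pre-divergence trunk epoch (`trunk_length`) along which the root
  repertoire arises sequentially: an essential immune core (`n_core`,
  oldest, never lost) and a primordial cohort (`n_primordial`, lossable).
  Root abundances follow the same exponential growth law as later
  duplication, so age is encoded in the root genome.
* Along every branch: originations (Poisson in branch length; every
  internal branch gets at least `min_internal_originations` so the
  generating topology is identifiable from the census), per-copy binomial
  duplication (expected exponential growth; stochastic per FSF, which is
  what makes abundance a heritable per-character signal rather than a
  single clock), and lineage-wise loss. Innovation slows once a lineage is
  clade-restricted (`clade_orig_factor`) and clusters toward the
  diversification end of stems.
* Reductive evolution: on the stems of the V and A clades the *inherited*
  repertoire (FSFs born outside the clade, minus the immune core) is lost
  at `reductive_multiplier` times the base rate — massive early loss,
  matching the biology the census method was built to detect. Clade-native
  FSFs are never penalized.
* Optional horizontal transfer copies an FSF column (with its count) from
  an already-simulated lineage; the default is zero so that every
  occurrence pattern is a connected subtree of the truth.

Every event is logged, and `replay_events()` reconstructs the emitted
census cell-for-cell from the log — the generator's own correctness oracle.

Two named study conditions are used throughout the tests:

* the **recovery benchmark** — the `sim_config()` defaults: 4 clades × 10
  proteomes, strong origination signal, near-zero background loss, no HGT.
  Here the inferred ToP matches the generating tree exactly
  (Robinson–Foulds 0) and node distance rank-correlates with true birth
  order at ρ ≥ 0.8 across seeds.
* the **erosive regime** — the same configuration with background
  `loss_rate` raised to 0.15. Here the timeline reproduces the
  qualitative published patterns: the f-versus-nd curve falls from f ≈ 1,
  bottoms out at an interior minimum, and recovers toward the present;
  the ABEV group is the most ancient by median nd; and reductive lineages
  carry visibly fewer distinct FSFs than eukaryotes.

What the generator does *not* emulate: unequal supergroup sampling (the
reference census is bacteria-heavy; clades here are balanced), sequence- or
structure-level assignment error, proteome-size covariates, and any direct
clade-versus-clade exchange of ancient repertoire. Passing tests therefore
certify the pipeline's inferential machinery under the model's own
assumptions, not the field accuracy of domain assignment.

A caveat the simulations make visible: node distance orders the *shared*
repertoire well, but clade-specific FSF blocks attach to the tree of
domains through their low-abundance (young) ends, so the depth order inside
such a block runs young-to-old. This geometry — supergroup-wide FSFs at
maximal depth — is also what produces the rising tail of the f-vs-nd curve,
and it bounds how far nd can agree with true birth order when most FSFs are
clade-restricted. The recovery benchmark keeps the clade-native share near
half for this reason.

## Numerical choices

* Rounding in the state formula: half-up; documented above.
* Scoring uses a large finite constant rather than IEEE infinity for
  impossible leaf states, keeping all arithmetic exact for integer step
  counts.
* Tie-breaks everywhere (insertion edges, swaps, Lundberg edges,
  NeighborNet selections) are "first in a fixed deterministic order", and
  every stochastic step consumes a caller-supplied seed.
* NNLS: Lawson–Hanson via `pracma::lsqnonneg`; split weights below 1e-9
  are treated as zero.
* `g1` skewness uses the standardized third central moment
  `m3 / m2^{3/2}`; constant length distributions return NaN with a
  degeneracy flag.
* Hypergeometric tails sum term-by-term in log space with a max-shift, so
  populations of 10^3–10^4 neither overflow nor underflow.

## Problem sizes in the test suite

The suite validates the engines on instances where independent oracles are
exact: brute-force state enumeration and exhaustive topology enumeration up
to 6 taxa (200 random instances), Fitch equivalence for binary characters,
an 8-taxon tree-metric identity for NeighborNet, and full end-to-end
recovery at the 40-proteome reference conditions above (about a hundred
FSFs; a few minutes of CPU). These sizes were chosen so each check has an
exact expected answer; the engines themselves have no hard size limits, and
the pipeline scales to censuses of a few hundred taxa in minutes.

## Limitations

* Maximum parsimony only; no likelihood or Bayesian alternative, no
  PAUP*-style ratchet searches. Search optimality is guaranteed only where
  exhaustively verified (≤ 6 taxa); larger searches are heuristic.
* The NEXUS reader handles the package's own dialect (DATA + ASSUMPTIONS
  with an ordered 24-symbol alphabet), not arbitrary NEXUS files.
* `nd` is a topological age proxy; no calibration to absolute time is
  attempted.
* The Vogel-style FSF-to-function mapping is user-supplied; the package
  bundles only the major/minor category skeleton for validation.
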