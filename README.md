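# domcensus

Phylogenomics from censuses of protein fold superfamilies (FSFs).

Comparative genomics at the protein-domain level asks how the repertoires
of SCOP fold superfamilies — domains grouped by structural and functional
evidence of common origin — evolved across Archaea (A), Bacteria (B),
Eukarya (E) and large DNA viruses (V). The raw observable is *genomic
abundance*: how many times each FSF occurs in each proteome. `domcensus`
implements the full analysis stack on such censuses:

* **Census building** from assignment tables keyed by SCOP concise
  classification strings (`c.37.1`), with fold-family collapse, pruning of
  unobserved FSFs, distribution indices *f* (fraction of proteomes carrying
  an FSF), reuse ratios, and the 15-way taxonomic-group partition of
  {A,B,E,V}.
* **Ordered character coding**: abundances `g` are mapped to 24 states by
  `round(ln(g+1)/ln(g_max+1) * 23)` (alphabet 0–9, A–N) and treated as
  linearly ordered Wagner characters, cost |i−j| per step.
* **Tree reconstruction**: Sankoff dynamic programming with linear costs,
  random-addition-sequence search with NNI/SPR swapping, outgroup-free
  Lundberg rooting against a declared ancestral state (23 for trees of
  domains, 0 for trees of proteomes), character bootstrap, consistency and
  retention indices (ensemble and per character), and tree-length skewness
  g1.
* **Timelines**: node distance *nd* ∈ [0,1] as a relative domain age, the
  f-versus-nd curve with its empirical minimum-f phase boundary, and
  group-age summaries.
* **Enrichment**: exact one-sided cumulative hypergeometric tails for
  with-letter versus without-letter taxonomic groups
  (P(X ≥ k) or P(X ≤ k) with margins k, n, M, N), computed in log space.
* **Split networks**: uncorrected-P distances, NeighborNet circular
  ordering, non-negative least-squares split weights, split bootstrap.
* **A proteome-evolution simulator** with known ground truth (origination,
  duplication, lineage-wise loss, reductive clades, optional HGT) and a
  recovery report (Robinson–Foulds distance, nd-vs-birth-order rank
  correlation), so the entire pipeline is testable without any database
  download.

## Worked example

Simulate a small census with known history, fit a tree of proteomes, and
age the domains on a tree of domains:

```r
library(domcensus)

sim    <- simulate_census(sim_config(n_per_group = 4, n_core = 6,
                                     n_primordial = 10, seed = 7))
census <- sim$census
census
#> FSF abundance census: 16 proteomes x 46 FSFs
#> supergroups: A=4 B=4 E=4 V=4

fit <- fsf_tree(census, "ToP", search_config(n_addition_sequences = 2, seed = 1))
fit
#> Rooted Wagner parsimony tree (ToP): 16 taxa, 46 characters
#>   length: 459 steps unrooted, 699 rooted (ancestral state 0)
#>   ensemble CI = 0.8845, RI = 0.9533; 1 optimal topology

tod  <- fsf_tree(census, "ToD", search_config(n_addition_sequences = 1,
                                              swap = "NNI", seed = 2))
ages <- domain_ages(tod)
head(group_age_summary(ages, assign_groups(census)), 4)
#>   category  n min_nd median_nd max_nd
#> 1     ABEV 13   0.00      0.24   0.52
#> 2      BEV  1   0.32      0.32   0.32
#> 3      ABE  4   0.40      0.50   0.56
#> 4       BE  6   0.48      0.58   0.64
```

The 459 unrooted steps are the minimum total state changes over all
characters; the rooted length includes the changes on the hypothetical
ancestor's edge. Ensemble CI/RI near 1 say the census fits the tree with
little homoplasy (expected here: the simulation ran with almost no loss).
In the group-age table, the FSFs shared by all four supergroups (ABEV) are
the most ancient — median *nd* 0.24 — recovering the simulated history, in
which the shared repertoire predates the supergroup radiations.

Enrichment works directly from census margins; for example, an
over-representation tail for k = 229 of n = 304 sampled FSFs against a
background of M = 557 in N = 1739:

```r
hypergeom_tail(229, 304, 557, 1739, "over")
#> [1] 1.03785e-66
```

`run_census_pipeline(census, "out/")` runs census → coding → both trees →
timeline → enrichment → split network end-to-end and writes TSV/Newick/
NEXUS/JSON artifacts plus a manifest whose every number is re-derivable
from the emitted files.

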