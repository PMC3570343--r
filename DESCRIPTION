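Package: domcensus
Title: Phylogenomic Census of Protein Domain Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of protein fold superfamily (FSF)
    repertoires. Builds proteome-by-FSF abundance censuses from SCOP concise
    classification string assignments, encodes them as 24-state linearly
    ordered phylogenetic characters, reconstructs rooted trees of domains and
    trees of proteomes under Wagner parsimony with Lundberg rooting, derives
    relative domain ages (node distances) and distribution-index timelines,
    tests taxonomic-group enrichment with exact hypergeometric tails, builds
    NeighborNet split networks from presence/absence data, annotates domains
    with molecular-function categories, and simulates proteome evolution with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
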