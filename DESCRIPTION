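Package: micasm
Title: Community Assembly and Micropollutant Removal Analysis for
    Serial-Transfer Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse serial-transfer microcosm experiments in
    which aquatic microbial communities are repeatedly exposed to trace
    micropollutants. Implements phylogenetic and taxonomic null-model
    partitioning of community assembly processes (abundance-weighted
    beta-mean nearest taxon distance, beta-nearest taxon index,
    Raup-Crick with Bray-Curtis), dissimilarity-overlap analysis with
    root Jensen-Shannon divergence, 16S rRNA gene copy-number weighted
    community traits with contiguity-constrained growth-phase
    clustering, differential-abundance ecological grouping of taxa
    (sensitive, opportunistic, tolerant), and micropollutant removal
    statistics. A bundled stochastic serial-transfer simulator provides
    ground-truthed synthetic experiments for validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
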