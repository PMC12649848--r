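Package: endotalk
Title: Embryo-Endometrium Ligand-Receptor Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying molecular crosstalk
    between a day-5 embryo (blastocyst) and the secretory-phase endometrium.
    Implements dual-criterion expressed-gene filtering, subcellular-localization
    compartmenting of receptors, secreted ligands and decoy soluble factors,
    assembly of a bipartite receptor-ligand network from confidence-scored
    physical interactions, two-group differential expression with fold-change
    and FDR gates, a gene-set-permutation GSEA engine, hypergeometric
    over-representation with a log10 observed/expected strength statistic,
    reference-correlation two-stage single-cell immune typing with per-sample
    proportions and pseudobulk aggregation, and overlay of perturbed genes onto
    the network with modulated-receptor summaries. All inputs can be emulated
    by seeded synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
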