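Package: teflux
Title: Flux-Balance Analysis of Somatic Retrotransposon Insertions in
    Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based analysis of how somatic retrotransposon
    (TE) insertions perturb metabolism. Loads genome-scale metabolic
    models from SBML, evaluates gene-protein-reaction rules to separate
    isozyme-buffered from effective genes, applies a fold-reduction
    flux knockdown to the reactions an insertion-hit gene catalyses,
    and uses flux variability and flux balance analysis to find the
    metabolites whose maximal biosynthesis rate falls. An L1
    endonuclease target-site (TTAAAA) scanner and a Monte Carlo
    redistribution of insertions across target sites provide an
    empirical null for testing whether affected metabolites are
    enriched for disease associations. A synthetic-data generator
    produces toy networks, sequences with planted target sites,
    multi-donor insertion tables and disease maps with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
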