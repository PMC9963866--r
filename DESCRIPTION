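Package: crossiso
Title: Reproductive Isolation Components, Gene Action and Genetic Distance
    from Diallel Crossing Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify interspecific reproductive barriers from diallel
    crossing experiments. Encodes pollination outcomes (pollen-tube scores,
    fruit and seed set, germination) into crossability indices, computes
    stage-wise reproductive-isolation indices standardized by self-pollination
    controls and their sequential absolute/relative contributions to total
    isolation, estimates degree of dominance (d/|a|) in F1 hybrids, builds
    SNP-based Nei (1972) genetic distances and bootstrapped neighbor-joining
    trees from filtered VCF genotypes, and tests isolation-distance association
    with Pearson and Mantel statistics. Includes a synthetic-data generator
    with known ground truth so the full pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
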