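Package: digenicRank
Title: Phenotype-Driven Prioritization of Digenic Variant Combinations in Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks digenic variant combinations extracted from a patient exome
    by fusing a per-combination pathogenicity score with a gene-pair
    disease-relevance score. The disease-relevance score is obtained by
    propagating phenotype (HPO) and gene-panel seeds through a heterogeneous
    knowledge graph with a random walk with restart, and the two scores are
    combined per exome via min-max scaling and rank fusion. Includes exome
    variant filtering, exhaustive digenic combination enumeration (at most two
    variants per gene), grouped cross-validation fold assignment, a spike-in
    benchmark generator with synthetic exomes and synthetic
    multiplex-heterogeneous graphs, and rank-based (top-K recovery) evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
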