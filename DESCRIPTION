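Package: foxomir
Title: miRNA Microarray, qPCR and Phenotype-Scoring Pipeline for the
    CD8+ T-Cell FOXO Memory Program
Version: 0.1.0
Authors@R:
    person("foxomir", "maintainers", email = "foxomir@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis chain linking smoking and nicotine exposure
    to a naive-memory CD8+ T-cell program: detection calling, background
    subtraction and QC of miRNA microarray intensities, cyclic loess
    normalization, empirical-Bayes moderated two-group differential
    expression, delta-delta-CT qPCR quantification with
    relative-quantity-to-median scaling, a median-threshold naive-memory
    phenotype score, the mRNA/miR ratio classifier with paired
    nicotine-response shift tests, exact small-sample nonparametric
    statistics, Ward/Spearman clustering, and seeded synthetic-cohort
    generators so the whole pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
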