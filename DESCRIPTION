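Package: phylopipe
Title: Supermatrix Construction, Marker Filtering, Recoding, and
    Compositional Diagnostics for Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building phylogenomic supermatrices from per-species
    protein sets and for diagnosing them: six-frame ORF extraction,
    redundancy collapse, two-step best-hit contamination screening with a
    positive-control false-positive estimate, reciprocal-best-hit
    orthogroup construction, strict-completeness and BUSCO-based marker set
    selection, progressive alignment with gap trimming, concatenation into
    partitioned matrices with distinct-pattern and gap statistics, gene-tree
    statistics with quartile-fence marker filters, low-support branch
    contraction, quartet-based species-tree estimation, Dayhoff 6-, 9-, and
    15-state amino-acid recoding, and across-taxa compositional
    heterogeneity z-scores against a taxon-homogeneous null.  A seeded
    synthetic-data generator with truth tables makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
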