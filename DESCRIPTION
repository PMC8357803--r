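Package: sigreverse
Title: Signature-Reversal Drug Repurposing from Imputed Disease Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Connectivity-map style drug repurposing for disease expression
    signatures imputed by transcriptome-wide association studies (TWAS).
    Collapses multi-tissue TWAS features to one feature per gene, builds
    top-N up/down query gene sets, scores them against a compound signature
    library with a weighted Kolmogorov-Smirnov connectivity statistic,
    normalizes scores within cell-line groups, assigns empirical p values
    from random-query nulls with false discovery rate control, and ranks
    candidate compounds for signature reversal by aggregating Kolmogorov-
    Smirnov, Spearman and Pearson dissimilarity ranks across nested gene-set
    sizes, with permutation significance from shuffled disease signatures.
    Also includes a prescription-record phenotyping algorithm for
    treatment-resistant depression (two or more qualifying antidepressant
    switches) with odds-ratio association tests, and synthetic-data
    generators with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
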