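Package: exfoliomics
Title: Stool Exfoliated-Cell Transcriptome Analysis Against Tissue Transcriptomes
Version: 0.1.0
Authors@R: person("Exfoliomics", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether the transcriptome of host cells exfoliated
    into stool (the "exfoliome") mirrors the small-intestinal mucosal
    transcriptome and discriminates drug-treated from control subjects.
    Implements abundance filtering, upper-quartile normalization,
    negative-binomial common-dispersion estimation and exact-test differential
    expression with Benjamini-Hochberg control, Bray-Curtis ordination with
    ANOSIM and non-metric multidimensional scaling, diagonal-covariance sparse
    canonical correlation analysis with soft-thresholding, binary search,
    deflation and leave-one-out tuning, single-feature linear discriminant
    ranking with bolstered resubstitution error, marker-panel scoring and
    pathway-concordance statistics, and a coupled three-source
    negative-binomial count simulator so the whole workflow is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
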