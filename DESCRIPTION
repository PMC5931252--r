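Package: ccmirnet
Title: Paired Tumor/Normal miRNA-mRNA Cell-Cycle Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for integrating paired carcinoma/normal
    RNA-seq and miRNA expression data with survival outcomes, centred on the
    cell-cycle pathway in colorectal cancer. Implements reads-per-million
    protein-coding-gene (RPMPCG) normalization and 75th-percentile miRNA
    scaling, paired negative-binomial differential expression with a
    protein-coding exposure offset, residual-bootstrap F tests for
    gene-miRNA association on subject-level differential profiles,
    permutation likelihood-ratio Cox survival analysis with hazard ratios
    per interquartile range, and 6/7/8-nt miRNA seed-match scanning of
    3' UTR sequences, plus a synthetic-data generator with planted effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    survival,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
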