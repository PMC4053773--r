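Package: mirti
Title: miRNA Target Interactions from AGO2 PAR-CLIP and Paired Tumor Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates biochemical identification of AGO2 binding sites from
    PAR-CLIP sequencing with patient-matched miRNA and mRNA expression profiles
    to prioritize miRNA-target interactions in tumor subtypes. Provides
    crosslink-centered-region site calling with dinucleotide-preserving shuffle
    k-mer enrichment, abundance-thresholded correlation-shift statistics, an
    elastic-net classifier for PAR-CLIP-like interactions, a permutation-based
    global test for gene-set association (linear, logistic, multinomial and Cox
    responses), equal-weight rank aggregation of miRNA activity and phenotype
    evidence, and Cox-based target prognostic signatures. A synthetic-data
    generator emulates every pipeline input with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    glmnet,
    survival,
    jsonlite,
    yaml,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
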