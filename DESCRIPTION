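Package: methet
Title: Inter-Metastatic Copy-Number Heterogeneity and Genomic Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies intra-patient inter-metastatic DNA copy-number
    heterogeneity and genomic complexity from SNP-array-like log R ratio
    (LRR) data, together with the downstream prognostic statistics.
    Provides exact penalized least-squares segmentation (single-sample and
    joint multi-sample piecewise constant fitting), atomic-segment
    construction across samples, Euclidean and proportion-of-genome
    heterogeneity scores, fraction-of-genome-altered complexity measures,
    copy-neutral LOH quantification, complete-linkage clustering with
    multiscale bootstrap cluster support, Kaplan-Meier/Cox survival
    analyses of genomic biomarkers, and a synthetic multi-deposit
    metastasis cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
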