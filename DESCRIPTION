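Package: epicval
Title: Computational Validation Toolkit for Infinium Methylation Array Manifests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational validation of Infinium DNA
    methylation arrays such as the MethylationEPIC v2.0 (900K) platform.
    Annotates array probes against gene models, CpG islands, chromatin-state
    segmentations and CTCF-binding tracks with 5'-to-3' prioritisation;
    compares probe manifests between array versions (shared, removed and
    added probes at row and unique-position level, per-chromosome and
    design-chemistry accounting, windowed probe density, transcript-coverage
    gains); computes QC filtering and replicate/FFPE concordance statistics
    on beta-value matrices; performs PCA, t-SNE, bootstrap Ward hierarchical
    clustering and dendrogram comparison; runs Fisher over-representation
    analysis with FDR control; and generates fully synthetic genomes,
    manifest pairs and beta matrices with machine-readable ground truth so
    the whole pipeline can be exercised without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    ape,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
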