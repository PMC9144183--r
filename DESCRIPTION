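Package: epitarget
Title: Promoter CpG-Island Filtering and Expression-Methylation Concordance
    for Epigenetic Target Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline that nominates epigenetically regulated
    therapeutic-target genes from a differentially-expressed-gene list.
    Promoters are extracted strand-aware from a genome, CpG islands are
    detected with a sliding-window scan under Gardiner-Garden-type criteria
    (GC content, observed/expected CpG ratio, minimum length), tumor-versus-
    normal methylation (beta values) and expression (TPM) direction calls are
    made with rank-based tests and Benjamini-Hochberg adjustment, and genes
    are classified by direction concordance into oncogene-like (upregulated,
    promoter hypomethylated) and tumor-suppressor-like (downregulated,
    promoter hypermethylated) candidates. Includes hypergeometric
    over-representation analysis against GMT gene sets and a synthetic-data
    generator with planted islands and planted group effects so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    fgsea,
    tibble,
    dplyr,
    readr,
    purrr,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
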