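Package: ampliclean
Title: Trimming, Filtering and Diversity Table Generation for 454-Style
    Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing of 454-style pyrosequencing amplicon reads for
    biodiversity surveys. Implements a seven-step trimming and quality
    filtering pipeline (adapter-B removal, ambiguity filtering, pooled
    low-frequency removal, barcode demultiplexing, length filtering,
    exact PCR primer clipping with a homopolymer boundary-offset error
    filter, and mean-quality filtering), frequency-annotated
    dereplication, taxonomy assignment against a reference collection
    with deepest-path and majority-rule tie-breaking, cross-sample
    overlap tables under a gap-excluded similarity, exporters for
    downstream rarefaction software, and a read simulator that emits
    multiplexed FASTA/qual data with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
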