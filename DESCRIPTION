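Package: hvrscan
Title: Locate Sequenced 16S rRNA Hypervariable Regions in Amplicon Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers which hypervariable regions (V1-V9) of the bacterial 16S
    rRNA gene were sequenced in amplicon (metabarcoding) samples whose
    technical metadata is missing or unreliable. Reads are quality-trimmed,
    paired mates are merged, and each processed sequence is aligned to a
    bundled 16S reference with a semi-global affine-gap aligner to obtain
    start and end positions on the E. coli coordinate system. Per-sample
    median alignment positions and per-region coverage drive the region
    calls, and a random-forest classifier on early-cycle quality-score
    statistics flags samples whose reads still carry primer sequences.
    Includes a ground-truth amplicon read simulator used for testing and
    for training the primer classifier, and writes a per-sample TSV report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    randomForest,
    Rcpp,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
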