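Package: nasdeconv
Title: Deconvolution of Pre-RNA Isoform Abundance from Nascent RNA
    Sequencing Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the abundances of overlapping pre-RNA isoforms
    from strand-specific nascent RNA-sequencing coverage (PRO-seq,
    GRO-seq) by constrained least squares on binned read counts, with
    optional machine-learning calls of active transcription start sites
    from bidirectional-transcription signatures, a metagene shape-profile
    correction of the design matrix, and masking of pause and termination
    peaks. Includes a read-count baseline, an archetype-resampling
    simulator of nascent RNA-seq data with known truth, a benchmarking
    harness, and a Shannon-entropy decomposition of isoform diversity
    into transcriptional and post-transcriptional components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
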