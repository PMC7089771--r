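Package: riboscr
Title: Stop-Codon Readthrough Quantification from Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide quantification of stop-codon readthrough from
    ribosome profiling (Ribo-seq) data. Selects a single transcript isoform
    per protein-coding gene, assigns ribosome-protected fragments to
    A-site nucleotide positions with read-length-specific offsets calibrated
    at start codons, builds per-transcript density tracks, and computes
    stop- and start-anchored metagene profiles, the Ribosome ReadThrough
    Score (RRTS), reading-frame and codon-occupancy summaries, the relative
    readthrough of 3'UTR termination codons, and stop-codon sequence-context
    statistics (RRTS-weighted positional tests with Benjamini-Hochberg
    correction and a one-hot ridge regression model). Includes a synthetic
    ribosome-profiling generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
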