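Package: riboRDI
Title: Ribosome Density Index and Processivity Analysis from Ribosome
    Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the ribosome density index (RDI), a per-transcript
    summary of ribosome processivity derived from per-codon
    ribosome-protected-fragment (RPF) densities, together with the
    supporting analysis pipeline: nucleotide-to-codon depth summation, TPM
    normalization, translated-mRNA filtering, codon adaptation index (CAI)
    analysis, length-normalized and per-codon metagene curves with
    bootstrap confidence intervals, per-region Mann-Whitney tests,
    Monte-Carlo subsampling empirical p-values, and generative simulators
    of ribosome drop-off and ribosome stalling used to characterize the
    metric and to produce fully synthetic test studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
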