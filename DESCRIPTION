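Package: crebox
Title: Genome-Wide Analysis of Catabolite Responsive Elements (cre Boxes)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of catabolite responsive
    elements (cre boxes), the 14-nt pseudo-palindromic operators bound by
    the carbon catabolite control regulator CcpA in Bacillus subtilis and
    related Gram-positive bacteria. Builds position frequency and log-odds
    weight matrices from aligned cre sequences, calls degenerate IUPAC
    consensus strings, scans both strands of a genome for motif occurrences
    above a calibrated score cutoff, attaches hits to operon first genes via
    a positional window around the start codon, classifies sites into
    high-affinity, low-affinity and activating classes from expression fold
    changes at three regulator-induction levels, computes palindromicity
    scores and per-position palindrome percentages, and summarises
    cre-to-TSS distances and DNA helical phasing. Includes a seeded
    synthetic-data generator that plants graded-affinity sites in a random
    genome together with matching expression tables for end-to-end
    parameter-recovery benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
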