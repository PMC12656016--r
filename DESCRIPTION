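Package: wboxscan
Title: W-Box Promoter Scanning and WRKY Target-Gene Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting WRKY transcription-factor target genes
    from plant promoter sequence. Extracts strand-aware 2000 bp upstream
    promoter regions from a genome (FASTA) and annotation (GFF3), scans
    both strands for the W-box core element TTGAC[C/T], builds 17 bp
    extended windows and ranks them by occurrence frequency, matches the
    top-ranked motifs against all promoters with a mismatch budget and a
    binomial expectation (E-value) filter, and assembles a candidate
    report gated on externally supplied interface-confidence (ipTM)
    scores. Also implements relative qPCR expression by the 2^-ddCt
    (Livak) method and a synthetic-data generator that emits genomes,
    annotations, planted W-box sites, ipTM tables and Ct tables with
    machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
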