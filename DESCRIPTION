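Package: islandscan
Title: Sort-Seq Analysis of Promoter Emergence in Motif-Dense Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sort-seq mutagenesis studies of promoter
    emergence and evolution in motif-dense bacterial "promoter island"
    sequences. Builds position weight matrices from aligned motif instances
    and scans both strands for sigma70 -10/-35 boxes, extended -10 (TGn)
    motifs, H-NS sites and UP-elements; turns per-bin sorting read counts
    into fluorescence scores and filtered, parent-mapped daughter tables;
    computes finite-sample-corrected mutual information footprints between
    nucleotide identity and fluorescence with pseudo-replicates and calls
    hotspots; performs sliding-window motif gain/loss association testing
    (Mann-Whitney U with Benjamini-Hochberg correction); estimates
    promoter-emergence statistics (P_new, sigmoid fits, k-mer and feature
    regressions, scrambling nulls, outlier calling); and simulates sort-seq
    datasets with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
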