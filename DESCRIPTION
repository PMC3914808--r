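Package: pairfuse
Title: Discordant Read-Pair Fusion Calling and Genomic Characterization of
    Flow-Sorted Tumor Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for whole-genome characterization of
    flow-sorted tumor samples, modeled on the genomics of
    well-differentiated liposarcoma. Implements sliding-window gene-fusion
    detection from discordant paired-end read pairs with germline
    blacklisting, coding-region restriction and a multi-partner
    prioritization filter; binary-segmentation copy-number calling from
    aCGH log2 ratios with fusion/amplicon breakpoint concordance; somatic
    SNV filtering (caller posterior threshold, normal-evidence
    subtraction, damaging-predictor selection); and DNA-content ploidy
    estimation from DAPI flow-cytometry histograms by peak-seeded Gaussian
    mixture fitting. Ships a full synthetic-data generator (toy genomes,
    implanted rearrangements with ground-truth junctions, read pairs,
    aCGH probes, variant tables, DNA histograms) and packaged validated
    fusion/SNV tables from a well-differentiated liposarcoma case.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
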