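Package: bsgbs
Title: Reduced-Representation Bisulfite Sequencing with De Novo Reference
    Reconstruction, Methylation and SNP Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for highly multiplexed, double-digest reduced-representation
    bisulfite sequencing (epiGBS-style libraries). Implements the full
    computational method: UMI-based PCR-clone removal, barcode expansion with
    control nucleotides for Watson/Crick strand annotation, demultiplexing with
    restriction-overhang validation, 3' adapter trimming, de novo reconstruction
    of unconverted reference loci from three-letter encoded reads, directional
    bisulfite alignment, per-cytosine methylation calling with CX reports and
    M-bias, double-masked diploid SNP calling with genotype likelihoods, and
    evaluation utilities (cluster-vs-truth statistics, precision-sensitivity
    curves with squash-ploidy, CpG destranding, coverage-filtered methylation
    correlation, Ward clustering). A synthetic library generator with exact
    ground truth, including in silico restriction digestion, makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
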