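Package: zfarray
Title: Diploid Genotyping and Analysis of Minisatellite Zinc-Finger
    Arrays from Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers diploid genotypes of the hypervariable PRDM9
    zinc-finger (ZF) minisatellite from barcoded long-read amplicon
    sequencing. Provides dual-barcode demultiplexing, flank-anchored
    extraction and 84-nt tiling of ZF arrays, frequency-rule length
    calling with consensus phasing of equal-length heterozygotes,
    two-character ZF and allele nomenclature, A-type/C-type allele
    classification by DNA-contact residues, population allele-frequency
    and heterozygosity summaries, trio and cross-platform concordance,
    a greedy template-switch engine (with an exact dynamic-programming
    oracle) that tests whether an allele can be derived from a pair of
    parental alleles, and a read simulator with PCR-slippage and
    sequencing-error models so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
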