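# Fixed sequences and dimensional constants of the PRDM9 ZF-array amplicon
# assay. The flanks and inner barcodes are the published assay sequences; the
# amplicon arithmetic is anchored on the GRCh38 reference allele (13 ZFs).

#' Length of one zinc-finger repeat unit in nucleotides
#' @export
ZF_UNIT_NT <- 84L

#' Length of one zinc-finger repeat unit in amino acids
#' @export
ZF_UNIT_AA <- 28L

# Amplicon layout around the ZF array (GRCh38 reference allele, 13 ZFs):
# 670 bp of upstream and 137 bp of downstream flanking sequence.
AMPLICON_FLANK5_NT <- 670L
AMPLICON_FLANK3_NT <- 137L

#' Expected amplicon length for an allele with a given number of ZFs
#'
#' The assay amplifies the ZF array plus 670 bp of upstream and 137 bp of
#' downstream flanking sequence; the array itself is 84 nt per finger.
#'
#' @param n_zf integer, number of 84-nt fingers in the allele.
#' @return named list with `array_nt` and `amplicon_nt`.
#' @examples
#' amplicon_length(13) # 1092-nt array, 1899-nt amplicon
#' @export
amplicon_length <- function(n_zf) {
  n_zf <- as.integer(n_zf)
  stopifnot(n_zf >= 1L)
  array_nt <- n_zf * ZF_UNIT_NT
  list(array_nt = array_nt,
       amplicon_nt = array_nt + AMPLICON_FLANK5_NT + AMPLICON_FLANK3_NT)
}

#' Sequence immediately 5' of the ZF array (252 nt)
#' @export
PRDM9_FLANK5 <- paste0(
  "CACAGCCGTAATGACAAAACCAAAGGTCAAGAGATCAAAGAAAGGTCCAAACTCTTGAATAAAAGG",
  "ACATGGCAGAGGGAGATTTCAAGGGCCTTTTCTAGCCCACCCAAAGGACAAATGGGGAGCTGTAGA",
  "GTGGGAAAAAGAATAATGGAAGAAGAGTCCAGAACAGGCCAGAAAGTGAATCCAGGGAACACAGGC",
  "AAATTATTTGTGGGGGTAGGAATCTCAAGAATTGCAAAAGTCAAGTATGGAGAG")

#' Sequence immediately 3' of the ZF array (252 nt)
#' @export
PRDM9_FLANK3 <- paste0(
  "GATGAGTAAGTCATTAGTAATAAAACCTCATCTCAATAGCCACAAAAAGACAAATGTGGTCACCAC",
  "ACACTTGCACACCCCAGCTGTGAGGTGGCTTCAGCGGAAGTCTGCTGACCCCTTATATTCCCCGAG",
  "AGTATAAAGAGATCGGAAATAACTGATTAAACAAATCCGCCACTTTCATGACTAGAGATGAGGAAG",
  "AACAAGGGATAGTTCTGTAAGTGTTCGGGGGACATCAGCATGTGTGGTTCTTTC")

#' The eight 12-nt inner barcodes of the dual-barcoding scheme
#' @export
INNER_BARCODES <- c(
  "ATCACGATCACG", "CGATGTCGATGT", "GATCAGGATCAG", "CTTGTACTTGTA",
  "ACAGTGACAGTG", "GCCAATGCCAAT", "CAGATCCAGATC", "ACTTGAACTTGA")

#' Number of outer barcodes in the second round of multiplexing
#' @export
N_OUTER_BARCODES <- 96L

#' Number of samples addressable by the dual-barcode scheme
#'
#' Eight inner primer barcodes crossed with the 96 outer PCR barcodes.
#'
#' @param n_inner,n_outer counts of inner and outer barcodes.
#' @return integer, `n_inner * n_outer`.
#' @examples
#' barcode_capacity() # 768
#' @export
barcode_capacity <- function(n_inner = length(INNER_BARCODES),
                             n_outer = N_OUTER_BARCODES) {
  as.integer(n_inner) * as.integer(n_outer)
}

#' Reverse-complement of DNA strings
#'
#' Plain-character implementation (kept off Biostrings for per-read speed);
#' agrees with [Biostrings::reverseComplement()] on the ACGTN alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s)))),
    character(1), USE.NAMES = FALSE)
}

# Translate an in-frame DNA string to amino acids (frame 0) via the standard
# genetic code; non-ACGT codons give "X".
translate_dna <- function(dna) {
  n <- nchar(dna)
  stopifnot(n %% 3L == 0L)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
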