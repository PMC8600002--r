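# A synthetic stand-in for the published human allele catalog.
#
# The real catalog of fingers and alleles is not redistributed here; this
# generator rebuilds a catalog with the same documented structure so that
# nomenclature, typing, statistics and template-switch analyses run
# end-to-end: allele A has 13 fingers (a 1,092-bp array); B differs from A
# by one nucleotide (one amino acid, off the contact residues); N is A with
# one finger deleted (a single template switch from A); C anchors the C-type
# cluster at 15 fingers; L4 is C with four fingers duplicated non-adjacently
# (a double template switch); L14 carries the intact C contact profile; 50
# alleles are A-lineage (length median 13) and 21 are C-lineage (median 15),
# with disjoint contact-residue vocabularies apart from the shared terminal
# fingers. All sequences are synthetic.

ref_codes <- function(n, prefix_letters = letters) {
  paste0(rep(prefix_letters, each = 26L)[seq_len(n)],
         rep(LETTERS, times = length(prefix_letters))[seq_len(n)])
}

distinct_triplets <- function(n, forbidden = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    t <- paste(sample(RESIDUE_POOL, 3L, replace = TRUE), collapse = "")
    if (!(t %in% out) && !(t %in% forbidden)) out <- c(out, t)
  }
  out
}

ref_finger_aa <- function(triplet) {
  aa <- SCAFFOLD_AA
  aa[SCAFFOLD_CONTACT] <- strsplit(triplet, "", fixed = TRUE)[[1]]
  aa[SCAFFOLD_VARIABLE] <- sample(RESIDUE_POOL, 3L, replace = TRUE)
  aa
}

# Derive a variant of base_codes with `target_len` fingers: delete interior
# fingers, duplicate interior blocks, and (sometimes) substitute a finger
# from the lineage pool; retried until the variant is new.
derive_variant <- function(base_codes, target_len, pool, existing_dna,
                           dna_of) {
  for (try in 1:50) {
    codes <- base_codes
    while (length(codes) > target_len)
      codes <- codes[-sample(2:(length(codes) - 1L), 1L)]
    while (length(codes) < target_len) {
      blk <- min(sample(1:2, 1L), target_len - length(codes))
      at <- sample(seq_len(length(codes) - blk + 1L), 1L)
      codes <- append(codes, codes[at:(at + blk - 1L)], after = at + blk - 1L)
    }
    if (runif(1) < 0.5 || identical(codes, base_codes)) {
      at <- sample(2:(length(codes) - 1L), 1L)
      codes[at] <- sample(pool, 1L)
    }
    dna <- dna_of(codes)
    if (!(dna %in% existing_dna)) return(codes)
  }
  stop("could not derive a fresh variant")
}

#' Synthetic reference catalog of A-type and C-type alleles
#'
#' Deterministically (given `seed`) rebuilds a 71-allele catalog with the
#' documented structure of the human repertoire (see source comments): use
#' it wherever the published allele catalog would be needed. All sequences
#' are synthetic; the planted lineage of each allele is recorded in
#' `type_label`.
#'
#' @param seed RNG seed (default fixed so every session sees one catalog).
#' @return a `zf_catalog` of 71 alleles.
#' @export
synthetic_reference_catalog <- function(seed = 711L) {
  set.seed(seed)
  tripA <- distinct_triplets(23L)
  tripC <- distinct_triplets(23L, forbidden = tripA)
  fingers <- list(); dnas <- character(0)
  add_finger <- function(code, aa, wobble = integer(0)) {
    dna <- finger_dna(aa, wobble)
    while (dna %in% dnas) {
      wobble <- sample(setdiff(seq_len(ZF_UNIT_AA), c(8L, 11L, 24L, 28L)),
                       sample(1:4, 1L))
      dna <- finger_dna(aa, wobble)
    }
    dnas <<- c(dnas, dna)
    fingers[[code]] <<- data.frame(code = code, dna = dna,
                                   stringsAsFactors = FALSE)
    code
  }
  codesA <- ref_codes(23L, letters[1:6])
  codesC <- ref_codes(23L, letters[7:12])
  # A's 13 fingers + 10 extra A-lineage fingers
  for (k in 1:23) {
    aa <- ref_finger_aa(tripA[k])
    if (k == 6L) aa[13L] <- "R"  # fixed so B's single-nt change is R->G
    add_finger(codesA[k], aa, wobble = sample(c(2L, 5L, 9L), sample(0:2, 1L)))
  }
  # C-lineage fingers; C shares its first and last finger with A
  for (k in 1:23)
    add_finger(codesC[k], ref_finger_aa(tripC[k]),
               wobble = sample(c(3L, 7L, 12L), sample(0:2, 1L)))
  A_codes <- codesA[1:13]
  C_codes <- c(codesA[1], codesC[1:13], codesA[13])
  poolA <- codesA[14:23]
  poolC <- codesC[14:23]
  # B: one nucleotide changed in A's sixth finger (R -> G at residue 13)
  a6 <- fingers[[codesA[6]]]$dna
  stopifnot(substr(a6, 37L, 39L) == CODON1[["R"]])
  b6_dna <- a6
  substr(b6_dna, 37L, 37L) <- "G"
  stopifnot(!(b6_dna %in% dnas))
  fingers[["bB"]] <- data.frame(code = "bB", dna = b6_dna,
                                stringsAsFactors = FALSE)
  dnas <- c(dnas, b6_dna)
  B_codes <- A_codes; B_codes[6] <- "bB"
  N_codes <- A_codes[-10]
  L4_codes <- C_codes[c(1:10, 5:8, 11:15)]
  # L14: same contact profile as C, different dna in finger 3
  aa3 <- ref_finger_aa(tripC[2])  # same triplet, fresh variable residues
  add_finger("nN", aa3)
  L14_codes <- C_codes; L14_codes[3] <- "nN"
  finger_df <- do.call(rbind, fingers)
  dna_of <- function(codes) {
    d <- setNames(finger_df$dna, finger_df$code)
    paste(d[codes], collapse = "")
  }
  alleles <- list(); allele_dnas <- character(0)
  push <- function(name, codes, provenance, type) {
    alleles[[name]] <<- data.frame(name = name,
                                   zf_codes = paste(codes, collapse = ","),
                                   provenance = provenance,
                                   type_label = type,
                                   stringsAsFactors = FALSE)
    allele_dnas <<- c(allele_dnas, dna_of(codes))
  }
  push("A", A_codes, "population", "A-type")
  push("B", B_codes, "population", "A-type")
  push("N", N_codes, "sperm", "A-type")
  push("C", C_codes, "population", "C-type")
  push("L4", L4_codes, "population", "C-type")
  push("L14", L14_codes, "population", "C-type")
  # remaining A-lineage alleles: 47 variants with overall length median 13
  lensA <- rep(c(11L, 12L, 13L, 14L, 15L, 16L), c(4L, 8L, 22L, 8L, 3L, 2L))
  namesA <- c("D", "L6", "L19", "L20", "L24", "Av:0024", "Av:0046",
              "Av:0053", "Av:0540", paste0("M", 1:38))
  provA <- c(rep("population", 5L), rep(c("blood", "sperm"), 2L),
             rep("novel", 38L))
  lensA <- sample(lensA)
  for (k in seq_along(lensA)) {
    codes <- derive_variant(A_codes, lensA[k], poolA, allele_dnas, dna_of)
    push(namesA[k], codes, provA[k], "A-type")
  }
  # remaining C-lineage alleles: 18 variants with overall length median 15
  lensC <- rep(c(13L, 14L, 15L, 16L, 17L, 18L), c(3L, 4L, 6L, 3L, 1L, 1L))
  namesC <- c("L7", "L11", "Cv:0283", paste0("M", 39:53))
  provC <- c("population", "population", "sperm", rep("novel", 15L))
  lensC <- sample(lensC)
  for (k in seq_along(lensC)) {
    codes <- derive_variant(C_codes, lensC[k], poolC, allele_dnas, dna_of)
    push(namesC[k], codes, provC[k], "C-type")
  }
  zf_catalog(finger_df, do.call(rbind, alleles))
}
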