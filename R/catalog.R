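# Catalog of zinc-finger units and named alleles.
#
# A ZF catalog holds the repertoire of 84-nt finger units (each with a
# two-character code) and the named alleles, each an ordered string of finger
# codes. An allele's DNA is always reconstructible as the concatenation of
# its member fingers.

ALLELE_PROVENANCES <- c("population", "sperm", "blood", "novel", "synthetic")
TYPE_LABELS <- c("A-type", "C-type", "untyped", "unclassified")

#' Construct one zinc-finger record
#'
#' @param code two-character finger identifier.
#' @param dna 84-nt DNA string over A/C/G/T whose frame-0 translation has no
#'   stop codon.
#' @param is_novel logical flag for fingers minted during encoding.
#' @param source free-text provenance.
#' @return one-row data.frame with columns code, dna, aa, is_novel, source.
#' @export
zinc_finger <- function(code, dna, is_novel = FALSE, source = NA_character_) {
  dna <- toupper(dna)
  if (nchar(dna) != ZF_UNIT_NT)
    stop("zinc finger '", code, "': dna length ", nchar(dna), ", expected ",
         ZF_UNIT_NT)
  if (grepl("[^ACGT]", dna))
    stop("zinc finger '", code, "': dna contains non-ACGT characters")
  aa <- translate_dna(dna)
  if (grepl("\\*", aa))
    stop("zinc finger '", code, "': translation contains a stop codon")
  data.frame(code = code, dna = dna, aa = aa, is_novel = is_novel,
             source = source, stringsAsFactors = FALSE)
}

#' Build a validated ZF catalog
#'
#' @param fingers data.frame with at least columns code, dna (one row per
#'   finger); aa/is_novel/source are filled in when absent.
#' @param alleles data.frame with columns name, zf_codes (comma-joined code
#'   string), and optionally provenance and type_label. The allele dna column
#'   is always rebuilt from the fingers.
#' @return object of class `zf_catalog`.
#' @export
zf_catalog <- function(fingers, alleles = NULL) {
  stopifnot(is.data.frame(fingers), all(c("code", "dna") %in% names(fingers)))
  fingers <- do.call(rbind, lapply(seq_len(nrow(fingers)), function(i) {
    zinc_finger(fingers$code[i], fingers$dna[i],
                is_novel = if ("is_novel" %in% names(fingers))
                  isTRUE(fingers$is_novel[i]) else FALSE,
                source = if ("source" %in% names(fingers))
                  as.character(fingers$source[i]) else NA_character_)
  }))
  if (anyDuplicated(fingers$code))
    stop("duplicate finger codes: ",
         paste(unique(fingers$code[duplicated(fingers$code)]), collapse = ", "))
  if (anyDuplicated(fingers$dna))
    stop("distinct finger codes share identical dna: ",
         paste(fingers$code[fingers$dna %in%
                              fingers$dna[duplicated(fingers$dna)]],
               collapse = ", "))
  if (is.null(alleles))
    alleles <- data.frame(name = character(), zf_codes = character(),
                          dna = character(), provenance = character(),
                          type_label = character(), stringsAsFactors = FALSE)
  else {
    stopifnot(is.data.frame(alleles),
              all(c("name", "zf_codes") %in% names(alleles)))
    if (anyDuplicated(alleles$name))
      stop("duplicate allele names")
    if (!("provenance" %in% names(alleles)))
      alleles$provenance <- "population"
    if (!("type_label" %in% names(alleles)))
      alleles$type_label <- "unclassified"
    bad <- !(alleles$provenance %in% ALLELE_PROVENANCES)
    if (any(bad)) stop("unknown allele provenance: ",
                       paste(unique(alleles$provenance[bad]), collapse = ", "))
    bad <- !(alleles$type_label %in% TYPE_LABELS)
    if (any(bad)) stop("unknown type label: ",
                       paste(unique(alleles$type_label[bad]), collapse = ", "))
    dna_by_code <- setNames(fingers$dna, fingers$code)
    alleles$dna <- vapply(strsplit(alleles$zf_codes, ",", fixed = TRUE),
                          function(cds) {
      cds <- trimws(cds)
      if (length(cds) < 1L) stop("allele with no finger codes")
      missing <- setdiff(cds, fingers$code)
      if (length(missing))
        stop("allele references unknown finger code(s): ",
             paste(missing, collapse = ", "))
      paste(dna_by_code[cds], collapse = "")
    }, character(1))
    alleles <- alleles[, c("name", "zf_codes", "dna", "provenance",
                           "type_label")]
    if (anyDuplicated(alleles$dna))
      warning("allele names with identical dna: ",
              paste(alleles$name[alleles$dna %in%
                                   alleles$dna[duplicated(alleles$dna)]],
                    collapse = ", "))
  }
  structure(list(fingers = fingers, alleles = alleles), class = "zf_catalog")
}

#' @export
print.zf_catalog <- function(x, ...) {
  cat("ZF catalog: ", nrow(x$fingers), " fingers (",
      sum(x$fingers$is_novel), " novel), ", nrow(x$alleles),
      " alleles\n", sep = "")
  invisible(x)
}

#' Ordered finger codes of a catalog allele
#' @param catalog a `zf_catalog`.
#' @param name allele name.
#' @return character vector of finger codes.
#' @export
allele_codes <- function(catalog, name) {
  i <- match(name, catalog$alleles$name)
  if (is.na(i)) stop("allele not in catalog: ", name)
  strsplit(catalog$alleles$zf_codes[i], ",", fixed = TRUE)[[1]]
}

#' DNA sequence of a catalog allele
#' @inheritParams allele_codes
#' @return DNA string.
#' @export
allele_dna <- function(catalog, name) {
  i <- match(name, catalog$alleles$name)
  if (is.na(i)) stop("allele not in catalog: ", name)
  catalog$alleles$dna[i]
}

#' Add an allele (by finger codes) to a catalog
#'
#' @inheritParams allele_codes
#' @param zf_codes character vector of finger codes (all must exist).
#' @param provenance,type_label allele annotations.
#' @return the updated catalog.
#' @export
catalog_add_allele <- function(catalog, name, zf_codes,
                               provenance = "novel",
                               type_label = "unclassified") {
  new <- rbind(catalog$alleles[, c("name", "zf_codes", "provenance",
                                   "type_label")],
               data.frame(name = name,
                          zf_codes = paste(zf_codes, collapse = ","),
                          provenance = provenance, type_label = type_label,
                          stringsAsFactors = FALSE))
  zf_catalog(catalog$fingers, new)
}

is_fasta_path <- function(path) {
  grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)
}

#' Read a ZF catalog from disk
#'
#' Fingers: TSV with columns code, dna, source (or FASTA with id = code).
#' Alleles: TSV with columns name, zf_codes (comma-joined), provenance,
#' type_label (or FASTA with id = name, in which case each sequence is
#' re-encoded against the fingers, minting novel finger codes as needed).
#'
#' @param zf_path path to the finger table/FASTA.
#' @param allele_path optional path to the allele table/FASTA.
#' @return a `zf_catalog`.
#' @export
load_catalog <- function(zf_path, allele_path = NULL) {
  if (!file.exists(zf_path)) stop("no such file: ", zf_path)
  if (is_fasta_path(zf_path)) {
    seqs <- Biostrings::readDNAStringSet(zf_path)
    fingers <- data.frame(code = names(seqs), dna = as.character(seqs),
                          stringsAsFactors = FALSE)
  } else {
    fingers <- read.delim(zf_path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("code", "dna") %in% names(fingers)))
      stop("finger TSV must have columns code, dna: ", zf_path)
  }
  bad <- which(nchar(fingers$dna) != ZF_UNIT_NT)
  if (length(bad))
    stop("finger record length != ", ZF_UNIT_NT, " at line ", bad[1] + 1L,
         " of ", zf_path, " (code ", fingers$code[bad[1]], ")")
  alleles <- NULL
  if (!is.null(allele_path)) {
    if (!file.exists(allele_path)) stop("no such file: ", allele_path)
    if (is_fasta_path(allele_path)) {
      cat0 <- zf_catalog(fingers)
      seqs <- Biostrings::readDNAStringSet(allele_path)
      codes <- character(length(seqs))
      for (i in seq_along(seqs)) {
        enc <- encode_allele(as.character(seqs[[i]]), cat0)
        cat0 <- enc$catalog
        codes[i] <- paste(enc$codes, collapse = ",")
      }
      return(zf_catalog(cat0$fingers,
                        data.frame(name = names(seqs), zf_codes = codes,
                                   stringsAsFactors = FALSE)))
    }
    alleles <- read.delim(allele_path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (!all(c("name", "zf_codes") %in% names(alleles)))
      stop("allele TSV must have columns name, zf_codes: ", allele_path)
  }
  zf_catalog(fingers, alleles)
}

#' Write a ZF catalog to TSV files
#'
#' Tab-separated, header row, UTF-8, no quoting; round-trips through
#' [load_catalog()] byte-identically at the table level.
#'
#' @inheritParams allele_codes
#' @param zf_path,allele_path output paths.
#' @export
write_catalog <- function(catalog, zf_path, allele_path = NULL) {
  write.table(catalog$fingers[, c("code", "dna", "source")],
              zf_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(allele_path))
    write.table(catalog$alleles[, c("name", "zf_codes", "provenance",
                                    "type_label")],
                allele_path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  invisible(catalog)
}

# Successor in the novel-finger code space: !A..!Z, !a..!z, !0..!9, then
# numbered codes !10, !11, ... (unbounded).
novel_code_space <- function(n) {
  base <- c(paste0("!", LETTERS), paste0("!", letters), paste0("!", 0:9))
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("!", seq(10L, length.out = n - length(base))))
}

next_novel_code <- function(existing) {
  used <- existing[startsWith(existing, "!")]
  cand <- novel_code_space(length(used) + 1L)
  setdiff(cand, used)[1]
}

#' Decompose an array DNA sequence into finger codes
#'
#' Each consecutive 84-nt unit is looked up in the catalog by exact sequence
#' match; units absent from the catalog are minted a new "!" code (uppercase
#' letters first, then lowercase, then digits) and added to the catalog with
#' `is_novel = TRUE`.
#'
#' @param dna array DNA, length divisible by 84.
#' @param catalog a `zf_catalog`.
#' @return list with `codes` (ordered finger codes, 5'->3'), `catalog` (the
#'   possibly-extended catalog) and `novel` (codes minted by this call).
#' @export
encode_allele <- function(dna, catalog) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0L || n %% ZF_UNIT_NT != 0L)
    stop("array length ", n, " is not a multiple of ", ZF_UNIT_NT,
         ": not a contiguous ZF array")
  starts <- seq(1L, n, by = ZF_UNIT_NT)
  units <- substring(dna, starts, starts + ZF_UNIT_NT - 1L)
  code_by_dna <- setNames(catalog$fingers$code, catalog$fingers$dna)
  codes <- character(length(units))
  novel <- character(0)
  fingers <- catalog$fingers
  for (i in seq_along(units)) {
    hit <- code_by_dna[units[i]]
    if (!is.na(hit)) {
      codes[i] <- hit
    } else {
      code <- next_novel_code(fingers$code)
      fingers <- rbind(fingers, zinc_finger(code, units[i], is_novel = TRUE,
                                            source = "minted"))
      code_by_dna[units[i]] <- code
      codes[i] <- code
      novel <- c(novel, code)
    }
  }
  catalog$fingers <- fingers
  list(codes = codes, catalog = catalog, novel = novel)
}

#' Name for a novel allele
#'
#' Alleles absent from the catalog receive the next free "M#" index, in
#' discovery order. If the finger-code string already belongs to a catalog
#' allele, that allele's existing name is returned.
#'
#' @param zf_codes character vector of finger codes.
#' @param catalog a `zf_catalog`.
#' @return allele name.
#' @export
name_new_allele <- function(zf_codes, catalog) {
  key <- paste(zf_codes, collapse = ",")
  i <- match(key, catalog$alleles$zf_codes)
  if (!is.na(i)) return(catalog$alleles$name[i])
  m <- grep("^M[0-9]+$", catalog$alleles$name, value = TRUE)
  idx <- if (length(m)) max(as.integer(sub("^M", "", m))) + 1L else 1L
  paste0("M", idx)
}

#' Render the five-part name of a variant allele
#'
#' Variants are named `<variant type>:<s|c>:<allele number>:<donor>:<parental
#' genotype>`, e.g. `Av:c:0065:M2S:A-L20`: an A-derived variant, complex
#' (more than one event), index 65, from the sperm of man 2, whose genotype
#' was A/L20. The short form collapses to `<variant type>:<allele number>`.
#'
#' @param variant_type parental allele name the variant derives from, with a
#'   "v" suffix, or "Rv" (recombinant) / "Uv" (unknown origin).
#' @param complexity "s" (simple, one event) or "c" (complex).
#' @param allele_number integer index; zero-padded to 4 digits.
#' @param donor donor identifier plus tissue code, e.g. "M2S" (man 2, sperm)
#'   or "M7B" (man 7, blood).
#' @param parental_genotype the donor's two allele names, e.g. c("A", "L20").
#' @param short if TRUE, render the short two-part form.
#' @return character name.
#' @examples
#' format_variant_name("Av", "c", 65, "M2S", c("A", "L20"))
#' @export
format_variant_name <- function(variant_type, complexity, allele_number,
                                donor, parental_genotype, short = FALSE) {
  stopifnot(complexity %in% c("s", "c"), length(parental_genotype) == 2L)
  num <- sprintf("%04d", as.integer(allele_number))
  if (short) return(paste(variant_type, num, sep = ":"))
  paste(variant_type, complexity, num, donor,
        paste(parental_genotype, collapse = "-"), sep = ":")
}

#' Parse a five-part variant allele name
#'
#' @param name a name produced by [format_variant_name()].
#' @return list with fields variant_type, complexity, allele_number, donor,
#'   parental_genotype.
#' @export
parse_variant_name <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 5L) stop("not a five-part variant name: ", name)
  list(variant_type = parts[1], complexity = parts[2],
       allele_number = as.integer(parts[3]), donor = parts[4],
       parental_genotype = strsplit(parts[5], "-", fixed = TRUE)[[1]])
}
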