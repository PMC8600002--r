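# Simulation of ZF catalogs, alleles, diploid individuals and barcoded
# long reads, with PCR-slippage and per-base error models. Everything is
# deterministic given (parameters, seed).
#
# Simulated fingers share a fixed C2H2-like 28-residue scaffold (zinc
# coordinating cysteines at positions 8/11 and histidines at 24/28, DNA
# contact residues at 16/20/23) so that units are homologous, mimicking the
# minisatellite structure of the real array.

SCAFFOLD_AA <- c("T", "G", "E", "K", "P", "Y", "V", "C", "R", "E", "C", "G",
                 "R", "G", "F", "S", "R", "K", "S", "N", "L", "I", "R", "H",
                 "Q", "R", "T", "H")
SCAFFOLD_CONTACT <- c(16L, 20L, 23L)     # helix -1 / 3 / 6
SCAFFOLD_VARIABLE <- c(13L, 17L, 19L)    # non-contact variable positions
CODON1 <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
            G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
            M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGG",
            S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
CODON2 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGA", H = "CAT", I = "ATT", K = "AAA", L = "CTC",
            M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "CGT",
            S = "TCC", T = "ACA", V = "GTC", W = "TGG", Y = "TAT")
RESIDUE_POOL <- c("Q", "R", "K", "N", "S", "T", "D", "E", "V", "A", "G",
                  "L", "I", "F", "Y", "W")

# Build an 84-nt finger from a 28-residue vector; `wobble` positions use the
# alternative codon, diversifying dna without changing the protein.
finger_dna <- function(aa, wobble = integer(0)) {
  codons <- CODON1[aa]
  if (length(wobble)) codons[wobble] <- CODON2[aa[wobble]]
  paste(codons, collapse = "")
}

random_finger_aa <- function() {
  aa <- SCAFFOLD_AA
  vary <- c(SCAFFOLD_CONTACT, SCAFFOLD_VARIABLE)
  aa[vary] <- sample(RESIDUE_POOL, length(vary), replace = TRUE)
  aa
}

#' Simulate a ZF catalog
#'
#' Fingers are random variants of a shared C2H2 scaffold (pairwise identity
#' well above 60% by construction); alleles are random finger strings.
#'
#' @param n_fingers number of distinct fingers (>= 2).
#' @param n_alleles number of alleles.
#' @param len_range range of allele lengths in fingers.
#' @param seed RNG seed; the seed fully determines the catalog.
#' @return a `zf_catalog` with synthetic provenance.
#' @export
simulate_catalog <- function(n_fingers = 12L, n_alleles = 6L,
                             len_range = c(8L, 16L), seed = 1L) {
  stopifnot(n_fingers >= 2L)
  set.seed(seed)
  codes <- paste0(rep(letters, each = 26L), rep(letters, times = 26L))
  codes <- codes[seq_len(n_fingers)]
  dnas <- character(0)
  rows <- list()
  for (k in seq_len(n_fingers)) {
    repeat {
      aa <- random_finger_aa()
      wob <- sample(setdiff(seq_len(ZF_UNIT_AA),
                            c(8L, 11L, 24L, 28L)), sample(0:3, 1))
      dna <- finger_dna(aa, wob)
      if (!(dna %in% dnas)) break
    }
    dnas <- c(dnas, dna)
    rows[[k]] <- data.frame(code = codes[k], dna = dna,
                            stringsAsFactors = FALSE)
  }
  fingers <- do.call(rbind, rows)
  alleles <- list()
  seen <- character(0)
  for (k in seq_len(n_alleles)) {
    repeat {
      len <- sample(len_range[1]:len_range[2], 1L)
      zf <- paste(sample(codes, len, replace = TRUE), collapse = ",")
      if (!(zf %in% seen)) break
    }
    seen <- c(seen, zf)
    alleles[[k]] <- data.frame(name = paste0("S", k), zf_codes = zf,
                               provenance = "synthetic",
                               stringsAsFactors = FALSE)
  }
  zf_catalog(fingers, do.call(rbind, alleles))
}

#' Plant a template-switch recombinant
#'
#' Builds a child from `k_switches` + 1 alternating parental fragments, each
#' longer than `min_match` nt: the first a prefix of `p1`, the last a suffix
#' of the final active parent, middle fragments at random positions.
#'
#' @param p1,p2 parental DNA strings.
#' @param k_switches number of planted switches (>= 0).
#' @param min_match fragment lengths exceed this (default 15).
#' @param seed RNG seed.
#' @return list with `child` and `path` (planted `switch_path`-style
#'   segments data.frame).
#' @export
simulate_recombinant <- function(p1, p2, k_switches, min_match = 15L,
                                 seed = 1L) {
  set.seed(seed)
  stopifnot(k_switches >= 0L)
  parents <- c(p1, p2)
  minlen <- min_match + 1L
  lens <- nchar(parents)
  if (any(lens < 2L * minlen))
    stop("parents too short to host fragments longer than ", min_match)
  segs <- list()
  for (s in seq_len(k_switches + 1L)) {
    p <- if (s %% 2L == 1L) 1L else 2L
    m <- lens[p]
    if (s == 1L && k_switches == 0L) {
      segs[[s]] <- c(p, 0L, m)  # single fragment: the whole parent
    } else if (s == 1L) {
      e <- sample(minlen:(m - minlen), 1L)
      segs[[s]] <- c(p, 0L, e)
    } else if (s == k_switches + 1L) {
      l <- sample(minlen:(m - minlen), 1L)
      segs[[s]] <- c(p, m - l, l)
    } else {
      l <- sample(minlen:(m - minlen), 1L)
      q <- sample(0L:(m - l), 1L)
      segs[[s]] <- c(p, q, l)
    }
  }
  df <- do.call(rbind, segs)
  segments <- data.frame(parent = df[, 1], start = df[, 2],
                         end = df[, 2] + df[, 3], length = df[, 3])
  child <- paste(vapply(seq_len(nrow(segments)), function(k)
    substr(parents[segments$parent[k]], segments$start[k] + 1L,
           segments$end[k]), character(1)), collapse = "")
  list(child = child,
       path = structure(list(child = child, parents = parents,
                             segments = segments,
                             n_switches = nrow(segments) - 1L,
                             min_match = min_match),
                        class = "switch_path"))
}

#' Sequencing / PCR error model
#'
#' @param substitution,insertion,deletion per-base error rates in \[0, 1).
#' @param slippage probability that a read is a whole-unit slippage artifact.
#' @param slip_shift_probs named numeric over unit shifts "-2","-1","1","2".
#' @param truncation probability that a read is truncated inside the array
#'   (losing the 3' flank).
#' @return object of class `error_model`.
#' @export
error_model <- function(substitution = 0.01, insertion = 0.005,
                        deletion = 0.005, slippage = 0.10,
                        slip_shift_probs = c("-2" = 0.15, "-1" = 0.35,
                                             "1" = 0.35, "2" = 0.15),
                        truncation = 0.02) {
  rates <- c(substitution, insertion, deletion, slippage, truncation)
  stopifnot(all(rates >= 0), all(rates < 1),
            abs(sum(slip_shift_probs) - 1) < 1e-9)
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion, slippage = slippage,
                 slip_shift_probs = slip_shift_probs,
                 truncation = truncation),
            class = "error_model")
}

#' An error-free model (slippage and truncation off)
#' @export
zero_error_model <- function() {
  error_model(0, 0, 0, 0, truncation = 0)
}

apply_base_errors <- function(seq, em) {
  if (em$substitution == 0 && em$insertion == 0 && em$deletion == 0)
    return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  u <- runif(n)
  del <- u < em$deletion
  sub <- !del & u < em$deletion + em$substitution
  if (any(sub)) {
    repl <- sample(bases, sum(sub), replace = TRUE)
    same <- repl == chars[sub]
    while (any(same)) {  # force a different base
      repl[same] <- sample(bases, sum(same), replace = TRUE)
      same <- repl == chars[sub]
    }
    chars[sub] <- repl
  }
  ins <- runif(n) < em$insertion
  if (any(ins)) {
    out <- character(n + sum(ins))
    j <- 1L
    for (i in seq_len(n)) {
      if (ins[i]) { out[j] <- sample(bases, 1L); j <- j + 1L }
      if (!del[i]) { out[j] <- chars[i]; j <- j + 1L }
    }
    return(paste(out[seq_len(j - 1L)], collapse = ""))
  }
  paste(chars[!del], collapse = "")
}

slip_array <- function(array_dna, em) {
  n_units <- nchar(array_dna) %/% ZF_UNIT_NT
  shift <- as.integer(sample(names(em$slip_shift_probs), 1L,
                             prob = em$slip_shift_probs))
  if (n_units + shift < 1L) shift <- abs(shift)
  starts <- seq(1L, nchar(array_dna), by = ZF_UNIT_NT)
  units <- substring(array_dna, starts, starts + ZF_UNIT_NT - 1L)
  if (shift > 0L) {
    at <- sample(seq_len(n_units), 1L)
    block <- units[max(1L, at - shift + 1L):at]
    units <- append(units, block, after = at)
  } else {
    k <- -shift
    at <- sample(seq_len(n_units - k + 1L), 1L)
    units <- units[-(at:(at + k - 1L))]
  }
  list(dna = paste(units, collapse = ""), shift = shift)
}

#' Simulate barcoded long reads for one diploid genotype
#'
#' Each read picks a haplotype 50/50, assembles outer barcode + inner
#' barcode + 5' flank + array + 3' flank + reverse-complemented barcodes,
#' then applies (in order) whole-unit PCR slippage, per-base errors,
#' optional truncation inside the array, and a random orientation flip.
#'
#' @param hap_dnas character vector of 1 or 2 allele array sequences.
#' @param coverage number of reads.
#' @param anchors a [flank_anchors()] supplying the flanking sequences.
#' @param outer,inner barcode sequences attached to this sample.
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @param read_prefix read-id prefix.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame read_id / haplotype / slipped / shift / truncated /
#'   strand).
#' @export
simulate_reads <- function(hap_dnas, coverage = 150L,
                           anchors = flank_anchors(),
                           outer = "TTCGAAGCCGTACGTTAGCCAATC",
                           inner = INNER_BARCODES[1],
                           em = error_model(), seed = 1L,
                           read_prefix = "read") {
  set.seed(seed)
  stopifnot(coverage >= 1L, length(hap_dnas) %in% 1:2)
  if (length(hap_dnas) == 1L) hap_dnas <- rep(hap_dnas, 2L)
  reads <- character(coverage); truth <- vector("list", coverage)
  for (r in seq_len(coverage)) {
    hap <- sample(1:2, 1L)
    array_dna <- hap_dnas[hap]
    slipped <- runif(1) < em$slippage
    shift <- 0L
    if (slipped) {
      sl <- slip_array(array_dna, em)
      array_dna <- sl$dna; shift <- sl$shift
    }
    insert <- paste0(anchors$flank5, array_dna, anchors$flank3)
    read <- paste0(outer, inner, insert, revcomp(inner), revcomp(outer))
    read <- apply_base_errors(read, em)
    truncated <- runif(1) < em$truncation
    if (truncated) {
      lo <- nchar(outer) + nchar(inner) + nchar(anchors$flank5) + 20L
      hi <- max(lo + 1L, nchar(read) - nchar(anchors$flank3) - 60L)
      read <- substr(read, 1L, sample(lo:hi, 1L))
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") read <- revcomp(read)
    reads[r] <- read
    truth[[r]] <- data.frame(read_id = paste0(read_prefix, r),
                             haplotype = hap, slipped = slipped,
                             shift = shift, truncated = truncated,
                             strand = strand, stringsAsFactors = FALSE)
  }
  names(reads) <- paste0(read_prefix, seq_len(coverage))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Simulate a cohort of diploid individuals
#'
#' Allele pairs are drawn uniformly (with replacement) from the catalog,
#' each individual gets a dual-barcode address, and reads are simulated per
#' individual.
#'
#' @param catalog a `zf_catalog` with at least one allele.
#' @param n_individuals cohort size.
#' @param coverage reads per individual.
#' @param em an [error_model()].
#' @param scheme a [barcode_scheme()]; individuals are assigned (outer,
#'   inner) pairs round-robin.
#' @param anchors a [flank_anchors()].
#' @param seed RNG seed.
#' @return list with `individuals` (list of per-individual lists: id,
#'   alleles (true names), hap_dnas, sample (barcode address), reads,
#'   truth).
#' @export
simulate_individuals <- function(catalog, n_individuals = 10L,
                                 coverage = 150L, em = error_model(),
                                 scheme = NULL, anchors = flank_anchors(),
                                 seed = 1L) {
  set.seed(seed)
  if (is.null(scheme)) {
    outer <- vapply(seq_len(max(1L, ceiling(n_individuals / 8L))),
                    function(i) paste(sample(c("A", "C", "G", "T"), 24L,
                                             replace = TRUE), collapse = ""),
                    character(1))
    scheme <- barcode_scheme(outer = outer)
  }
  addresses <- expand.grid(inner = seq_along(scheme$inner),
                           outer = seq_along(scheme$outer))
  stopifnot(nrow(addresses) >= n_individuals)
  out <- vector("list", n_individuals)
  seeds <- sample.int(.Machine$integer.max, n_individuals)
  for (k in seq_len(n_individuals)) {
    nms <- sample(catalog$alleles$name, 2L, replace = TRUE)
    hap_dnas <- vapply(nms, allele_dna, character(1), catalog = catalog)
    oi <- addresses$outer[k]; ii <- addresses$inner[k]
    sim <- simulate_reads(unname(hap_dnas), coverage, anchors,
                          outer = scheme$outer[oi],
                          inner = scheme$inner[ii], em = em,
                          seed = seeds[k],
                          read_prefix = paste0("ind", k, "_r"))
    out[[k]] <- list(id = paste0("ind", k), alleles = nms,
                     hap_dnas = unname(hap_dnas),
                     sample = paste(names(scheme$outer)[oi],
                                    names(scheme$inner)[ii], sep = "_"),
                     reads = sim$reads, truth = sim$truth)
  }
  list(individuals = out, scheme = scheme)
}
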