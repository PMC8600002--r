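# Diploid genotype inference from extracted array observations.
#
# The caller proceeds: coverage gate -> length-frequency rules (which absorb
# PCR slippage products) -> per-length consensus, with clustering-based
# phasing when both haplotypes have the same number of fingers.

#' Length-frequency table of array observations
#'
#' Lengths (finger counts) are ordered by read count, ties broken toward the
#' smaller count, giving deterministic i/j/k labels for the most frequent,
#' second and third most frequent lengths.
#'
#' @param n_units integer vector of per-read finger counts, or a list of
#'   `array_observation`s.
#' @return object of class `length_frequency_table`: data.frame with columns
#'   n_units, count, freq, ordered i, j, k, ...
#' @export
length_frequency_table <- function(n_units) {
  if (is.list(n_units))
    n_units <- vapply(n_units, function(o) o$n_units, integer(1))
  stopifnot(length(n_units) >= 1L)
  tab <- table(n_units)
  df <- data.frame(n_units = as.integer(names(tab)),
                   count = as.integer(tab))
  df <- df[order(-df$count, df$n_units), , drop = FALSE]
  df$freq <- df$count / sum(df$count)
  rownames(df) <- NULL
  class(df) <- c("length_frequency_table", "data.frame")
  df
}

#' Infer the two haplotype lengths from a length-frequency table
#'
#' The five rules are processed consecutively; the first satisfied rule wins.
#' With f_i, f_j, f_k the frequencies of the most, second and third most
#' frequent lengths i, j, k (f_k = 0 when fewer than three lengths were
#' observed, so f_j / f_k is infinite):
#' 1. only one length observed (f_i = 1): homozygous-length (i, i);
#' 2. f_i + f_j >= 0.7 and f_i / f_j < 2: (i, j);
#' 3. f_i + f_j >= 0.7 and f_i / f_j < 3 and f_j / f_k > 2: (i, j);
#' 4. f_i + f_j >= 0.7 and f_i / f_j > 3: (i, i);
#' 5. f_i >= 0.7: (i, i);
#' otherwise no call. Note the printed operators are strict, so a ratio
#' f_i / f_j of exactly 3 escapes rules 3 and 4 and falls through to rule 5.
#'
#' @param table a [length_frequency_table()] (or a vector of finger counts).
#' @return object of class `length_call`: list with `rule` (1-5 or NA for no
#'   call) and `hap_lengths` (pair of finger counts, NA on no call).
#' @export
infer_lengths <- function(table) {
  if (!inherits(table, "length_frequency_table"))
    table <- length_frequency_table(table)
  fi <- table$freq[1]; i <- table$n_units[1]
  fj <- if (nrow(table) >= 2L) table$freq[2] else 0
  j <- if (nrow(table) >= 2L) table$n_units[2] else NA_integer_
  fk <- if (nrow(table) >= 3L) table$freq[3] else 0
  call <- function(rule, a, b)
    structure(list(rule = rule, hap_lengths = c(a, b)), class = "length_call")
  if (nrow(table) == 1L) return(call(1L, i, i))
  if (fi + fj >= 0.7) {
    if (fi / fj < 2) return(call(2L, i, j))
    jk_ratio <- if (fk == 0) Inf else fj / fk
    if (fi / fj < 3 && jk_ratio > 2) return(call(3L, i, j))
    if (fi / fj > 3) return(call(4L, i, i))
  }
  if (fi >= 0.7) return(call(5L, i, i))
  structure(list(rule = NA_integer_, hap_lengths = c(NA_integer_,
                                                     NA_integer_)),
            class = "length_call")
}

#' Per-position consensus of equal-length sequences
#'
#' The consensus base at each position is the modal base among non-N, non-gap
#' observations (ties broken alphabetically); the consensus frequency f_c is
#' the modal count divided by the number of non-N, non-gap observations.
#' Positions where every sequence has N get consensus N and f_c NA.
#'
#' @param arrays character vector of equal-length sequences (Ns allowed).
#' @return object of class `consensus_profile`: list with `consensus`, `f_c`,
#'   `depth` (non-N observations per position) and `length`.
#' @export
build_consensus <- function(arrays) {
  stopifnot(length(arrays) >= 1L)
  L <- unique(nchar(arrays))
  if (length(L) != 1L) stop("sequences have differing lengths")
  m <- matrix(unlist(strsplit(arrays, "", fixed = TRUE), use.names = FALSE),
              nrow = length(arrays), ncol = L, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, bases))
  depth <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  consensus <- bases[top]
  f_c <- counts[cbind(seq_len(L), top)] / depth
  consensus[depth == 0] <- "N"
  f_c[depth == 0] <- NA_real_
  structure(list(consensus = paste(consensus, collapse = ""), f_c = f_c,
                 depth = depth, length = L),
            class = "consensus_profile")
}

# Positions whose defined f_c falls below a floor.
low_fc_positions <- function(profile, floor) {
  which(!is.na(profile$f_c) & profile$f_c < floor)
}

#' Phase equal-length arrays into one or two haplotypes
#'
#' If every position has consensus frequency f_c >= `f_c_floor` the sample is
#' called homozygous with the full consensus. Otherwise each sequence is
#' restricted to the positions with f_c below the floor, pairwise Hamming
#' distances are computed (N excluded pairwise), and complete-linkage
#' hierarchical clustering is cut at the cluster count n (1 <= n <
#' `max_clusters` + 1) minimising the mean within-cluster pairwise distance
#' pooled over clusters (singletons contribute no pairs; ties go to the
#' smallest n). The two largest clusters are taken as the haplotypes; each
#' must hold at least two sequences and its full-length consensus must have
#' all f_c >= the floor, else that haplotype fails.
#'
#' @param arrays character vector of equal-length array sequences.
#' @param f_c_floor consensus-frequency floor (default 0.7).
#' @param max_clusters largest cluster count tried (default 19).
#' @return list with `status` ("hom", "het" or "fail"), `consensi`,
#'   `supports`, `reason` (on failure) and `n_clusters`.
#' @export
phase_equal_length <- function(arrays, f_c_floor = 0.7, max_clusters = 19L) {
  prof <- build_consensus(arrays)
  het_pos <- low_fc_positions(prof, f_c_floor)
  if (!length(het_pos))
    return(list(status = "hom", consensi = prof$consensus,
                supports = length(arrays), n_clusters = 1L))
  m <- matrix(unlist(strsplit(arrays, "", fixed = TRUE), use.names = FALSE),
              nrow = length(arrays), byrow = TRUE)
  restricted <- apply(m[, het_pos, drop = FALSE], 1L, paste, collapse = "")
  if (length(arrays) < 4L)
    return(list(status = "fail", reason = "insufficient_support"))
  d <- cpp_hamming_matrix(restricted)
  dd <- structure(d, Size = length(arrays), Diag = FALSE, Upper = FALSE,
                  class = "dist", method = "hamming")
  hc <- hclust(dd, method = "complete")
  ns <- seq_len(min(max_clusters, length(arrays)))
  dm <- as.matrix(dd)
  mean_within <- vapply(ns, function(n) {
    ct <- cutree(hc, k = n)
    tot <- 0; pairs <- 0
    for (cl in unique(ct)) {
      idx <- which(ct == cl)
      if (length(idx) < 2L) next
      sub <- dm[idx, idx]
      tot <- tot + sum(sub[lower.tri(sub)])
      pairs <- pairs + length(idx) * (length(idx) - 1L) / 2L
    }
    if (pairs == 0) Inf else tot / pairs
  }, numeric(1))
  n_opt <- ns[which.min(mean_within)]  # which.min takes the smallest index on ties
  ct <- cutree(hc, k = n_opt)
  sizes <- sort(table(ct), decreasing = TRUE)
  if (length(sizes) < 2L)
    return(list(status = "fail", reason = "single_cluster",
                n_clusters = n_opt))
  top2 <- as.integer(names(sizes)[1:2])
  consensi <- character(2); supports <- integer(2); reasons <- character(2)
  for (k in 1:2) {
    idx <- which(ct == top2[k])
    supports[k] <- length(idx)
    if (length(idx) < 2L) {
      reasons[k] <- "insufficient_support"
      next
    }
    cprof <- build_consensus(arrays[idx])
    if (length(low_fc_positions(cprof, f_c_floor))) {
      reasons[k] <- "consensus_below_floor"
      next
    }
    consensi[k] <- cprof$consensus
    reasons[k] <- ""
  }
  if (any(reasons != ""))
    return(list(status = "fail", reason = reasons[reasons != ""][1],
                consensi = consensi, supports = supports,
                n_clusters = n_opt))
  if (consensi[1] == consensi[2])
    return(list(status = "hom", consensi = consensi[1],
                supports = sum(supports), n_clusters = n_opt))
  list(status = "het", consensi = consensi, supports = supports,
       n_clusters = n_opt)
}

#' Coverage gate
#'
#' Individuals with fewer post-extraction observations than `min_coverage`
#' (default 100) are not genotyped.
#'
#' @param observations list of `array_observation`s (or an integer count).
#' @param min_coverage minimum retained-read count.
#' @return logical.
#' @export
coverage_gate <- function(observations, min_coverage = 100L) {
  n <- if (is.numeric(observations)) observations else length(observations)
  n >= min_coverage
}

obs_array_string <- function(o) paste(o$units, collapse = "")

allele_entry <- function(dna, support, catalog, qc = "pass", reason = "") {
  if (qc != "pass" || is.na(dna) || dna == "" || grepl("N", dna, fixed = TRUE)) {
    if (qc == "pass") { qc <- "fail"; reason <- "ambiguous_consensus" }
    return(list(entry = list(name = NA_character_, codes = character(0),
                             dna = if (is.na(dna)) NA_character_ else dna,
                             support = support, qc = qc, reason = reason),
                catalog = catalog))
  }
  enc <- tryCatch(encode_allele(dna, catalog), error = function(e) NULL)
  if (is.null(enc))
    return(list(entry = list(name = NA_character_, codes = character(0),
                             dna = dna, support = support, qc = "fail",
                             reason = "invalid_unit"),
                catalog = catalog))
  catalog <- enc$catalog
  i <- match(dna, catalog$alleles$dna)
  if (!is.na(i)) name <- catalog$alleles$name[i]
  else {
    name <- name_new_allele(enc$codes, catalog)
    if (!(name %in% catalog$alleles$name))
      catalog <- catalog_add_allele(catalog, name, enc$codes,
                                    provenance = "novel")
  }
  list(entry = list(name = name, codes = enc$codes, dna = dna,
                    support = support, qc = "pass", reason = ""),
       catalog = catalog)
}

#' Call the diploid genotype of one individual
#'
#' Orchestrates the coverage gate, the length-frequency rules, per-length
#' read retention, consensus calling (per-length consensus with a 0.6 f_c
#' floor for unequal-length heterozygotes; clustering-based phasing with a
#' 0.7 floor for equal-length samples) and allele naming against the catalog
#' (novel fingers and alleles are minted and registered).
#'
#' @param observations list of `array_observation`s for one individual.
#' @param catalog a `zf_catalog`.
#' @param individual identifier recorded in the genotype.
#' @param min_coverage coverage gate (default 100 reads).
#' @param f_c_unequal consensus floor on the unequal-length path (0.6).
#' @param f_c_equal consensus floor on the equal-length path (0.7).
#' @param max_clusters cluster-count cap for phasing (19).
#' @return list with `genotype` (class `diploid_genotype`) and `catalog`
#'   (possibly extended with novel fingers/alleles).
#' @export
call_genotype <- function(observations, catalog, individual = "sample",
                          min_coverage = 100L, f_c_unequal = 0.6,
                          f_c_equal = 0.7, max_clusters = 19L) {
  fail <- function(reason, rule = NA_integer_, lengths = NULL)
    list(genotype = structure(
      list(individual = individual, alleles = NULL, zygosity = NA_character_,
           rule = rule, hap_lengths = lengths, qc = "fail", reason = reason,
           n_reads = length(observations)),
      class = "diploid_genotype"), catalog = catalog)
  if (!coverage_gate(observations, min_coverage))
    return(fail("low_coverage"))
  # deterministic input order
  ids <- vapply(observations, function(o) o$read_id, character(1))
  observations <- observations[order(ids)]
  lc <- infer_lengths(length_frequency_table(observations))
  if (is.na(lc$rule)) return(fail("length_no_call"))
  n_units <- vapply(observations, function(o) o$n_units, integer(1))
  i <- lc$hap_lengths[1]; j <- lc$hap_lengths[2]
  entries <- vector("list", 2L)
  if (i != j) {
    zygosity <- "het_unequal_length"
    for (k in 1:2) {
      ell <- lc$hap_lengths[k]
      arrays <- vapply(observations[n_units == ell], obs_array_string,
                       character(1))
      prof <- build_consensus(arrays)
      if (length(low_fc_positions(prof, f_c_unequal))) {
        res <- allele_entry(NA_character_, length(arrays), catalog,
                            qc = "fail", reason = "consensus_below_0.6")
      } else {
        res <- allele_entry(prof$consensus, length(arrays), catalog)
      }
      entries[[k]] <- res$entry; catalog <- res$catalog
    }
  } else {
    arrays <- vapply(observations[n_units == i], obs_array_string,
                     character(1))
    ph <- phase_equal_length(arrays, f_c_floor = f_c_equal,
                             max_clusters = max_clusters)
    if (ph$status == "hom") {
      zygosity <- "hom"
      for (k in 1:2) {
        res <- allele_entry(ph$consensi, ph$supports, catalog)
        entries[[k]] <- res$entry; catalog <- res$catalog
      }
    } else if (ph$status == "het") {
      zygosity <- "het_equal_length"
      for (k in 1:2) {
        res <- allele_entry(ph$consensi[k], ph$supports[k], catalog)
        entries[[k]] <- res$entry; catalog <- res$catalog
      }
    } else {
      return(fail(paste0("phasing_", ph$reason), rule = lc$rule,
                  lengths = lc$hap_lengths))
    }
  }
  qc <- if (all(vapply(entries, function(e) e$qc == "pass", logical(1))))
    "pass" else "partial"
  list(genotype = structure(
    list(individual = individual, alleles = entries, zygosity = zygosity,
         rule = lc$rule, hap_lengths = lc$hap_lengths, qc = qc, reason = "",
         n_reads = length(observations)),
    class = "diploid_genotype"), catalog = catalog)
}

#' @export
print.diploid_genotype <- function(x, ...) {
  cat("Diploid genotype for", x$individual, "-", x$qc, "\n")
  if (x$qc == "fail") {
    cat("  reason:", x$reason, "\n")
  } else {
    cat("  zygosity:", x$zygosity, "(length rule", x$rule, ")\n")
    for (a in x$alleles)
      cat("  allele:", a$name, "(", length(a$codes), "ZFs,", a$support,
          "reads,", a$qc, ")\n")
  }
  invisible(x)
}

genotype_dnas <- function(g) {
  if (is.null(g$alleles)) return(character(0))
  vapply(g$alleles, function(a)
    if (identical(a$qc, "pass")) a$dna else NA_character_, character(1))
}

#' Merge two platform calls for one individual
#'
#' Two genotypes are concordant when their unordered allele-sequence pairs
#' are identical. The concordance record carries the zygosity category and a
#' flag for discordant pairs sharing at least one allele.
#'
#' @param genotype_a,genotype_b `diploid_genotype`s for the same individual.
#' @return list with `concordant`, `category` (hom / het_equal /
#'   het_unequal), `shared_allele` and `genotype` (the first call when
#'   concordant, else NULL).
#' @export
merge_platform_calls <- function(genotype_a, genotype_b) {
  da <- sort(genotype_dnas(genotype_a)); db <- sort(genotype_dnas(genotype_b))
  ok <- length(da) == 2L && length(db) == 2L && !anyNA(da) && !anyNA(db)
  concordant <- ok && identical(da, db)
  category <- switch(genotype_a$zygosity,
                     hom = "hom", het_equal_length = "het_equal",
                     het_unequal_length = "het_unequal", NA_character_)
  shared <- length(intersect(da, db)) >= 1L
  list(concordant = concordant, category = category, shared_allele = shared,
       genotype = if (concordant) genotype_a else NULL)
}
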