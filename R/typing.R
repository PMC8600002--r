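# Allele typing and cohort statistics.
#
# Each C2H2 finger contacts DNA mainly through the residues at helix
# positions -1, 3 and 6; the per-finger triplet of these residues summarises
# the binding specificity of the array. Alleles are labelled A-type or C-type
# by aligning their triplet lists against the PRDM9-A and PRDM9-C reference
# profiles.

#' Locate the DNA-contact residue offsets of a 28-aa finger unit
#'
#' The offsets are anchored on the conserved zinc-coordinating histidine
#' pair (H-x3/4/5-H) near the unit's C-terminus: with the first histidine at
#' helix position 7, the contact residues at helix positions -1, 3 and 6 sit
#' 8, 4 and 1 residues before it.
#'
#' @param aa a 28-residue finger translation.
#' @return integer vector of three 1-based offsets into the unit.
#' @export
contact_offsets <- function(aa) {
  stopifnot(nchar(aa) == ZF_UNIT_AA)
  hpos <- gregexpr("H", aa, fixed = TRUE)[[1]]
  if (hpos[1] == -1L) stop("no histidine in finger unit: ", aa)
  first_h <- NA_integer_
  for (p in rev(as.integer(hpos))) {
    gaps <- as.integer(hpos) - p
    if (any(gaps %in% 4:6)) { first_h <- p; break }
  }
  if (is.na(first_h))
    stop("no conserved histidine pair (H-x3/4/5-H) in finger unit: ", aa)
  off <- c(first_h - 8L, first_h - 4L, first_h - 1L)
  if (any(off < 1L)) stop("histidine pair too close to unit start: ", aa)
  off
}

#' DNA-contact residue profile of an allele
#'
#' One 3-residue token per finger: the amino acids at helix positions -1, 3
#' and 6 of the finger's 28-residue translation.
#'
#' @param allele an allele name (looked up in `catalog`) or a raw array DNA
#'   string with length divisible by 84.
#' @param catalog a `zf_catalog` (required when `allele` is a name).
#' @param offsets 1-based offsets of the three contact residues within the
#'   unit; by default derived from the first unit via [contact_offsets()].
#' @return object of class `contact_profile`: list with `triplets` (one
#'   token per finger) and `offsets`.
#' @export
contact_profile <- function(allele, catalog = NULL, offsets = NULL) {
  dna <- if (!is.null(catalog) && allele %in% catalog$alleles$name)
    allele_dna(catalog, allele) else allele
  n <- nchar(dna)
  if (n %% ZF_UNIT_NT != 0L)
    stop("allele dna length not a multiple of ", ZF_UNIT_NT)
  starts <- seq(1L, n, by = ZF_UNIT_NT)
  units <- substring(dna, starts, starts + ZF_UNIT_NT - 1L)
  aas <- vapply(units, translate_dna, character(1), USE.NAMES = FALSE)
  if (any(grepl("\\*", aas))) stop("stop codon in finger unit")
  if (is.null(offsets)) offsets <- contact_offsets(aas[1])
  stopifnot(length(offsets) == 3L)
  triplets <- vapply(aas, function(a)
    paste(substring(a, offsets, offsets), collapse = ""), character(1),
    USE.NAMES = FALSE)
  structure(list(triplets = triplets, offsets = offsets),
            class = "contact_profile")
}

# Global (Needleman-Wunsch) alignment score of two token vectors with
# match 1 / mismatch 0 / gap -0.5 (linear gaps).
token_alignment_score <- function(a, b, match = 1, mismatch = 0,
                                  gap = -0.5) {
  n <- length(a); m <- length(b)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      cur[j + 1L] <- max(prev[j] + s, prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Classify an allele as A-type or C-type
#'
#' The query's contact-residue triplet list is globally aligned against each
#' reference profile (match 1, mismatch 0, gap -0.5) and the score is
#' normalised by the reference's finger count. The label is the best-scoring
#' reference when its similarity reaches `threshold`, else "untyped".
#'
#' @param allele query (name or dna, as in [contact_profile()]).
#' @param refA,refC reference alleles (names or dna).
#' @param catalog optional `zf_catalog` for name lookup.
#' @param threshold similarity floor for assigning a label (default 0.5).
#' @param offsets contact-residue offsets, shared by all profiles.
#' @return object of class `type_score`: list with `sim_A`, `sim_C`, `label`.
#' @export
classify_type <- function(allele, refA, refC, catalog = NULL,
                          threshold = 0.5, offsets = NULL) {
  q <- contact_profile(allele, catalog, offsets)
  a <- contact_profile(refA, catalog, q$offsets)
  c_ <- contact_profile(refC, catalog, q$offsets)
  sim_A <- token_alignment_score(q$triplets, a$triplets) / length(a$triplets)
  sim_C <- token_alignment_score(q$triplets, c_$triplets) /
    length(c_$triplets)
  label <- if (max(sim_A, sim_C) < threshold || sim_A == sim_C) "untyped"
  else if (sim_A > sim_C) "A-type" else "C-type"
  structure(list(sim_A = sim_A, sim_C = sim_C, label = label),
            class = "type_score")
}

#' Label every catalog allele as A-type or C-type
#'
#' @param catalog a `zf_catalog` containing the reference alleles.
#' @param refA,refC names of the reference alleles (default "A" and "C").
#' @inheritParams classify_type
#' @return list with `catalog` (type_label column filled) and `scores`
#'   (data.frame allele/sim_A/sim_C/label).
#' @export
classify_catalog <- function(catalog, refA = "A", refC = "C",
                             threshold = 0.5, offsets = NULL) {
  pa <- contact_profile(refA, catalog, offsets)
  pc <- contact_profile(refC, catalog, pa$offsets)
  scores <- do.call(rbind, lapply(catalog$alleles$name, function(nm) {
    q <- contact_profile(nm, catalog, pa$offsets)
    sim_A <- token_alignment_score(q$triplets, pa$triplets) /
      length(pa$triplets)
    sim_C <- token_alignment_score(q$triplets, pc$triplets) /
      length(pc$triplets)
    label <- if (max(sim_A, sim_C) < threshold || sim_A == sim_C) "untyped"
    else if (sim_A > sim_C) "A-type" else "C-type"
    data.frame(allele = nm, sim_A = sim_A, sim_C = sim_C,
               label = label, stringsAsFactors = FALSE)
  }))
  catalog$alleles$type_label <- scores$label
  list(catalog = catalog, scores = scores)
}

#' Array-length statistics by allele type
#'
#' Median finger count per type label plus a two-sample Wilcoxon rank-sum
#' test (two-sided, normal approximation with continuity and tie
#' correction).
#'
#' @param catalog a `zf_catalog` with type labels, or NULL when `lengths`
#'   and `labels` are given directly.
#' @param lengths,labels finger counts and type labels (overriding
#'   `catalog`).
#' @return list with `medians` (named by label) and `p_value`.
#' @export
length_stats <- function(catalog = NULL, lengths = NULL, labels = NULL) {
  if (is.null(lengths)) {
    stopifnot(!is.null(catalog))
    lengths <- nchar(catalog$alleles$dna) / ZF_UNIT_NT
    labels <- catalog$alleles$type_label
  }
  keep <- labels %in% c("A-type", "C-type")
  lengths <- lengths[keep]; labels <- labels[keep]
  if (!all(c("A-type", "C-type") %in% labels))
    stop("need at least one allele of each type")
  med <- tapply(lengths, labels, median)
  wt <- suppressWarnings(
    wilcox.test(lengths[labels == "A-type"], lengths[labels == "C-type"],
                exact = FALSE, correct = TRUE))
  list(medians = med, p_value = wt$p.value)
}

check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("individual", "population", "allele1", "allele2")
                %in% names(cohort)))
  if ("qc" %in% names(cohort)) {
    dropped <- cohort$individual[cohort$qc != "pass"]
    if (length(dropped))
      message("excluding ", length(dropped), " qc-failed individual(s)")
    cohort <- cohort[cohort$qc == "pass", , drop = FALSE]
  }
  cohort
}

#' Per-population allele frequencies with exact 99% confidence intervals
#'
#' Each qc-pass individual contributes two alleles; frequencies are allele
#' counts over 2N with Clopper-Pearson 99% binomial confidence intervals.
#'
#' @param cohort data.frame with columns individual, population, allele1,
#'   allele2 and optionally qc ("pass" rows kept).
#' @param conf.level confidence level (default 0.99).
#' @return data.frame population/allele/count/frequency/ci_lower/ci_upper.
#' @export
allele_frequencies <- function(cohort, conf.level = 0.99) {
  cohort <- check_cohort(cohort)
  out <- lapply(split(cohort, cohort$population), function(pc) {
    alleles <- c(pc$allele1, pc$allele2)
    tab <- sort(table(alleles), decreasing = TRUE)
    n <- sum(tab)
    do.call(rbind, lapply(names(tab), function(a) {
      ct <- as.integer(tab[[a]])
      ci <- binom.test(ct, n, conf.level = conf.level)$conf.int
      data.frame(population = pc$population[1], allele = a, count = ct,
                 frequency = ct / n, ci_lower = ci[1], ci_upper = ci[2],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fraction of heterozygous individuals per population
#'
#' @inheritParams allele_frequencies
#' @return data.frame population/n/heterozygosity.
#' @export
heterozygosity <- function(cohort) {
  cohort <- check_cohort(cohort)
  out <- do.call(rbind, lapply(split(cohort, cohort$population),
                               function(pc) {
    data.frame(population = pc$population[1], n = nrow(pc),
               heterozygosity = mean(pc$allele1 != pc$allele2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

as_allele_pair <- function(g) {
  if (inherits(g, "diploid_genotype")) {
    p <- genotype_dnas(g)
    if (length(p) != 2L || anyNA(p)) stop("genotype is not qc-pass")
    return(p)
  }
  stopifnot(length(g) == 2L)
  as.character(g)
}

#' Mendelian consistency of a child genotype with its parents
#'
#' Consistent when the child's allele pair can be split as one allele from
#' the mother's pair and one from the father's.
#'
#' @param child,mother,father allele pairs (length-2 character vectors of
#'   allele sequences or names) or qc-pass `diploid_genotype`s.
#' @return list with `consistent` and `phase` (data.frame child_allele /
#'   parent for one consistent assignment, or NULL).
#' @export
trio_concordance <- function(child, mother, father) {
  ch <- as_allele_pair(child); mo <- as_allele_pair(mother)
  fa <- as_allele_pair(father)
  for (perm in list(c(1L, 2L), c(2L, 1L))) {
    if (ch[perm[1]] %in% mo && ch[perm[2]] %in% fa)
      return(list(consistent = TRUE,
                  phase = data.frame(child_allele = ch[perm],
                                     parent = c("mother", "father"),
                                     stringsAsFactors = FALSE)))
  }
  list(consistent = FALSE, phase = NULL)
}

pair_category <- function(a1, a2) {
  if (a1 == a2) "hom"
  else if (nchar(a1) == nchar(a2)) "het_equal"
  else "het_unequal"
}

#' Concordance between two sets of diploid genotype calls
#'
#' Individuals present in both sets are compared as unordered allele pairs;
#' concordance is reported per zygosity category and overall, and discordant
#' individuals are flagged when the two calls share one allele.
#'
#' @param set1,set2 data.frames with columns individual, allele1, allele2
#'   (allele sequences, or names when a `category` column is supplied).
#' @return list with `overall_pct`, `by_category` (data.frame), `n` and
#'   `discordant` (data.frame with shared_allele flag).
#' @export
compare_genotype_sets <- function(set1, set2) {
  stopifnot(all(c("individual", "allele1", "allele2") %in% names(set1)),
            all(c("individual", "allele1", "allele2") %in% names(set2)))
  ids <- intersect(set1$individual, set2$individual)
  i1 <- match(ids, set1$individual); i2 <- match(ids, set2$individual)
  cat_of <- function(df, i) {
    if ("category" %in% names(df)) df$category[i]
    else pair_category(df$allele1[i], df$allele2[i])
  }
  rows <- lapply(seq_along(ids), function(k) {
    p1 <- sort(c(set1$allele1[i1[k]], set1$allele2[i1[k]]))
    p2 <- sort(c(set2$allele1[i2[k]], set2$allele2[i2[k]]))
    data.frame(individual = ids[k], category = cat_of(set1, i1[k]),
               concordant = identical(p1, p2),
               shared_allele = length(intersect(p1, p2)) >= 1L,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  by_cat <- do.call(rbind, lapply(split(rows, rows$category), function(rc) {
    data.frame(category = rc$category[1], n = nrow(rc),
               concordance_pct = 100 * mean(rc$concordant),
               stringsAsFactors = FALSE)
  }))
  rownames(by_cat) <- NULL
  list(overall_pct = 100 * mean(rows$concordant), n = nrow(rows),
       by_category = by_cat,
       discordant = rows[!rows$concordant, , drop = FALSE])
}
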