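# Per-sample pipeline orchestration and report writing.

#' Genotype one sample from raw reads
#'
#' Runs extraction (flank anchoring + unit tiling) over the reads, applies
#' the coverage gate and the genotyper, and records the counts at every
#' filter stage.
#'
#' @param reads named character vector (or DNAStringSet) of reads for one
#'   individual (already demultiplexed).
#' @param catalog a `zf_catalog`.
#' @param anchors a [flank_anchors()].
#' @param individual identifier.
#' @param min_coverage coverage gate (default 100).
#' @param ... further arguments to [call_genotype()].
#' @return list with `genotype`, `catalog` (possibly extended), `stages`
#'   (named counts: reads_in, retained, plus one count per rejection
#'   reason) and `rejections`.
#' @export
genotype_sample <- function(reads, catalog, anchors = flank_anchors(),
                            individual = "sample", min_coverage = 100L,
                            ...) {
  ex <- extract_arrays(reads, anchors, catalog)
  stages <- c(reads_in = length(reads),
              retained = length(ex$observations))
  if (nrow(ex$rejections)) {
    tab <- table(ex$rejections$reason)
    stages <- c(stages, setNames(as.integer(tab), names(tab)))
  }
  res <- call_genotype(ex$observations, catalog, individual = individual,
                       min_coverage = min_coverage, ...)
  list(genotype = res$genotype, catalog = res$catalog, stages = stages,
       rejections = ex$rejections)
}

#' Simulate, demultiplex and genotype a cohort, scoring allele recovery
#'
#' Full pipeline round trip: reads for `n_individuals` simulated diploid
#' genotypes are pooled, demultiplexed by their dual barcodes, extracted and
#' genotyped; each called allele is compared with the simulated truth.
#'
#' @param catalog a `zf_catalog` the true genotypes are drawn from.
#' @param n_individuals,coverage cohort size and reads per individual.
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @param min_coverage coverage gate passed to [call_genotype()].
#' @param anchors a [flank_anchors()].
#' @return list with `per_individual` (data.frame individual / true alleles /
#'   called alleles / n_recovered / qc), `allele_recovery` (fraction of the
#'   2 x n true alleles called exactly) and `genotypes`.
#' @export
run_recovery_experiment <- function(catalog, n_individuals = 20L,
                                    coverage = 150L, em = error_model(),
                                    seed = 1L, min_coverage = 100L,
                                    anchors = flank_anchors()) {
  sim <- simulate_individuals(catalog, n_individuals, coverage, em,
                              anchors = anchors, seed = seed)
  pooled <- unlist(lapply(sim$individuals, `[[`, "reads"))
  dmx <- demultiplex(pooled, sim$scheme)
  rows <- list(); genotypes <- list()
  for (ind in sim$individuals) {
    ids <- dmx$samples[[ind$sample]]
    reads <- pooled[ids]
    res <- genotype_sample(reads, catalog, anchors, individual = ind$id,
                           min_coverage = min_coverage)
    g <- res$genotype
    called <- if (is.null(g$alleles)) character(0)
              else vapply(g$alleles, function(a)
                if (is.na(a$dna)) "" else a$dna, character(1))
    truth <- ind$hap_dnas
    # match each true allele against the called pair without reuse
    avail <- called
    n_rec <- 0L
    for (d in truth) {
      hit <- match(d, avail)
      if (!is.na(hit)) { n_rec <- n_rec + 1L; avail <- avail[-hit] }
    }
    genotypes[[ind$id]] <- g
    rows[[ind$id]] <- data.frame(
      individual = ind$id, true1 = ind$alleles[1], true2 = ind$alleles[2],
      n_recovered = n_rec, qc = g$qc, stringsAsFactors = FALSE)
  }
  per_individual <- do.call(rbind, rows)
  rownames(per_individual) <- NULL
  list(per_individual = per_individual,
       allele_recovery = sum(per_individual$n_recovered) /
         (2L * n_individuals),
       genotypes = genotypes)
}

genotype_report <- function(genotype, stages = NULL) {
  rep <- list(individual = genotype$individual, qc = genotype$qc,
              zygosity = genotype$zygosity, rule = genotype$rule,
              reason = genotype$reason, n_reads = genotype$n_reads,
              alleles = lapply(genotype$alleles, function(a)
                list(name = a$name, zf_codes = a$codes, dna = a$dna,
                     support = a$support, qc = a$qc, reason = a$reason)))
  if (!is.null(stages)) rep$stages <- as.list(stages)
  rep
}

#' Write a genotype report as JSON
#'
#' @param genotype a `diploid_genotype`.
#' @param path output path.
#' @param stages optional named stage counts from [genotype_sample()].
#' @export
write_genotype_report <- function(genotype, path, stages = NULL) {
  jsonlite::write_json(genotype_report(genotype, stages), path,
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Cohort table of allele calls
#'
#' @param genotypes list of `diploid_genotype`s.
#' @return data.frame, one row per allele call (individual, zygosity, rule,
#'   allele name, n_zf, support, qc).
#' @export
cohort_allele_table <- function(genotypes) {
  rows <- list()
  for (g in genotypes) {
    if (is.null(g$alleles)) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual = g$individual, zygosity = NA_character_,
        rule = NA_integer_, allele = NA_character_, n_zf = NA_integer_,
        support = NA_integer_, qc = g$qc, reason = g$reason,
        stringsAsFactors = FALSE)
      next
    }
    for (a in g$alleles)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = g$individual, zygosity = g$zygosity, rule = g$rule,
        allele = a$name,
        n_zf = if (is.na(a$dna)) NA_integer_
               else nchar(a$dna) %/% ZF_UNIT_NT,
        support = a$support, qc = a$qc, reason = a$reason,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
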