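test_that("length-frequency labels are deterministic under ties", {
  tab <- length_frequency_table(c(13L, 13L, 12L, 12L, 14L))
  expect_equal(tab$n_units[1:2], c(12L, 13L))  # tie broken to smaller count
  expect_equal(sum(tab$freq), 1)
  expect_true(all(diff(tab$count) <= 0))
})

test_that("the five length rules fire on their worked examples", {
  rule_of <- function(freqs) {
    counts <- round(freqs * 1000)
    infer_lengths(rep(as.integer(names(counts)), counts))
  }
  r <- rule_of(c("13" = 1.0))
  expect_equal(r$rule, 1L); expect_equal(r$hap_lengths, c(13L, 13L))
  r <- rule_of(c("13" = 0.40, "14" = 0.35, "15" = 0.25))
  expect_equal(r$rule, 2L); expect_equal(r$hap_lengths, c(13L, 14L))
  r <- rule_of(c("14" = 0.50, "13" = 0.22, "12" = 0.08, "11" = 0.08,
                 "10" = 0.08, "9" = 0.04))
  expect_equal(r$rule, 3L); expect_equal(r$hap_lengths, c(14L, 13L))
  r <- rule_of(c("13" = 0.72, "12" = 0.20, "14" = 0.08))
  expect_equal(r$rule, 4L); expect_equal(r$hap_lengths, c(13L, 13L))
  # a frequency ratio of exactly 3 escapes rules 3 and 4, landing on rule 5
  r <- rule_of(c("13" = 0.72, "12" = 0.24, "14" = 0.04))
  expect_equal(r$rule, 5L); expect_equal(r$hap_lengths, c(13L, 13L))
  r <- rule_of(c("13" = 0.40, "12" = 0.25, "14" = 0.20, "11" = 0.15))
  expect_true(is.na(r$rule))
})

test_that("rule engine matches the independent tracer on random tables", {
  set.seed(17)
  for (i in 1:500) {
    k <- sample(1:5, 1)
    lens <- sample(8:20, k)
    counts <- as.integer(sample(1:50, k, replace = TRUE))
    n_units <- rep(lens, counts)
    got <- infer_lengths(n_units)
    freqs <- setNames(as.numeric(counts) / sum(counts), lens)
    want <- trace_length_rules(freqs)
    expect_identical(got$rule, want$rule,
                     info = paste(lens, counts, collapse = " "))
    expect_identical(got$hap_lengths, want$hap)
  }
})

test_that("consensus frequencies exclude Ns from the denominator", {
  prof <- build_consensus(rep("ACGT", 10))
  expect_identical(prof$consensus, "ACGT")
  expect_equal(prof$f_c, rep(1, 4))

  arrays <- c(rep("AA", 7), rep("CA", 3))
  prof <- build_consensus(arrays)
  expect_identical(prof$consensus, "AA")
  expect_equal(prof$f_c[1], 0.7)

  arrays <- c(rep("A", 4), rep("C", 4), rep("N", 2))
  prof <- build_consensus(arrays)
  expect_equal(prof$f_c[1], 0.5)      # 4 / 8, Ns excluded
  expect_equal(prof$depth[1], 8)

  prof <- build_consensus(c("N", "N"))
  expect_identical(prof$consensus, "N")
  expect_true(is.na(prof$f_c[1]))
})

test_that("equal-length phasing separates two haplotypes", {
  set.seed(23)
  base <- random_dna(420)
  other <- base
  for (p in c(50, 200, 390))
    substr(other, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(other, p, p)), 1)
  arrays <- c(rep(base, 25), rep(other, 25))
  ph <- phase_equal_length(sample(arrays))
  expect_identical(ph$status, "het")
  expect_setequal(ph$consensi, c(base, other))
  expect_equal(sort(ph$supports), c(25L, 25L))

  # identical input is homozygous
  ph <- phase_equal_length(rep(base, 20))
  expect_identical(ph$status, "hom")
  expect_identical(ph$consensi, base)

  # stray error sequences form small clusters that are ignored
  stray <- vapply(1:3, function(i) {
    s <- base
    for (p in sample(420, 6))
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    s
  }, character(1))
  ph <- phase_equal_length(c(arrays, stray))
  expect_identical(ph$status, "het")
  expect_setequal(ph$consensi, c(base, other))
})

test_that("coverage gate fires below 100 reads", {
  expect_false(coverage_gate(99))
  expect_true(coverage_gate(100))
  expect_false(coverage_gate(0))
  expect_false(coverage_gate(list()))
})

test_that("genotypes are called for hom, unequal-het and 1-nt equal-het", {
  cat0 <- small_catalog()
  anchors <- flank_anchors()
  em <- error_model()  # default: 1% sub, 0.5% ins, 0.5% del, 10% slippage

  # unequal-length heterozygote
  dnas <- c(allele_dna(cat0, "S1"), allele_dna(cat0, "S3"))
  expect_true(nchar(dnas[1]) != nchar(dnas[2]))
  sim <- simulate_reads(dnas, coverage = 150, em = em, seed = 61)
  ex <- extract_arrays(sim$reads, anchors, cat0)
  res <- call_genotype(ex$observations, cat0)
  expect_identical(res$genotype$qc, "pass")
  expect_identical(res$genotype$zygosity, "het_unequal_length")
  expect_setequal(vapply(res$genotype$alleles, `[[`, "", "dna"), dnas)
  expect_setequal(vapply(res$genotype$alleles, `[[`, "", "name"),
                  c("S1", "S3"))

  # homozygote
  sim <- simulate_reads(dnas[1], coverage = 150, em = em, seed = 62)
  ex <- extract_arrays(sim$reads, anchors, cat0)
  res <- call_genotype(ex$observations, cat0)
  expect_identical(res$genotype$zygosity, "hom")
  expect_identical(res$genotype$alleles[[1]]$dna, dnas[1])
  expect_identical(res$genotype$alleles[[2]]$dna, dnas[1])

  # equal-length heterozygote differing at a single nucleotide
  one <- dnas[1]
  substr(one, 500, 500) <- if (substr(one, 500, 500) == "A") "G" else "A"
  enc <- encode_allele(one, cat0)
  cat1 <- enc$catalog
  sim <- simulate_reads(c(dnas[1], one), coverage = 150, em = em, seed = 63)
  ex <- extract_arrays(sim$reads, anchors, cat1)
  res <- call_genotype(ex$observations, cat1)
  expect_identical(res$genotype$qc, "pass")
  expect_identical(res$genotype$zygosity, "het_equal_length")
  expect_setequal(vapply(res$genotype$alleles, `[[`, "", "dna"),
                  c(dnas[1], one))
})

test_that("hom and het paths agree on duplicated single-allele data", {
  cat0 <- small_catalog()
  sim <- simulate_reads(rep(allele_dna(cat0, "S2"), 2), coverage = 120,
                        em = zero_error_model(), seed = 64)
  ex <- extract_arrays(sim$reads, flank_anchors(), cat0)
  res <- call_genotype(ex$observations, cat0)
  expect_identical(res$genotype$zygosity, "hom")
  expect_identical(res$genotype$alleles[[1]]$dna, allele_dna(cat0, "S2"))
})

test_that("low coverage and uncallable length tables fail qc with reasons", {
  cat0 <- small_catalog()
  res <- call_genotype(list(), cat0)
  expect_identical(res$genotype$qc, "fail")
  expect_identical(res$genotype$reason, "low_coverage")

  # ambiguous length mixture -> no call
  obs <- lapply(1:120, function(i)
    structure(list(read_id = paste0("r", i),
                   n_units = c(10L, 11L, 12L, 13L)[(i %% 4) + 1L],
                   units = rep(strrep("A", 84), 10L)),
              class = "array_observation"))
  res <- call_genotype(obs, cat0)
  expect_identical(res$genotype$qc, "fail")
  expect_identical(res$genotype$reason, "length_no_call")
})

test_that("novel alleles found during calling are minted M names", {
  cat0 <- small_catalog()
  novel <- allele_dna(cat0, "S1")
  substr(novel, 100, 100) <- if (substr(novel, 100, 100) == "A") "T" else "A"
  sim <- simulate_reads(novel, coverage = 120, em = zero_error_model(),
                        seed = 65)
  ex <- extract_arrays(sim$reads, flank_anchors(), cat0)
  res <- call_genotype(ex$observations, cat0)
  expect_identical(res$genotype$alleles[[1]]$name, "M1")
  expect_identical(allele_dna(res$catalog, "M1"), novel)
  expect_true(any(res$catalog$fingers$is_novel))
})

test_that("platform merging compares unordered allele pairs", {
  g <- function(d1, d2, zyg) structure(
    list(individual = "x",
         alleles = list(list(dna = d1, qc = "pass"),
                        list(dna = d2, qc = "pass")),
         zygosity = zyg, qc = "pass"),
    class = "diploid_genotype")
  a <- g("AAA", "CCC", "het_unequal_length")
  b <- g("CCC", "AAA", "het_unequal_length")
  m <- merge_platform_calls(a, b)
  expect_true(m$concordant)
  expect_identical(m$category, "het_unequal")
  m <- merge_platform_calls(a, g("AAA", "GGG", "het_unequal_length"))
  expect_false(m$concordant)
  expect_true(m$shared_allele)
  m <- merge_platform_calls(a, g("TTT", "GGG", "het_unequal_length"))
  expect_false(m$concordant)
  expect_false(m$shared_allele)
})
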