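test_that("contact offsets anchor on the conserved histidine pair", {
  aa <- paste(zfarray:::SCAFFOLD_AA, collapse = "")
  expect_equal(contact_offsets(aa), c(16L, 20L, 23L))
  expect_error(contact_offsets(gsub("H", "A", aa)), "histidine")
})

test_that("contact profiles are a function of the finger codes only", {
  cat0 <- ref_catalog()
  pA <- contact_profile("A", cat0)
  expect_length(pA$triplets, 13L)
  expect_true(all(nchar(pA$triplets) == 3L))
  # B differs from A by one amino acid off the contact residues
  pB <- contact_profile("B", cat0)
  expect_lte(sum(pA$triplets != pB$triplets), 1L)
  # an allele of n identical fingers has n identical tokens
  one <- cat0$fingers$dna[cat0$fingers$code == "aC"]
  p <- contact_profile(strrep(one, 5))
  expect_length(unique(p$triplets), 1L)
  # L14 keeps C's contact profile intact
  expect_identical(contact_profile("L14", cat0)$triplets,
                   contact_profile("C", cat0)$triplets)
})

test_that("type classification is reflexive and recovers the references", {
  cat0 <- ref_catalog()
  tsA <- classify_type("A", "A", "C", cat0)
  expect_equal(tsA$sim_A, 1)
  expect_identical(tsA$label, "A-type")
  tsC <- classify_type("C", "A", "C", cat0)
  expect_equal(tsC$sim_C, 1)
  expect_identical(tsC$label, "C-type")
  expect_identical(classify_type("L14", "A", "C", cat0)$label, "C-type")
  expect_identical(classify_type("L4", "A", "C", cat0)$label, "C-type")
  expect_identical(classify_type("N", "A", "C", cat0)$label, "A-type")
})

test_that("classification is stable under finger-code renaming", {
  cat0 <- ref_catalog()
  # classify from raw dna (no codes at all): same labels
  for (nm in c("B", "L4", "M1")) {
    by_name <- classify_type(nm, "A", "C", cat0)
    by_dna <- classify_type(allele_dna(cat0, nm), allele_dna(cat0, "A"),
                            allele_dna(cat0, "C"))
    expect_identical(by_name$label, by_dna$label)
    expect_equal(by_name$sim_A, by_dna$sim_A)
  }
})

test_that("length statistics give per-type medians and a rank-sum p", {
  ls <- length_stats(lengths = c(13, 13, 13, 15, 15),
                     labels = c(rep("A-type", 3), rep("C-type", 2)))
  expect_equal(unname(ls$medians["A-type"]), 13)
  expect_equal(unname(ls$medians["C-type"]), 15)
  # identical groups: p close to 1 under the normal approximation
  ls <- length_stats(lengths = rep(c(13, 14, 15), 2),
                     labels = rep(c("A-type", "C-type"), each = 3))
  expect_gte(ls$p_value, 0.9)
  expect_error(length_stats(lengths = c(13, 13), labels = rep("A-type", 2)),
               "each type")
})

test_that("allele frequencies count two alleles per individual with CIs", {
  cohort <- data.frame(
    individual = paste0("i", 1:4), population = "POP",
    allele1 = c("A", "A", "A", "A"), allele2 = c("A", "A", "A", "C"),
    stringsAsFactors = FALSE)
  fr <- allele_frequencies(cohort)
  expect_equal(fr$frequency[fr$allele == "A"], 7 / 8)
  expect_equal(fr$frequency[fr$allele == "C"], 1 / 8)
  expect_equal(sum(fr$frequency), 1)
  expect_true(all(fr$ci_lower <= fr$frequency & fr$frequency <= fr$ci_upper))
  # oracle: Clopper-Pearson bounds from binom.test
  ci <- binom.test(7, 8, conf.level = 0.99)$conf.int
  expect_equal(fr$ci_lower[fr$allele == "A"], ci[1])
  expect_equal(fr$ci_upper[fr$allele == "A"], ci[2])
  # qc-failed individuals are excluded
  cohort$qc <- c("pass", "pass", "fail", "pass")
  expect_message(fr2 <- allele_frequencies(cohort), "excluding 1")
  expect_equal(sum(fr2$count), 6)
})

test_that("heterozygosity is the fraction of differing allele pairs", {
  cohort <- data.frame(
    individual = paste0("i", 1:4), population = "P1",
    allele1 = c("A", "A", "B", "C"), allele2 = c("A", "B", "C", "C"))
  h <- heterozygosity(cohort)
  expect_equal(h$heterozygosity, 0.5)
  cohort$allele2 <- cohort$allele1
  expect_equal(heterozygosity(cohort)$heterozygosity, 0)
  cohort$allele2 <- c("X", "Y", "Z", "W")
  expect_equal(heterozygosity(cohort)$heterozygosity, 1)
})

test_that("trio consistency matches brute-force enumeration", {
  expect_true(trio_concordance(c("A", "C"), c("A", "A"),
                               c("C", "L14"))$consistent)
  expect_false(trio_concordance(c("B", "B"), c("A", "C"),
                                c("A", "C"))$consistent)
  expect_true(trio_concordance(c("A", "A"), c("A", "C"),
                               c("A", "B"))$consistent)
  # brute force over random trios
  brute <- function(ch, mo, fa) {
    any(vapply(1:2, function(i) ch[i] %in% mo && ch[3 - i] %in% fa,
               logical(1)))
  }
  set.seed(41)
  pool <- LETTERS[1:5]
  for (i in 1:200) {
    ch <- sample(pool, 2, replace = TRUE)
    mo <- sample(pool, 2, replace = TRUE)
    fa <- sample(pool, 2, replace = TRUE)
    expect_identical(trio_concordance(ch, mo, fa)$consistent,
                     brute(ch, mo, fa),
                     info = paste(ch, mo, fa, collapse = "/"))
  }
})

test_that("genotype-set concordance is scored per category and overall", {
  set.seed(43)
  n <- 461L
  alle <- replicate(n, sort(sample(c(strrep("A", 84), strrep("C", 84),
                                     strrep("G", 168)), 2, replace = TRUE)))
  set1 <- data.frame(individual = paste0("i", 1:n),
                     allele1 = alle[1, ], allele2 = alle[2, ],
                     stringsAsFactors = FALSE)
  set2 <- set1
  flip <- sample(n, 13)  # 13 discordant of 461
  set2$allele1[flip] <- strrep("T", 84)
  res <- compare_genotype_sets(set1, set2)
  expect_equal(res$n, 461L)
  expect_equal(round(res$overall_pct, 1), 97.2)
  expect_equal(nrow(res$discordant), 13L)
  expect_true(all(res$by_category$concordance_pct <= 100))
  # identical and disjoint sets
  expect_equal(compare_genotype_sets(set1, set1)$overall_pct, 100)
  set3 <- set1
  set3$allele1 <- strrep("T", 84); set3$allele2 <- strrep("T", 84)
  expect_equal(compare_genotype_sets(set1, set3)$overall_pct, 0)
})
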