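test_that("demultiplexing assigns uniquely within mismatch budgets", {
  set.seed(5)
  outer <- c(vapply(1:4, function(i) random_dna(24), character(1)))
  scheme <- barcode_scheme(outer = outer)
  insert <- random_dna(300)
  mk <- function(o, i) paste0(o, i, insert, revcomp(i), revcomp(o))
  reads <- c(
    exact = mk(outer[2], INNER_BARCODES[3]),
    onemm = {
      b <- INNER_BARCODES[5]; substr(b, 4, 4) <- "T"
      mk(outer[1], b)
    },
    rc = revcomp(mk(outer[3], INNER_BARCODES[1])),
    none = paste0(random_dna(36), insert))
  res <- demultiplex(reads, scheme)
  expect_identical(res$assignments$sample[1], "02_3")
  expect_identical(res$assignments$sample[2], "01_5")
  expect_identical(res$assignments$sample[3], "03_1")
  expect_identical(res$unassigned, "none")
  # conservation: every read is assigned or unassigned
  expect_equal(length(unlist(res$samples)) + length(res$unassigned),
               length(reads))
})

test_that("ambiguous barcode ties go to the unassigned bin", {
  # two identical-up-to-budget outer barcodes make the pair ambiguous
  outer <- c("AAAAAAAAAAAA", "AAAAAAAAAAAT", "GGGGGGGGGGGG")
  scheme <- barcode_scheme(outer = outer, max_mismatch_outer = 2L)
  read <- paste0(outer[1], INNER_BARCODES[1], random_dna(200),
                 revcomp(INNER_BARCODES[1]), revcomp(outer[1]))
  res <- demultiplex(c(amb = read), scheme)
  expect_identical(res$unassigned, "amb")
})

test_that("find_flank matches the local-alignment oracle", {
  anchors <- flank_anchors()
  set.seed(21)
  read <- paste0(random_dna(120), anchors$flank5, random_dna(400))
  hit <- find_flank(read, anchors$flank5)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$start, 120)
  expect_equal(hit$end, 120 + nchar(anchors$flank5))
  expect_identical(hit$strand, "+")

  # embedded with 5% substitutions: found at high identity, and the hit
  # interval agrees with Biostrings pairwiseAlignment
  mut <- anchors$flank5
  pos <- sample(nchar(mut), round(0.05 * nchar(mut)))
  for (p in pos)
    substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(mut, p, p)), 1)
  read2 <- paste0(random_dna(150), mut, random_dna(300))
  hit2 <- find_flank(read2, anchors$flank5)
  expect_gte(hit2$identity, 0.9)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  ora <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(anchors$flank5), Biostrings::DNAString(read2),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  expect_equal(hit2$score, Biostrings::score(ora))
  expect_equal(hit2$start,
               Biostrings::start(Biostrings::subject(ora)) - 1L)

  # random sequence: no hit at the identity/span gates
  expect_null(find_flank(random_dna(500), anchors$flank5,
                         min_identity = 0.8))

  # reverse-complemented read is found on the minus strand
  hit3 <- find_flank(revcomp(read), anchors$flank5)
  expect_identical(hit3$strand, "-")
  expect_equal(hit3$start, 120)
})

test_that("extract_array recovers a clean 13-finger array", {
  cat0 <- ref_catalog()
  arr <- allele_dna(cat0, "A")
  expect_equal(nchar(arr), 1092L)
  obs <- extract_array(make_read(arr), flank_anchors(), cat0)
  expect_s3_class(obs, "array_observation")
  expect_equal(obs$n_units, 13L)
  expect_identical(obs$array_dna, arr)
  expect_identical(paste(obs$units, collapse = ""), arr)
  expect_identical(obs$strand, "+")
  # same read, minus strand
  obs2 <- extract_array(revcomp(make_read(arr)), flank_anchors(), cat0)
  expect_identical(obs2$strand, "-")
  expect_identical(obs2$array_dna, arr)
})

test_that("extraction rejections carry the expected reasons", {
  cat0 <- small_catalog()
  anchors <- flank_anchors()
  arr <- allele_dna(cat0, "S1")
  # missing 3' flank
  r <- extract_array(paste0("GAT", anchors$flank5, arr), anchors, cat0)
  expect_s3_class(r, "array_rejection")
  expect_identical(r$reason, "no_flank3")
  # missing 5' flank
  r <- extract_array(paste0(arr, anchors$flank3), anchors, cat0)
  expect_identical(r$reason, "no_flank5")
  # flanks out of order
  r <- extract_array(paste0(anchors$flank3, arr, anchors$flank5),
                     anchors, cat0)
  expect_identical(r$reason, "disordered_flanks")
  # non-array sequence between the flanks
  set.seed(31)
  r <- extract_array(make_read(paste0(arr, random_dna(40))), anchors, cat0)
  expect_identical(r$reason, "non_contiguous_array")
})

test_that("tiling pads read deletions with Ns and rejects insertions", {
  cat0 <- small_catalog()
  arr <- allele_dna(cat0, "S2")
  # 10-nt deletion inside unit 2
  mut <- paste0(substr(arr, 1, 84 + 30), substr(arr, 84 + 41, nchar(arr)))
  obs <- extract_array(make_read(mut), flank_anchors(), cat0)
  expect_s3_class(obs, "array_observation")
  expect_equal(unique(nchar(obs$units)), 84L)
  expect_equal(sum(strsplit(obs$units[2], "")[[1]] == "N"), 10L)
  expect_identical(gsub("N", "", obs$units[2]),
                   paste0(substr(arr, 85, 114), substr(arr, 125, 168)))
  # a 40-nt foreign insertion between units fails tiling
  set.seed(8)
  ins <- paste0(substr(arr, 1, 168), random_dna(40),
                substr(arr, 169, nchar(arr)))
  r <- extract_array(make_read(ins), flank_anchors(), cat0)
  expect_identical(r$reason, "non_contiguous_array")
})

test_that("error-free reads are all extracted with the true unit count", {
  cat0 <- small_catalog()
  dnas <- c(allele_dna(cat0, "S1"), allele_dna(cat0, "S3"))
  sim <- simulate_reads(dnas, coverage = 30, em = zero_error_model(),
                        seed = 12)
  ex <- extract_arrays(sim$reads, flank_anchors(), cat0)
  expect_equal(length(ex$observations), 30L)
  nu <- vapply(ex$observations, function(o) o$n_units, integer(1))
  truth_nu <- nchar(dnas[sim$truth$haplotype]) / 84
  ids <- vapply(ex$observations, function(o) o$read_id, character(1))
  expect_equal(nu, truth_nu[match(ids, sim$truth$read_id)])
  # every accepted observation is whole-unit
  expect_true(all(vapply(ex$observations, function(o)
    all(nchar(o$units) == 84L), logical(1))))
})

test_that("slippage reads survive extraction with shifted unit counts", {
  cat0 <- small_catalog()
  em <- error_model(substitution = 0, insertion = 0, deletion = 0,
                    slippage = 0.9, truncation = 0)
  sim <- simulate_reads(allele_dna(cat0, "S4"), coverage = 15, em = em,
                        seed = 13)
  ex <- extract_arrays(sim$reads, flank_anchors(), cat0)
  expect_equal(length(ex$observations), 15L)
  expect_gt(sum(sim$truth$slipped), 0L)
  nu <- vapply(ex$observations, function(o) o$n_units, integer(1))
  true_n <- nchar(allele_dna(cat0, "S4")) / 84
  ids <- vapply(ex$observations, function(o) o$read_id, character(1))
  shifts <- sim$truth$shift[match(ids, sim$truth$read_id)]
  expect_equal(nu, true_n + shifts)
})
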