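test_that("a child identical to a parent needs zero switches", {
  set.seed(51)
  p1 <- random_dna(600); p2 <- random_dna(600)
  path <- greedy_switch_path(p1, p1, p2)
  expect_equal(path$n_switches, 0L)
  expect_equal(nrow(path$segments), 1L)
  expect_identical(switch_path_sequence(path), p1)
  expect_equal(min_switches_dp(p1, p1, p2), 0L)
})

test_that("a planted junction in unique context yields one switch", {
  set.seed(52)
  p1 <- random_dna(700); p2 <- random_dna(700)
  child <- paste0(substr(p1, 1, 200), substr(p2, 201, 700))
  path <- greedy_switch_path(child, p1, p2)
  expect_equal(path$n_switches, 1L)
  expect_identical(switch_path_sequence(path), child)
  expect_equal(min_switches_dp(child, p1, p2), 1L)
  # unreachable child
  expect_null(greedy_switch_path(random_dna(400), p1, p2))
  expect_identical(min_switches_dp(random_dna(400), p1, p2), Inf)
})

test_that("planted k-switch recombinants are recovered exactly by the dp", {
  set.seed(53)
  for (i in 1:40) {
    k <- sample(0:5, 1)
    p1 <- random_dna(sample(400:800, 1))
    p2 <- random_dna(sample(400:800, 1))
    sim <- simulate_recombinant(p1, p2, k, seed = i)
    expect_identical(switch_path_sequence(sim$path), sim$child)
    dp <- min_switches_dp(sim$child, p1, p2)
    expect_equal(dp, k, info = paste("k =", k, "i =", i))
    g <- greedy_switch_path(sim$child, p1, p2)
    expect_false(is.null(g))
    expect_gte(g$n_switches, dp)
    expect_equal(g$n_switches, dp)  # junctions are unique in random parents
  }
})

test_that("greedy paths are valid and never beat the dp oracle", {
  set.seed(54)
  for (i in 1:60) {
    # homologous parents: shuffled unit structure creates alternative paths
    cat0 <- small_catalog()
    nms <- sample(cat0$alleles$name, 2)
    p1 <- allele_dna(cat0, nms[1]); p2 <- allele_dna(cat0, nms[2])
    k <- sample(1:4, 1)
    sim <- simulate_recombinant(p1, p2, k, seed = 100 + i)
    g <- greedy_switch_path(sim$child, p1, p2)
    dp <- min_switches_dp(sim$child, p1, p2)
    expect_lte(dp, k)
    if (!is.null(g)) {
      expect_identical(switch_path_sequence(g), sim$child)
      expect_gte(g$n_switches, dp)
      segs <- g$segments
      expect_true(all(segs$length > g$min_match))
      expect_equal(segs$start[1], 0L)
      last <- segs[nrow(segs), ]
      expect_equal(last$end, nchar(g$parents[last$parent]))
      if (nrow(segs) > 1)
        expect_true(all(diff(segs$parent) != 0L))  # alternation
    }
  }
})

test_that("parent order does not change the best switch count", {
  set.seed(55)
  for (i in 1:20) {
    p1 <- random_dna(500); p2 <- random_dna(500)
    sim <- simulate_recombinant(p1, p2, sample(1:3, 1), seed = 200 + i)
    a <- greedy_switch_path(sim$child, p1, p2)
    b <- greedy_switch_path(sim$child, p2, p1)
    expect_equal(a$n_switches, b$n_switches)
  }
})

test_that("raising min_match never lowers the minimal switch count", {
  set.seed(56)
  for (i in 1:15) {
    p1 <- random_dna(600); p2 <- random_dna(600)
    sim <- simulate_recombinant(p1, p2, 2, min_match = 30, seed = 300 + i)
    d15 <- min_switches_dp(sim$child, p1, p2, min_match = 15)
    d30 <- min_switches_dp(sim$child, p1, p2, min_match = 30)
    expect_gte(d30, d15)
  }
})

test_that("matches of exactly min_match are rejected (strictly longer)", {
  set.seed(57)
  p1 <- random_dna(300)
  p2 <- random_dna(300)
  # pin the junction: the prefix match cannot extend past 100 and the
  # suffix match cannot extend before 286
  substr(p2, 286, 286) <- setdiff(c("A", "C", "G", "T"),
                                  c(substr(p1, 101, 101),
                                    substr(p2, 285, 285)))[1]
  substr(p1, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                  substr(p2, 285, 285))[1]
  # child whose only possible second fragment is exactly 15 nt
  child <- paste0(substr(p1, 1, 100), substr(p2, 286, 300))
  expect_null(greedy_switch_path(child, p1, p2, min_match = 15L))
  expect_identical(min_switches_dp(child, p1, p2, min_match = 15L), Inf)
  # at min_match 14 the same child becomes reachable
  expect_equal(greedy_switch_path(child, p1, p2,
                                  min_match = 14L)$n_switches, 1L)
})

test_that("parental scans classify uni/bi origin", {
  set.seed(58)
  cat0 <- small_catalog()
  # an allele present in the catalog is uni at 0 switches
  scan <- scan_parents("S1", cat0)
  expect_identical(scan$origin_class, "uni")
  expect_equal(scan$best_switches, 0L)
  # a junction-spanning recombinant of two alleles is biparental
  p1 <- allele_dna(cat0, "S1"); p2 <- allele_dna(cat0, "S2")
  # build a child crossing from S1 into S2 at a non-unit boundary so that
  # neither single parent explains it; total length stays a unit multiple
  a <- 210L
  k <- (a + nchar(p2)) %/% 84L - 1L
  s <- 84L * k - a
  child <- paste0(substr(p1, 1, a), substr(p2, nchar(p2) - s + 1, nchar(p2)))
  enc <- encode_allele(child, cat0)
  cat1 <- catalog_add_allele(enc$catalog, "X1", enc$codes)
  scan <- scan_parents("X1", cat1, include_child = FALSE)
  expect_identical(scan$origin_class, "bi")
  tab <- scan$table
  hit <- tab[!is.na(tab$n_switches), ]
  expect_true(all(c("S1", "S2") %in% c(hit$p1, hit$p2)))
})

test_that("cohort summaries aggregate per parental-type class", {
  cat0 <- ref_catalog()
  sub <- cat0
  keep <- c("A", "B", "N", "C", "L4", "L14")
  sub$alleles <- sub$alleles[sub$alleles$name %in% keep, , drop = FALSE]
  cs <- cohort_switch_summary(c("N", "L4"), sub)
  expect_true(all(cs$derivable$derivable))
  n_row <- cs$per_child[cs$per_child$child == "N" &
                          cs$per_child$class == "AxA", ]
  expect_equal(n_row$min_switches, 1L)
  l4_row <- cs$per_child[cs$per_child$child == "L4" &
                           cs$per_child$class == "CxC", ]
  expect_equal(l4_row$min_switches, 2L)
})
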