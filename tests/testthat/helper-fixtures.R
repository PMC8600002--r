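# Shared fixtures, built in code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small simulated catalog reused across files (deterministic).
small_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_catalog(n_fingers = 10L,
                                                   n_alleles = 6L,
                                                   len_range = c(8L, 14L),
                                                   seed = 42L)
    cache
  }
})

# The synthetic reference catalog is expensive (~2 s); build once.
ref_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_reference_catalog()
    cache
  }
})

# A bare two-finger catalog whose fingers are easy to reason about.
tiny_catalog <- function() {
  set.seed(7)
  zf_catalog(
    data.frame(code = c("z1", "z2"),
               dna = c(zfarray:::finger_dna(zfarray:::SCAFFOLD_AA),
                       zfarray:::finger_dna(zfarray:::SCAFFOLD_AA,
                                            wobble = c(2L, 5L, 9L, 15L)))),
    data.frame(name = "A1", zf_codes = "z1,z2"))
}

# Assemble a well-formed read around an array (no barcodes).
make_read <- function(array_dna, anchors = flank_anchors(),
                      lead = "GATTACA", tail = "TTGGCCA") {
  paste0(lead, anchors$flank5, array_dna, anchors$flank3, tail)
}

# Independent rule tracer for the length-frequency table: a direct
# transcription of the five printed rules, kept separate from the
# implementation on purpose.
trace_length_rules <- function(freqs) {
  # freqs: named numeric, names = unit counts; must sum to 1
  ord <- order(-freqs, as.integer(names(freqs)))
  f <- unname(freqs[ord])
  lens <- as.integer(names(freqs)[ord])
  fi <- f[1]
  fj <- if (length(f) >= 2) f[2] else 0
  fk <- if (length(f) >= 3) f[3] else 0
  if (length(f) == 1) return(list(rule = 1L, hap = c(lens[1], lens[1])))
  if (fi + fj >= 0.7 && fi / fj < 2)
    return(list(rule = 2L, hap = c(lens[1], lens[2])))
  if (fi + fj >= 0.7 && fi / fj < 3 &&
      (if (fk == 0) Inf else fj / fk) > 2)
    return(list(rule = 3L, hap = c(lens[1], lens[2])))
  if (fi + fj >= 0.7 && fi / fj > 3)
    return(list(rule = 4L, hap = c(lens[1], lens[1])))
  if (fi >= 0.7) return(list(rule = 5L, hap = c(lens[1], lens[1])))
  list(rule = NA_integer_, hap = c(NA_integer_, NA_integer_))
}
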