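# Array extraction: demultiplexing, flank anchoring, and 84-nt unit tiling.
#
# Reads carry an outer barcode, then an inner barcode, at the 5' end, with
# the reverse complements at the 3' end. The ZF array is located between the
# two fixed genomic flanking sequences; only reads with both flanks and a
# contiguous tiling of 84-nt finger units are retained. PCR slippage products
# survive extraction (they are real, complete arrays of the wrong length) and
# are removed later by the genotyper's length-frequency rules.

#' Dual-barcode scheme
#'
#' @param inner character vector of inner (primer) barcodes; defaults to the
#'   eight published 12-nt barcodes.
#' @param outer character vector of outer (second-round) barcodes.
#' @param max_mismatch_inner,max_mismatch_outer Hamming mismatch budgets.
#' @return object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(inner = INNER_BARCODES, outer,
                           max_mismatch_inner = 1L, max_mismatch_outer = 2L) {
  stopifnot(length(inner) >= 1L, length(outer) >= 1L,
            !anyDuplicated(inner), !anyDuplicated(outer))
  if (is.null(names(outer))) names(outer) <- sprintf("%02d", seq_along(outer))
  if (is.null(names(inner))) names(inner) <- as.character(seq_along(inner))
  structure(list(inner = inner, outer = outer,
                 max_mismatch_inner = as.integer(max_mismatch_inner),
                 max_mismatch_outer = as.integer(max_mismatch_outer)),
            class = "barcode_scheme")
}

# Hamming distance from a fixed-length prefix to each barcode in a set.
hamming_to_set <- function(prefix, barcodes) {
  pv <- utf8ToInt(prefix)
  vapply(barcodes, function(b) {
    bv <- utf8ToInt(b)
    if (length(pv) < length(bv)) return(length(bv))
    sum(pv[seq_along(bv)] != bv)
  }, integer(1))
}

#' Assign reads to samples by their dual barcodes
#'
#' A read is assigned if and only if exactly one (outer, inner) barcode pair
#' matches its 5' end within the mismatch budgets, in either orientation.
#' Reads matching no pair, or more than one, go to the unassigned bin.
#'
#' @param reads named character vector of read sequences (names = read ids),
#'   or a [Biostrings::DNAStringSet].
#' @param scheme a [barcode_scheme()].
#' @return list with `samples` (named list, sample id "outer_inner" ->
#'   character vector of read ids), `unassigned` (read ids) and
#'   `assignments` (data.frame read_id/outer/inner/sample).
#' @export
demultiplex <- function(reads, scheme) {
  if (is(reads, "DNAStringSet")) reads <- setNames(as.character(reads),
                                                   names(reads))
  stopifnot(!is.null(names(reads)))
  outer_len <- nchar(scheme$outer[1])
  inner_len <- nchar(scheme$inner[1])
  rows <- lapply(names(reads), function(id) {
    hits <- list()
    for (seqs in list(reads[[id]], revcomp(reads[[id]]))) {
      od <- hamming_to_set(substr(seqs, 1L, outer_len), scheme$outer)
      id_ok <- which(od <= scheme$max_mismatch_outer)
      if (!length(id_ok)) next
      inn <- substr(seqs, outer_len + 1L, outer_len + inner_len)
      idd <- hamming_to_set(inn, scheme$inner)
      in_ok <- which(idd <= scheme$max_mismatch_inner)
      for (o in id_ok) for (i in in_ok)
        hits[[paste(names(scheme$outer)[o], names(scheme$inner)[i],
                    sep = "_")]] <- TRUE
    }
    hits <- names(hits)
    if (length(hits) == 1L) {
      parts <- strsplit(hits, "_", fixed = TRUE)[[1]]
      data.frame(read_id = id, outer = parts[1], inner = parts[2],
                 sample = hits, stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = id, outer = NA_character_, inner = NA_character_,
                 sample = NA_character_, stringsAsFactors = FALSE)
    }
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments))
    assignments <- data.frame(read_id = character(), outer = character(),
                              inner = character(), sample = character())
  assigned <- assignments[!is.na(assignments$sample), , drop = FALSE]
  list(samples = split(assigned$read_id, assigned$sample),
       unassigned = assignments$read_id[is.na(assignments$sample)],
       assignments = assignments)
}

#' Flanking-anchor configuration
#'
#' @param flank5,flank3 the sequences immediately 5' and 3' of the ZF array.
#' @param min_identity minimum identity over the aligned span for a flank hit.
#' @param min_span minimum fraction of the anchor that must align.
#' @return object of class `flank_anchors`.
#' @export
flank_anchors <- function(flank5 = PRDM9_FLANK5, flank3 = PRDM9_FLANK3,
                          min_identity = 0.75, min_span = 0.5) {
  stopifnot(nchar(flank5) > 0L, nchar(flank3) > 0L,
            min_identity > 0, min_identity <= 1)
  structure(list(flank5 = flank5, flank3 = flank3,
                 min_identity = min_identity, min_span = min_span),
            class = "flank_anchors")
}

# Alignment scores used throughout extraction (BLAST-like defaults).
ALN_MATCH <- 2; ALN_MISMATCH <- -3; ALN_GAP_OPEN <- 5; ALN_GAP_EXT <- 2

# Best local alignment of anchor against one strand of a read. Seeds the
# search with exact 16-mers of the anchor and verifies by Smith-Waterman on a
# window; falls back to a full-read Smith-Waterman when no seed matches.
sw_anchor_hit <- function(read, anchor, seed_len = 16L,
                          full_fallback = TRUE) {
  n <- nchar(anchor)
  starts <- seq(1L, n - seed_len + 1L, by = seed_len)
  seeds <- substring(anchor, starts, starts + seed_len - 1L)
  windows <- list()
  for (k in seq_along(seeds)) {
    hit <- gregexpr(seeds[k], read, fixed = TRUE)[[1]]
    if (hit[1] == -1L) next
    for (p in as.integer(hit)) {
      ws <- max(1L, p - starts[k] + 1L - 40L)
      windows[[length(windows) + 1L]] <- c(ws, min(nchar(read), ws + n + 80L))
    }
  }
  best <- NULL
  if (length(windows)) {
    # collapse windows proposing (nearly) the same anchor placement
    ws <- sort(unique(vapply(windows, `[`, numeric(1), 1L)))
    keep <- ws[c(TRUE, diff(ws) > 30)]
    near_perfect <- 0.95 * ALN_MATCH * n
    for (w1 in keep) {
      w2 <- min(nchar(read), w1 + n + 80L)
      aln <- cpp_sw_align(anchor, substr(read, w1, w2),
                         ALN_MATCH, ALN_MISMATCH, ALN_GAP_OPEN, ALN_GAP_EXT)
      if (is.null(aln$sstart)) next
      aln$sstart <- aln$sstart + w1 - 1L
      aln$send <- aln$send + w1 - 1L
      if (is.null(best) || aln$score > best$score) best <- aln
      if (best$score >= near_perfect) break
    }
  }
  if (is.null(best)) {
    if (!full_fallback) return(NULL)
    best <- cpp_sw_align(anchor, read,
                         ALN_MATCH, ALN_MISMATCH, ALN_GAP_OPEN, ALN_GAP_EXT)
    if (is.null(best$sstart)) return(NULL)
  }
  best
}

#' Locate a flanking anchor in a read
#'
#' Smith-Waterman local alignment of the anchor against the read and, when
#' `both_strands`, against its reverse complement; the best-scoring hit is
#' returned if its identity over the aligned span reaches `min_identity` and
#' the aligned anchor span reaches `min_span` of the anchor length.
#'
#' @param read read sequence.
#' @param anchor anchor sequence.
#' @param min_identity identity floor over the aligned span.
#' @param min_span minimum aligned fraction of the anchor.
#' @param both_strands also search the reverse complement.
#' @param full_fallback when no exact 16-mer seed of the anchor occurs in the
#'   read, run a full-read Smith-Waterman (TRUE, the reference behaviour) or
#'   report the anchor as absent (FALSE, used for fast strand probing).
#' @return NULL if absent, else a list with `start`/`end` (0-based half-open
#'   interval on the reported strand), `identity`, `score`, `strand`.
#' @export
find_flank <- function(read, anchor, min_identity = 0.75, min_span = 0.5,
                       both_strands = TRUE, full_fallback = TRUE) {
  cand <- list(list(seq = read, strand = "+"))
  if (both_strands) cand <- c(cand, list(list(seq = revcomp(read),
                                              strand = "-")))
  best <- NULL
  for (ci in cand) {
    aln <- sw_anchor_hit(ci$seq, anchor, full_fallback = full_fallback)
    if (is.null(aln)) next
    if (is.null(best) || aln$score > best$score) {
      best <- aln
      best$strand <- ci$strand
    }
  }
  if (is.null(best)) return(NULL)
  if (best$identity < min_identity) return(NULL)
  if ((best$pend - best$pstart) < min_span * nchar(anchor)) return(NULL)
  list(start = best$sstart, end = best$send, identity = best$identity,
       score = best$score, strand = best$strand)
}

# Project one fitting alignment onto finger coordinates: aligned read bases
# keep their value, read deletions become N, read insertions are dropped.
project_unit <- function(pattern_aln, subject_aln) {
  p <- strsplit(pattern_aln, "", fixed = TRUE)[[1]]
  s <- strsplit(subject_aln, "", fixed = TRUE)[[1]]
  keep <- p != "-"
  out <- s[keep]
  out[out == "-"] <- "N"
  paste(out, collapse = "")
}

#' Tile an array sequence into 84-nt finger units
#'
#' Greedy 5'->3' tiling: at each offset the best-fitting catalog finger is
#' aligned (finger anchored at both ends, read end free), accepted when it
#' covers at least `min_unit_coverage` of the 84 positions at identity >=
#' `min_identity`, and the consumed read bases advance the offset. Units are
#' reported in finger coordinates: read deletions are padded with Ns so every
#' unit has length 84. Tiling must cover the array end-to-end.
#'
#' @param array_dna the inter-flank read segment.
#' @param catalog a `zf_catalog` supplying the finger repertoire.
#' @param min_unit_coverage minimum aligned fraction of the 84 positions.
#' @param min_identity per-unit identity floor (matches / alignment columns).
#' @param window_slack extra read bases offered to each unit alignment to
#'   absorb insertions.
#' @return list with `units` (84-nt strings) and `codes` (best-matching
#'   catalog finger per unit), or NULL when the array cannot be tiled
#'   contiguously.
#' @export
tile_units <- function(array_dna, catalog, min_unit_coverage = 0.5,
                       min_identity = 0.75, window_slack = 12L) {
  len <- nchar(array_dna)
  if (len == 0L) return(NULL)
  fingers <- catalog$fingers
  finger_ints <- lapply(fingers$dna, utf8ToInt)
  units <- character(0); codes <- character(0)
  o <- 0L
  while (o < len) {
    chunk <- substr(array_dna, o + 1L, o + ZF_UNIT_NT)
    # mismatch prescreen on the raw 84-nt chunk: a small Hamming distance
    # implies no indel shift, so the chunk can be accepted without alignment;
    # otherwise only the closest fingers are aligned (an indel shift inflates
    # all distances roughly equally, in which case all fingers are tried).
    cand <- seq_len(nrow(fingers))
    if (nchar(chunk) == ZF_UNIT_NT) {
      ci <- utf8ToInt(chunk)
      hd <- vapply(finger_ints, function(fi) sum(fi != ci), integer(1))
      kmin <- which.min(hd)
      if (hd[kmin] == 0L || (hd[kmin] <= 6L &&
                             hd[kmin] <= (1 - min_identity) * ZF_UNIT_NT)) {
        units <- c(units, chunk); codes <- c(codes, fingers$code[kmin])
        o <- o + ZF_UNIT_NT
        next
      }
      if (hd[kmin] <= 20L) cand <- which(hd <= hd[kmin] + 8L)
    }
    window <- substr(array_dna, o + 1L, min(len, o + ZF_UNIT_NT + window_slack))
    best <- NULL; best_code <- NA_character_
    for (k in cand) {
      aln <- cpp_fit_align(fingers$dna[k], window,
                           ALN_MATCH, ALN_MISMATCH, ALN_GAP_OPEN, ALN_GAP_EXT)
      if (is.null(best) || aln$score > best$score) {
        best <- aln; best_code <- fingers$code[k]
      }
    }
    if (is.null(best) || best$identity < min_identity) return(NULL)
    aligned <- sum(strsplit(best$subject_aln, "", fixed = TRUE)[[1]] != "-")
    covered <- sum(strsplit(best$pattern_aln, "", fixed = TRUE)[[1]] != "-" &
                   strsplit(best$subject_aln, "", fixed = TRUE)[[1]] != "-")
    if (covered < min_unit_coverage * ZF_UNIT_NT) return(NULL)
    if (best$consumed < 1L) return(NULL)
    units <- c(units, project_unit(best$pattern_aln, best$subject_aln))
    codes <- c(codes, best_code)
    o <- o + best$consumed
  }
  list(units = units, codes = codes)
}

#' Extract and validate the ZF array of one read
#'
#' Locates both flanking anchors (resolving strand by the orientation in
#' which both flanks occur in order), takes the inter-flank interval as the
#' array, and tiles it into 84-nt units. Rejections carry a reason:
#' `no_flank5`, `no_flank3`, `disordered_flanks` or `non_contiguous_array`.
#'
#' @param read read sequence.
#' @param anchors a [flank_anchors()].
#' @param catalog a `zf_catalog`.
#' @param read_id identifier recorded in the observation.
#' @param ... passed to [tile_units()].
#' @return an `array_observation` (list with read_id, array_dna, n_units,
#'   units, flank5_identity, flank3_identity, strand) or a rejection (list
#'   with read_id and reason; class `array_rejection`).
#' @export
extract_array <- function(read, anchors, catalog, read_id = "read", ...) {
  reject <- function(reason)
    structure(list(read_id = read_id, reason = reason),
              class = "array_rejection")
  best <- NULL
  diag_reason <- c("+" = "no_flank5", "-" = "no_flank5")
  diag_found <- c("+" = 0L, "-" = 0L)
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") read else revcomp(read)
    h5 <- find_flank(seqs, anchors$flank5, anchors$min_identity,
                     anchors$min_span, both_strands = FALSE,
                     full_fallback = FALSE)
    h3 <- find_flank(seqs, anchors$flank3, anchors$min_identity,
                     anchors$min_span, both_strands = FALSE,
                     full_fallback = FALSE)
    diag_found[strand] <- sum(!is.null(h5), !is.null(h3))
    if (is.null(h5) || is.null(h3)) {
      diag_reason[strand] <- if (is.null(h5)) "no_flank5" else "no_flank3"
      next
    }
    if (h5$end <= h3$start) {
      cand <- list(seqs = seqs, h5 = h5, h3 = h3, strand = strand)
      if (is.null(best) || (h5$score + h3$score) >
            (best$h5$score + best$h3$score)) best <- cand
    } else {
      diag_reason[strand] <- "disordered_flanks"
    }
  }
  if (is.null(best)) {
    # report the orientation with the most flank evidence (ties go to +)
    pick <- if (diag_found["-"] > diag_found["+"]) "-" else "+"
    return(reject(unname(diag_reason[pick])))
  }
  array_dna <- substr(best$seqs, best$h5$end + 1L, best$h3$start)
  tiling <- tile_units(array_dna, catalog, ...)
  if (is.null(tiling)) return(reject("non_contiguous_array"))
  structure(list(read_id = read_id, array_dna = array_dna,
                 n_units = length(tiling$units), units = tiling$units,
                 codes = tiling$codes,
                 flank5_identity = best$h5$identity,
                 flank3_identity = best$h3$identity,
                 strand = best$strand),
            class = "array_observation")
}

#' Extract arrays from a set of reads
#'
#' @param reads named character vector or DNAStringSet.
#' @param anchors a [flank_anchors()].
#' @param catalog a `zf_catalog`.
#' @param ... passed to [extract_array()].
#' @return list with `observations` (list of `array_observation`) and
#'   `rejections` (data.frame read_id/reason).
#' @export
extract_arrays <- function(reads, anchors, catalog, ...) {
  if (is(reads, "DNAStringSet")) reads <- setNames(as.character(reads),
                                                   names(reads))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  obs <- list(); rej <- list()
  for (id in names(reads)) {
    r <- extract_array(reads[[id]], anchors, catalog, read_id = id, ...)
    if (inherits(r, "array_rejection"))
      rej[[length(rej) + 1L]] <- data.frame(read_id = id, reason = r$reason,
                                            stringsAsFactors = FALSE)
    else obs[[length(obs) + 1L]] <- r
  }
  list(observations = obs,
       rejections = if (length(rej)) do.call(rbind, rej)
                    else data.frame(read_id = character(),
                                    reason = character()))
}
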