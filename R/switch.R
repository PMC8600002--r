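# Template-switch derivation of alleles.
#
# A child allele is derivable from a pair of parental alleles when it can be
# written as alternating fragments of the two parents: the first fragment is
# a prefix of the starting parent, the last fragment runs to the 3' end of
# the active parent, every fragment is longer than `min_match` nucleotides,
# and consecutive fragments come from different parents (a self-pair, p1 ==
# p2, models a homozygous donor). The greedy engine reproduces the published
# procedure (always take the longest match, from both starting parents); the
# dynamic program is an exact oracle for the minimum number of switches.

# Per-parent matching context reused across greedy/dp calls.
ts_context <- function(child, parent) {
  me <- cpp_maxext(child, parent)
  list(len = me$len, pos = me$pos,
       lcp = cpp_lcp(child, parent),
       lcsuf = cpp_lcs_suffix(child, parent),
       m = nchar(parent))
}

greedy_from <- function(n, ctxs, start, min_match, max_switches) {
  segs <- list()
  ctx <- ctxs[[start]]
  l <- ctx$lcp
  if (l <= min_match) return(NULL)
  if (l == n) {
    if (n == ctx$m)
      return(list(segments = data.frame(parent = start, start = 0L,
                                        end = n, length = n),
                  n_switches = 0L))
    return(NULL)  # child is a strict prefix: no valid single-fragment path
  }
  segs[[1]] <- c(start, 0L, l)
  c_ <- l
  active <- start
  while (length(segs) <= max_switches + 1L) {
    active <- 3L - active
    ctx <- ctxs[[active]]
    rem <- n - c_
    if (rem > min_match && rem <= ctx$lcsuf) {  # remainder is a parent suffix
      segs[[length(segs) + 1L]] <- c(active, ctx$m - rem, rem)
      df <- do.call(rbind, segs)
      return(list(segments = data.frame(parent = df[, 1], start = df[, 2],
                                        end = df[, 2] + df[, 3],
                                        length = df[, 3]),
                  n_switches = nrow(df) - 1L))
    }
    l <- ctx$len[c_ + 1L]
    if (l <= min_match) return(NULL)
    if (c_ + l >= n) return(NULL)  # consumed the child without a suffix ending
    segs[[length(segs) + 1L]] <- c(active, ctx$pos[c_ + 1L], l)
    c_ <- c_ + l
  }
  NULL
}

#' Greedy template-switch path from two parents to a child
#'
#' Implements the published greedy procedure: take the longest match between
#' the child's 5' end and the starting parent's 5' end, then repeatedly take
#' the longest match between the truncated child and any position of the
#' other parent, alternating parents, until the remainder matches the 3' end
#' of the active parent. Both starting parents are tried and the path with
#' fewer switches is returned (ties go to the path starting from `p1`). All
#' matches must be longer than `min_match` nucleotides.
#'
#' @param child,p1,p2 DNA strings.
#' @param min_match matches must exceed this length (default 15, so the
#'   shortest accepted fragment is 16 nt).
#' @param max_switches cap on switches explored (default 50).
#' @return a `switch_path` (list with `segments` data.frame of parent index /
#'   start / end (0-based half-open parent coordinates) / length, and
#'   `n_switches`), or NULL when the child is unreachable.
#' @export
greedy_switch_path <- function(child, p1, p2, min_match = 15L,
                               max_switches = 50L) {
  n <- nchar(child)
  ctxs <- list(ts_context(child, p1), ts_context(child, p2))
  best <- NULL
  for (start in 1:2) {
    res <- greedy_from(n, ctxs, start, min_match, max_switches)
    if (!is.null(res) &&
        (is.null(best) || res$n_switches < best$n_switches)) best <- res
    if (identical(p1, p2)) break  # self-pair: both starts are identical
  }
  if (is.null(best)) return(NULL)
  structure(list(child = child, parents = c(p1, p2),
                 segments = best$segments, n_switches = best$n_switches,
                 min_match = min_match),
            class = "switch_path")
}

#' Re-concatenate the fragments of a switch path
#'
#' @param path a `switch_path`.
#' @return the reconstructed child DNA.
#' @export
switch_path_sequence <- function(path) {
  paste(vapply(seq_len(nrow(path$segments)), function(k) {
    s <- path$segments[k, ]
    substr(path$parents[s$parent], s$start + 1L, s$end)
  }, character(1)), collapse = "")
}

#' Exact minimum number of template switches (dynamic program)
#'
#' Breadth-first search over (child prefix covered, active parent) states
#' under the same constraints as the greedy engine: fragments longer than
#' `min_match`, the first fragment a prefix of its parent, the last a suffix
#' of its parent, and parents alternating between fragments. Unlike the
#' greedy engine it considers fragments of every admissible length, so it
#' returns the true minimum.
#'
#' @inheritParams greedy_switch_path
#' @return integer minimum switch count, or Inf when unreachable.
#' @export
min_switches_dp <- function(child, p1, p2, min_match = 15L,
                            max_switches = 50L) {
  n <- nchar(child)
  minlen <- min_match + 1L
  if (n < minlen) return(Inf)
  ctxs <- list(ts_context(child, p1), ts_context(child, p2))
  for (p in 1:2)
    if (n == ctxs[[p]]$m && ctxs[[p]]$lcp == n) return(0L)
  # frontier: logical matrix visited[c + 1, parent]
  visited <- matrix(FALSE, nrow = n + 1L, ncol = 2L)
  frontier <- matrix(FALSE, nrow = n + 1L, ncol = 2L)
  for (p in 1:2) {
    l <- ctxs[[p]]$lcp
    if (l >= minlen) {
      hi <- min(l, n - 1L)  # c = n handled only via the final-fragment check
      if (hi >= minlen) frontier[(minlen:hi) + 1L, p] <- TRUE
    }
  }
  visited <- visited | frontier
  d <- 1L  # segments so far
  while (any(frontier) && d <= max_switches) {
    for (p in 1:2) {  # can we finish with one fragment from the other parent?
      cs <- which(frontier[, p]) - 1L
      if (!length(cs)) next
      o <- 3L - p
      rem <- n - cs
      if (any(rem >= minlen & rem <= ctxs[[o]]$lcsuf)) return(d)  # d+1 segments
    }
    nxt <- matrix(FALSE, nrow = n + 1L, ncol = 2L)
    for (p in 1:2) {
      cs <- which(frontier[, p]) - 1L
      if (!length(cs)) next
      o <- 3L - p
      for (c_ in cs) {
        L <- ctxs[[o]]$len[c_ + 1L]
        if (L >= minlen) {
          hi <- min(c_ + L, n - 1L)
          lo <- c_ + minlen
          if (hi >= lo) nxt[(lo:hi) + 1L, o] <- TRUE
        }
      }
    }
    frontier <- nxt & !visited
    visited <- visited | frontier
    d <- d + 1L
  }
  Inf
}

# Does a greedy path use both (distinct) parents?
path_is_biparental <- function(path) {
  length(unique(path$segments$parent)) == 2L &&
    !identical(path$parents[1], path$parents[2])
}

#' Scan a catalog for parental pairs explaining a child allele
#'
#' Every unordered pair of catalog alleles (including self-pairs, which model
#' homozygous donors) is tested with the greedy engine. The child is classed
#' `uni` when its best derivation uses a single parent, `bi` when every best
#' derivation needs both parents of a pair, `uni_or_bi` when single- and
#' two-parent derivations tie, and `unreachable` when no pair explains it.
#'
#' @param child child allele DNA (or name, with `catalog`).
#' @param catalog a `zf_catalog` providing candidate parents.
#' @param min_match,max_switches as in [greedy_switch_path()].
#' @param include_child keep the child itself among candidate parents
#'   (an allele present in the catalog is then trivially `uni` at 0
#'   switches); set FALSE to ask how it derives from *other* alleles.
#' @return object of class `parent_scan`: list with `child`, `table`
#'   (data.frame p1/p2/n_switches/biparental), `origin_class` and
#'   `best_switches`.
#' @export
scan_parents <- function(child, catalog, min_match = 15L, max_switches = 50L,
                         include_child = TRUE) {
  child_dna <- if (child %in% catalog$alleles$name)
    allele_dna(catalog, child) else child
  cand <- catalog$alleles
  if (!include_child)
    cand <- cand[cand$dna != child_dna, , drop = FALSE]
  nms <- cand$name; dnas <- cand$dna
  ctxs <- lapply(dnas, ts_context, child = child_dna)
  n <- nchar(child_dna)
  rows <- list()
  for (i in seq_along(nms)) for (j in i:length(nms)) {
    cpair <- list(ctxs[[i]], ctxs[[j]])
    best <- NULL
    for (start in 1:2) {
      res <- greedy_from(n, cpair, start, min_match, max_switches)
      if (!is.null(res) &&
          (is.null(best) || res$n_switches < best$n_switches)) best <- res
      if (i == j) break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      p1 = nms[i], p2 = nms[j],
      n_switches = if (is.null(best)) NA_integer_ else best$n_switches,
      biparental = if (is.null(best)) NA else
        (i != j && length(unique(best$segments$parent)) == 2L),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  reached <- table[!is.na(table$n_switches), , drop = FALSE]
  if (!nrow(reached)) {
    origin <- "unreachable"; best_sw <- Inf
  } else {
    best_sw <- min(reached$n_switches)
    uni_best <- suppressWarnings(
      min(reached$n_switches[!reached$biparental]))
    bi_best <- suppressWarnings(
      min(reached$n_switches[reached$biparental]))
    origin <- if (uni_best < bi_best) "uni"
    else if (bi_best < uni_best) "bi" else "uni_or_bi"
  }
  structure(list(child = child, table = table, origin_class = origin,
                 best_switches = best_sw),
            class = "parent_scan")
}

#' Switch-count summary for a set of child alleles
#'
#' For every child, scans all parental pairs drawn from the catalog
#' (excluding the child itself) and summarises, per parental-type class
#' (A-type x A-type, A-type x C-type, C-type x C-type), the minimal switch
#' count and the number of parental combinations achieving it. Class
#' averages are taken over the per-child minima, restricted to derivable
#' children.
#'
#' @param children character vector of child allele names (in `catalog`).
#' @param catalog a type-labelled `zf_catalog`.
#' @param min_match,max_switches as in [greedy_switch_path()].
#' @return list with `per_child` (data.frame child / child_type / class /
#'   min_switches / n_combinations), `class_means` (data.frame by child type
#'   and parental class) and `derivable` (data.frame child / derivable).
#' @export
cohort_switch_summary <- function(children, catalog, min_match = 15L,
                                  max_switches = 50L) {
  labels <- setNames(catalog$alleles$type_label, catalog$alleles$name)
  pair_class <- function(a, b) {
    t <- sort(c(labels[[a]], labels[[b]]))
    if (t[1] == "A-type" && t[2] == "A-type") "AxA"
    else if (t[1] == "A-type" && t[2] == "C-type") "AxC"
    else if (t[1] == "C-type" && t[2] == "C-type") "CxC"
    else "other"
  }
  per_child <- list(); derivable <- list()
  for (ch in children) {
    scan <- scan_parents(ch, catalog, min_match, max_switches,
                         include_child = FALSE)
    tab <- scan$table
    tab$class <- mapply(pair_class, tab$p1, tab$p2)
    reached <- tab[!is.na(tab$n_switches) & tab$class != "other", ,
                   drop = FALSE]
    derivable[[ch]] <- data.frame(child = ch,
                                  child_type = labels[[ch]],
                                  derivable = nrow(reached) > 0L,
                                  stringsAsFactors = FALSE)
    if (!nrow(reached)) next
    for (cl in unique(reached$class)) {
      sub <- reached[reached$class == cl, , drop = FALSE]
      mn <- min(sub$n_switches)
      per_child[[paste(ch, cl)]] <- data.frame(
        child = ch, child_type = labels[[ch]], class = cl,
        min_switches = mn, n_combinations = sum(sub$n_switches == mn),
        stringsAsFactors = FALSE)
    }
  }
  per_child <- do.call(rbind, c(per_child, list(NULL)))
  derivable <- do.call(rbind, c(derivable, list(NULL)))
  rownames(per_child) <- rownames(derivable) <- NULL
  class_means <- NULL
  if (!is.null(per_child) && nrow(per_child)) {
    class_means <- do.call(rbind, lapply(
      split(per_child, list(per_child$child_type, per_child$class),
            drop = TRUE),
      function(s) data.frame(child_type = s$child_type[1],
                             class = s$class[1], n_children = nrow(s),
                             mean_min_switches = mean(s$min_switches),
                             stringsAsFactors = FALSE)))
    rownames(class_means) <- NULL
  }
  list(per_child = per_child, class_means = class_means,
       derivable = derivable)
}
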