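#' De novo detection of a shared 5' leader across read clusters
#'
#' Finds `kmer`-length words occurring within the first `window` bases of at
#' least `cluster_fraction_min` of cluster representatives, chains
#' overlapping enriched words into consensus candidates, and, for each
#' supporting cluster, records the junction offset (read position of the
#' last leader base, allowing one mismatch in the consensus match). Leaders
#' are detected as shared 5' words with a common 3' end and ragged 5' starts
#' (SL-donor TSS heterogeneity), not as fixed-length prefixes.
#'
#' @param clusters list of `read_cluster` objects (from [cluster_by_gene()]).
#' @param window 5' window searched for enriched words (default 40 nt).
#' @param kmer word length (default 12).
#' @param cluster_fraction_min fraction of representatives a word must occur
#'   in (default 0.5).
#' @param min_clusters minimum supporting clusters for a candidate
#'   (default 5).
#' @return list of `leader_candidate` objects ranked by support (ties:
#'   longer consensus, then lexicographic); empty list when nothing reaches
#'   `min_clusters`.
#' @export
detect_leader <- function(clusters, window = 40, kmer = 12,
                          cluster_fraction_min = 0.5, min_clusters = 5) {
  n <- length(clusters)
  if (n < min_clusters) return(list())
  reps <- vapply(clusters, function(cl) cl$representative, character(1))
  cl_ids <- vapply(clusters, function(cl) cl$cluster_id, character(1))
  heads <- substr(reps, 1, window)
  per_head <- lapply(heads, kmers, k = kmer)
  tab <- table(unlist(per_head))
  enriched <- names(tab)[tab / n >= cluster_fraction_min]
  if (!length(enriched)) return(list())
  support_of <- as.integer(tab[enriched])
  names(support_of) <- enriched

  candidates <- list()
  unused <- enriched[order(-support_of, enriched)]
  while (length(unused)) {
    chain <- assemble_chain(unused[1], unused, support_of, kmer)
    unused <- setdiff(unused, chain$words)
    if (nchar(chain$consensus) < 16) next
    cand <- call_junctions(chain$consensus, reps, cl_ids, min_overlap = kmer)
    if (cand$support < min_clusters) next
    candidates[[length(candidates) + 1]] <- cand
  }
  if (!length(candidates)) return(list())
  sup <- vapply(candidates, function(x) x$support, numeric(1))
  len <- vapply(candidates, function(x) nchar(x$consensus), numeric(1))
  con <- vapply(candidates, function(x) x$consensus, character(1))
  candidates[order(-sup, -len, con)]
}

## extend a seed word left and right through uniquely overlapping enriched
## words (highest support, then lexicographic, on branches)
assemble_chain <- function(seed, pool, support_of, k) {
  words <- seed
  cons <- seed
  repeat {
    suf <- substring(cons, nchar(cons) - k + 2)
    nxt <- pool[startsWith(pool, suf) & !(pool %in% words)]
    if (!length(nxt)) break
    nxt <- nxt[order(-support_of[nxt], nxt)][1]
    cons <- paste0(cons, substring(nxt, k))
    words <- c(words, nxt)
  }
  repeat {
    pre <- substr(cons, 1, k - 1)
    prv <- pool[substring(pool, 2) == pre & !(pool %in% words)]
    if (!length(prv)) break
    prv <- prv[order(-support_of[prv], prv)][1]
    cons <- paste0(substr(prv, 1, 1), cons)
    words <- c(words, prv)
  }
  list(consensus = cons, words = words)
}

## align a consensus suffix to the 5' region of each representative:
## the consensus 3' base `c` lands at read position `j`; overlap
## min(j, c) >= min_overlap with <= 1 mismatch. Per read, the last
## consensus-matching base is the largest valid `c`; the consensus is
## trimmed to the modal such position and junctions recomputed there.
call_junctions <- function(consensus, reps, cl_ids, min_overlap = 12,
                           max_mismatch = 1, trim_search = 5) {
  M <- nchar(consensus)
  c_last <- vapply(reps, function(r) {
    for (c in M:max(M - trim_search, min_overlap)) {
      if (!is.na(best_junction(r, substr(consensus, 1, c), min_overlap, max_mismatch)))
        return(c)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  ok <- !is.na(c_last)
  if (!any(ok)) {
    return(structure(list(consensus = consensus, support = 0L,
                          junctions = integer(0), flags = leader_flags(consensus)),
                     class = "leader_candidate"))
  }
  c_mode <- modal_value(c_last[ok])
  cons <- substr(consensus, 1, c_mode)
  j <- vapply(reps, best_junction, integer(1),
              consensus = cons, min_overlap = min_overlap,
              max_mismatch = max_mismatch, USE.NAMES = FALSE)
  ok <- !is.na(j)
  structure(list(consensus = cons, support = sum(ok),
                 junctions = setNames(j[ok], cl_ids[ok]),
                 flags = leader_flags(cons)),
            class = "leader_candidate")
}

## read position of the consensus 3' end, NA when no acceptable placement;
## the 3'-anchor base must match exactly (so the single-mismatch tolerance
## cannot silently absorb a consensus overrun); placements are scored by
## overlap (desc), then mismatches, then position
best_junction <- function(read, consensus, min_overlap = 12, max_mismatch = 1) {
  M <- nchar(consensus)
  nr <- nchar(read)
  last_base <- substring(consensus, M)
  best <- NULL
  for (j in min_overlap:min(nr, M + min_overlap + 8)) {
    ov <- min(j, M)
    if (ov < min_overlap) next
    if (substr(read, j, j) != last_base) next
    mm <- mismatch_count(substring(consensus, M - ov + 1),
                         substr(read, j - ov + 1, j))
    if (mm > max_mismatch) next
    if (is.null(best) || ov > best$ov || (ov == best$ov && mm < best$mm))
      best <- list(j = j, ov = ov, mm = mm)
  }
  if (is.null(best)) NA_integer_ else best$j
}

modal_value <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

leader_flags <- function(consensus) {
  list(has_uuu = grepl("TTT", consensus) || grepl("UUU", consensus),
       terminal_g = substring(consensus, nchar(consensus)) == "G",
       length_ok = nchar(consensus) >= 16 && nchar(consensus) <= 52)
}

#' @export
print.leader_candidate <- function(x, ...) {
  cat(sprintf("<leader_candidate %s (%d nt) support=%d uuu=%s 3'G=%s len_ok=%s>\n",
              x$consensus, nchar(x$consensus), x$support,
              x$flags$has_uuu, x$flags$terminal_g, x$flags$length_ok))
  invisible(x)
}

#' Observed attached-leader length spectrum
#'
#' For every read in the clusters supporting a leader candidate, reports the
#' length of its 5' segment matching a suffix of the consensus — the
#' attached leader length, whose spread reflects SL-donor TSS heterogeneity.
#'
#' @param candidate a `leader_candidate`.
#' @param clusters the clusters the candidate was called from.
#' @return integer vector (multiset) of observed leader lengths.
#' @export
leader_length_spectrum <- function(candidate, clusters) {
  sup <- names(candidate$junctions)
  if (!length(sup)) return(integer(0))
  out <- integer(0)
  for (cl in clusters) {
    if (!(cl$cluster_id %in% sup)) next
    j <- vapply(cl$member_seqs, best_junction, integer(1),
                consensus = candidate$consensus, USE.NAMES = FALSE)
    out <- c(out, j[!is.na(j)])
  }
  out
}

#' Collect reads containing the conserved leader core
#'
#' Forward orientation only (5'-end reads are stranded); records the match
#' offset per read.
#'
#' @param reads a [seq_set()].
#' @param core conserved core sequence (>= 12 nt).
#' @param max_mismatch mismatches tolerated (default 0).
#' @return the matching subset of `reads` with a `core_offset` column
#'   (1-based position of the core match).
#' @export
collect_sl_reads <- function(reads, core, max_mismatch = 0) {
  if (nchar(core) < 12) stop("core must be at least 12 nt")
  if (max_mismatch == 0) {
    off <- regexpr(core, reads$seq, fixed = TRUE)
    keep <- off > 0
  } else {
    m <- Biostrings::vmatchPattern(core, Biostrings::DNAStringSet(reads$seq),
                                   max.mismatch = max_mismatch, fixed = TRUE)
    st <- Biostrings::startIndex(m)
    off <- vapply(st, function(x) if (is.null(x) || !length(x)) -1L else min(x),
                  integer(1))
    keep <- off > 0
  }
  out <- reads[keep, , drop = FALSE]
  out$core_offset <- as.integer(off[keep])
  out
}
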