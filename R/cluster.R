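## Greedy k-mer read clustering. Stands in for contig assembly as a
## grouping mechanism: only per-gene grouping, not contiguity, is consumed
## downstream. Input is sorted by descending length (then id) first, so the
## procedure is deterministic; the representative of a cluster is its
## longest member (the founder).
greedy_kmer_cluster <- function(ids, keys, full_seqs, k, share_min) {
  ord <- order(-nchar(keys), ids)
  ids <- ids[ord]; keys <- keys[ord]; full_seqs <- full_seqs[ord]
  rep_kmers <- list()
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    kf <- kmers(keys[i], k)
    placed <- FALSE
    if (length(kf)) {
      for (c in seq_along(rep_kmers)) {
        if (mean(kf %in% rep_kmers[[c]]) >= share_min) {
          assignment[i] <- c
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      rep_kmers[[length(rep_kmers) + 1]] <- kf
      assignment[i] <- length(rep_kmers)
    }
  }
  lapply(seq_along(rep_kmers), function(c) {
    idx <- which(assignment == c)
    structure(list(cluster_id = sprintf("cl%04d", c),
                   member_ids = ids[idx],
                   member_seqs = full_seqs[idx],
                   representative = full_seqs[idx[1]],
                   representative_id = ids[idx[1]]),
              class = "read_cluster")
  })
}

#' @export
print.read_cluster <- function(x, ...) {
  cat(sprintf("<read_cluster %s: %d reads, representative %s (%d nt)>\n",
              x$cluster_id, length(x$member_ids), x$representative_id,
              nchar(x$representative)))
  invisible(x)
}

#' Cluster reads by gene of origin
#'
#' Greedy k-mer clustering on the read *body* (the sequence after the first
#' `skip_5p` bases, so a shared 5' leader cannot glue unrelated genes
#' together): a read joins the first cluster whose representative shares at
#' least `share_min` of its body k-mers, else founds a new cluster. Input is
#' sorted by descending length for determinism; the representative is the
#' longest member.
#'
#' @param reads a [seq_set()]; reads shorter than `skip_5p + k` found their
#'   own clusters.
#' @param skip_5p leading bases excluded from the clustering key (default 40).
#' @param k k-mer length (default 15).
#' @param share_min k-mer sharing fraction required to join (default 0.5).
#' @return list of `read_cluster` objects.
#' @export
cluster_by_gene <- function(reads, skip_5p = 40, k = 15, share_min = 0.5) {
  reads <- reads[!duplicated(reads$id), , drop = FALSE]
  keys <- substring(reads$seq, skip_5p + 1)
  greedy_kmer_cluster(reads$id, keys, reads$seq, k, share_min)
}

#' Group leader-bearing reads by their downstream (gene) sequence
#'
#' Clusters reads on the sequence downstream of the conserved-core match
#' (the gene-specific tail), approximating the per-gene contigs an assembler
#' would produce from leader-bearing reads.
#'
#' @param sl_reads a [seq_set()] with a `core_offset` column (from
#'   [collect_sl_reads()]).
#' @param core the conserved core sequence whose match position anchors the
#'   tail.
#' @param k k-mer length (default 12).
#' @param share_min sharing fraction (default 0.5).
#' @return list of `read_cluster` objects.
#' @export
group_sl_tails <- function(sl_reads, core, k = 12, share_min = 0.5) {
  if (is.null(sl_reads$core_offset)) stop("sl_reads must come from collect_sl_reads()")
  tails <- substring(sl_reads$seq, sl_reads$core_offset + nchar(core))
  greedy_kmer_cluster(sl_reads$id, tails, sl_reads$seq, k, share_min)
}
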