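#' Adapter trimming specification
#'
#' @param linker_5p 5' linker sequence expected at the read start.
#' @param adapter_3p 3' adapter sequence.
#' @param max_mismatch mismatches tolerated in a linker/adapter match (<= 2).
#' @param min_overlap minimum 3'-adapter overlap (nt).
#' @return a `trim_spec` list.
#' @export
trim_spec <- function(linker_5p, adapter_3p, max_mismatch = 1L, min_overlap = 5L) {
  if (!nzchar(linker_5p) || !nzchar(adapter_3p))
    stop("linker and adapter sequences must be non-empty")
  if (max_mismatch > 2) stop("max_mismatch must be <= 2")
  structure(list(linker_5p = toupper(linker_5p), adapter_3p = toupper(adapter_3p),
                 max_mismatch = as.integer(max_mismatch),
                 min_overlap = as.integer(min_overlap)),
            class = "trim_spec")
}

mismatch_count <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

#' Trim 5' linker and 3' adapter sequences
#'
#' The 5' linker is removed when it matches at the read start within
#' `max_mismatch`; the 3' adapter is removed from the first (leftmost)
#' position where the read suffix matches an adapter prefix of at least
#' `min_overlap` nt within `max_mismatch`. Reads with neither match pass
#' through unchanged and are flagged.
#'
#' @param reads a [seq_set()].
#' @param spec a [trim_spec()].
#' @return list with `reads` (trimmed; logical column `untrimmed` marks
#'   untouched reads) and `report` (a [filter_report()]).
#' @export
trim_adapters <- function(reads, spec) {
  stopifnot(inherits(spec, "trim_spec"))
  n <- nrow(reads)
  lk <- spec$linker_5p; nl <- nchar(lk)
  seqs <- reads$seq
  touched <- logical(n)
  from <- rep(1L, n)
  to <- nchar(seqs)
  for (i in seq_len(n)) {
    s <- seqs[i]
    if (nchar(s) >= nl && mismatch_count(substr(s, 1, nl), lk) <= spec$max_mismatch) {
      from[i] <- nl + 1L
      touched[i] <- TRUE
    }
    pos <- adapter_start(substr(s, from[i], to[i]), spec$adapter_3p,
                         spec$max_mismatch, spec$min_overlap)
    if (!is.na(pos)) {
      to[i] <- from[i] + pos - 2L
      touched[i] <- TRUE
    }
  }
  out <- reads
  out$seq <- substr(seqs, from, to)
  if (!is.null(out$qual)) out$qual <- substr(out$qual, from, to)
  out$untrimmed <- !touched
  out <- out[nzchar(out$seq), , drop = FALSE]
  list(reads = out,
       report = filter_report("trim_adapters", n, nrow(out),
                              c(empty_after_trim = n - nrow(out))))
}

## leftmost read position where a prefix of the adapter (>= min_overlap)
## matches through the read end within max_mismatch
adapter_start <- function(read, adapter, max_mismatch, min_overlap) {
  nr <- nchar(read); na <- nchar(adapter)
  if (nr < min_overlap) return(NA_integer_)
  for (pos in 1:(nr - min_overlap + 1)) {
    ov <- min(na, nr - pos + 1)
    if (ov < min_overlap) break
    if (mismatch_count(substr(read, pos, pos + ov - 1), substr(adapter, 1, ov)) <=
        max_mismatch)
      return(pos)
  }
  NA_integer_
}

#' Discard short reads
#'
#' @param reads a [seq_set()].
#' @param min_len minimum length kept (default 30 nt; shorter reads are
#'   discarded).
#' @return list with `reads` and `report`.
#' @export
length_filter <- function(reads, min_len = 30) {
  n <- nrow(reads)
  keep <- nchar(reads$seq) >= min_len
  list(reads = reads[keep, , drop = FALSE],
       report = filter_report("length_filter", n, sum(keep),
                              c(too_short = sum(!keep))))
}

#' Screen reads against contaminant/rRNA references
#'
#' In `kmer` mode a read is removed when at least `containment_min` of its
#' k-mers (on either strand) occur in the reference k-mer set; in `table`
#' mode a read is removed when its id appears in a supplied hit table
#' (letting an external aligner's output stand in for the built-in screen).
#'
#' @param reads a [seq_set()].
#' @param refs reference sequences ([seq_set()]) for `kmer` mode.
#' @param hit_table character vector (or 1-column data frame) of read ids
#'   for `table` mode.
#' @param k k-mer length (default 15).
#' @param containment_min fraction of read k-mers that must be contained for
#'   removal. The default 0.5 sits well below the expected k-mer survival of
#'   a true contaminant read ((1-e)^k, about 0.93 at a 0.5% error rate) and
#'   far above the chance containment of an unrelated read (about 4^-k per
#'   k-mer), so the decision is insensitive to sequencing error.
#' @param mode `"kmer"` or `"table"`.
#' @return list with `kept`, `removed` and `report`.
#' @export
screen_references <- function(reads, refs = NULL, hit_table = NULL, k = 15,
                              containment_min = 0.5,
                              mode = c("kmer", "table")) {
  mode <- match.arg(mode)
  n <- nrow(reads)
  if (mode == "table") {
    if (is.null(hit_table)) stop("table mode requires a hit table")
    ids <- if (is.data.frame(hit_table)) hit_table[[1]] else hit_table
    hit <- reads$id %in% ids
  } else {
    if (is.null(refs)) stop("kmer mode requires reference sequences")
    ref_kmers <- unique(unlist(lapply(refs$seq, kmers, k = k)))
    hit <- vapply(reads$seq, function(s) {
      kf <- kmers(s, k)
      if (!length(kf)) {
        warning("read shorter than k: kept")
        return(FALSE)
      }
      cf <- mean(kf %in% ref_kmers)
      cr <- mean(kmers(revcomp(s), k) %in% ref_kmers)
      max(cf, cr) >= containment_min
    }, logical(1), USE.NAMES = FALSE)
  }
  list(kept = reads[!hit, , drop = FALSE],
       removed = reads[hit, , drop = FALSE],
       report = filter_report("screen_references", n, sum(!hit),
                              c(reference_hit = sum(hit))))
}

#' Select reads encoding protein N-termini
#'
#' A read is kept when any of its six reading frames (frames split at stop
#' codons before seeding) contains an exact `seed_len`-residue word from the
#' first `n_term_len` residues of any supplied protein, extended ungapped
#' under BLOSUM62 to a score of at least `min_score`.
#'
#' @param reads a [seq_set()].
#' @param proteins a [seq_set()] of protein sequences.
#' @param n_term_len N-terminal window searched (aa).
#' @param seed_len exact seed length (aa).
#' @param min_score minimum ungapped extension score.
#' @return list with `kept` and `report`.
#' @export
select_protein_proximal <- function(reads, proteins, n_term_len = 50,
                                    seed_len = 8, min_score = 40) {
  n <- nrow(reads)
  blosum <- get_blosum62()
  ## index: seed word -> matrix of (protein index, position)
  index <- new.env(hash = TRUE, parent = emptyenv())
  nterm <- character(nrow(proteins))
  for (p in seq_len(nrow(proteins))) {
    aa <- proteins$seq[p]
    if (nchar(aa) < seed_len) {
      warning("protein ", proteins$id[p], " shorter than seed length: skipped")
      next
    }
    win <- substr(aa, 1, n_term_len)
    nterm[p] <- win
    for (pos in 1:(nchar(win) - seed_len + 1)) {
      w <- substr(win, pos, pos + seed_len - 1)
      index[[w]] <- rbind(index[[w]] %||% NULL, c(p, pos))
    }
  }
  pep <- six_frame_peptides(reads$seq)
  keep <- logical(n)
  if (nrow(pep)) {
    ## enumerate seed words across all peptides at once
    np <- nchar(pep$pep)
    ok <- np >= seed_len
    pep <- pep[ok, , drop = FALSE]; np <- np[ok]
    if (nrow(pep)) {
      reps <- np - seed_len + 1L
      widx <- rep.int(seq_len(nrow(pep)), reps)
      starts <- unlist(lapply(reps, seq_len), use.names = FALSE)
      words <- substr(rep.int(pep$pep, reps), starts, starts + seed_len - 1L)
      hit <- which(words %in% ls(index))
      for (h in hit) {
        ri <- pep$read[widx[h]]
        if (keep[ri]) next
        entries <- index[[words[h]]]
        for (e in seq_len(nrow(entries))) {
          sc <- extend_ungapped(pep$pep[widx[h]], starts[h],
                                nterm[entries[e, 1]], entries[e, 2],
                                seed_len, blosum)
          if (sc >= min_score) { keep[ri] <- TRUE; break }
        }
      }
    }
  }
  list(kept = reads[keep, , drop = FALSE],
       report = filter_report("select_protein_proximal", n, sum(keep),
                              c(no_protein_match = sum(!keep))))
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

## translate all six frames of all reads (batched), split at stop codons;
## returns a data frame of (read index, peptide)
six_frame_peptides <- function(seqs) {
  frames <- character(0); owner <- integer(0)
  rc <- revcomp(seqs)
  for (s in list(seqs, rc)) {
    for (off in 0:2) {
      sub <- substring(s, off + 1)
      len <- nchar(sub) - nchar(sub) %% 3
      keep <- len >= 3
      if (!any(keep)) next
      frames <- c(frames, substr(sub[keep], 1, len[keep]))
      owner <- c(owner, which(keep))
    }
  }
  if (!length(frames)) return(data.frame(read = integer(0), pep = character(0)))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(frames),
                                           if.fuzzy.codon = "X"))
  segs <- strsplit(aa, "*", fixed = TRUE)
  lens <- lengths(segs)
  data.frame(read = rep.int(owner, lens), pep = unlist(segs, use.names = FALSE),
             stringsAsFactors = FALSE)
}

## best ungapped extension score around an exact seed
extend_ungapped <- function(pep, ppos, prot, qpos, seed_len, blosum) {
  score_pair <- function(a, b) {
    if (a %in% rownames(blosum) && b %in% colnames(blosum)) blosum[a, b] else -4
  }
  pp <- strsplit(pep, "")[[1]]; qq <- strsplit(prot, "")[[1]]
  base <- sum(vapply(0:(seed_len - 1), function(i)
    score_pair(pp[ppos + i], qq[qpos + i]), numeric(1)))
  ## rightward
  best_r <- 0; run <- 0
  i <- ppos + seed_len; j <- qpos + seed_len
  while (i <= length(pp) && j <= length(qq)) {
    run <- run + score_pair(pp[i], qq[j])
    if (run > best_r) best_r <- run
    i <- i + 1; j <- j + 1
  }
  ## leftward
  best_l <- 0; run <- 0
  i <- ppos - 1; j <- qpos - 1
  while (i >= 1 && j >= 1) {
    run <- run + score_pair(pp[i], qq[j])
    if (run > best_l) best_l <- run
    i <- i - 1; j <- j - 1
  }
  base + best_r + best_l
}
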