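#' Genome-wide scan for SL RNA gene loci
#'
#' Scans both strands of every contig for the conserved leader core followed
#' by an exact splice-donor dinucleotide, tolerating up to `max_mismatch`
#' substitutions in the core. Overlapping placements are merged keeping the
#' lowest-mismatch one (ties: plus strand, then leftmost).
#'
#' @param contigs a [seq_set()] of genome contigs.
#' @param leader_core conserved core sequence (>= 12 nt).
#' @param donor splice-donor dinucleotide (default `"GT"`, matched exactly).
#' @param max_mismatch substitutions tolerated in the core (default 2).
#' @param downstream_window intron-side context captured per locus
#'   (default 300 nt); `truncated` is set when the contig ends inside it.
#' @return data frame of loci: contig, strand, strand-coordinate exon
#'   interval, donor position (first base of the donor), mismatches, exon
#'   and downstream sequences, truncation flag.
#' @export
scan_loci <- function(contigs, leader_core, donor = "GT", max_mismatch = 2,
                      downstream_window = 300) {
  if (nchar(leader_core) < 12) stop("leader_core must be at least 12 nt")
  hits <- list()
  for (i in seq_len(nrow(contigs))) {
    L <- nchar(contigs$seq[i])
    for (strand in c("+", "-")) {
      subject <- oriented_contig(contigs, contigs$id[i], strand)
      m <- Biostrings::matchPattern(leader_core, Biostrings::DNAString(subject),
                                    max.mismatch = max_mismatch, fixed = TRUE)
      for (h in seq_along(m)) {
        s <- BiocGenerics::start(m)[h]; e <- BiocGenerics::end(m)[h]
        if (e + nchar(donor) > nchar(subject)) next
        if (substr(subject, e + 1, e + nchar(donor)) != donor) next
        mm <- mismatch_count(substr(subject, s, e), leader_core)
        avail <- nchar(subject) - e
        down <- substr(subject, e + 1, min(nchar(subject), e + downstream_window))
        ## forward-coordinate footprint, for overlap merging across strands
        fs <- if (strand == "+") s else L - e + 1
        fe <- if (strand == "+") e else L - s + 1
        hits[[length(hits) + 1]] <- data.frame(
          contig = contigs$id[i], strand = strand,
          exon_start = s, exon_end = e, donor_pos = e + 1L,
          mismatches = mm, exon_seq = substr(subject, s, e),
          downstream_seq = down,
          truncated = avail < downstream_window,
          fwd_start = fs, fwd_end = fe, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(0), strand = character(0),
                      exon_start = integer(0), exon_end = integer(0),
                      donor_pos = integer(0), mismatches = integer(0),
                      exon_seq = character(0), downstream_seq = character(0),
                      truncated = logical(0), fwd_start = integer(0),
                      fwd_end = integer(0)))
  }
  df <- do.call(rbind, hits)
  ## merge overlapping placements per contig, keeping the lowest mismatch
  keep <- logical(nrow(df))
  for (ctg in unique(df$contig)) {
    idx <- which(df$contig == ctg)
    idx <- idx[order(df$mismatches[idx], df$strand[idx] != "+", df$fwd_start[idx])]
    taken <- matrix(numeric(0), ncol = 2)
    for (r in idx) {
      ov <- nrow(taken) && any(df$fwd_start[r] <= taken[, 2] &
                               df$fwd_end[r] >= taken[, 1])
      if (!ov) {
        keep[r] <- TRUE
        taken <- rbind(taken, c(df$fwd_start[r], df$fwd_end[r]))
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$contig, df$fwd_start), , drop = FALSE]
  df$locus_id <- sprintf("locus%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

#' Classify SL gene loci into subtypes by their intronic sequence
#'
#' Computes pairwise global identity of the first `intron_prefix` nt
#' downstream of the donor dinucleotide (end-gap-free; gaps count as
#' mismatches), single-linkage clusters at `identity_min`, and names
#' clusters SL-I, SL-II, ... by descending copy number. Singletons and loci
#' with fewer than 20 nt of downstream sequence are labelled `unassigned`.
#'
#' @param loci data frame from [scan_loci()].
#' @param intron_prefix intron comparison window (default 60 nt).
#' @param identity_min single-linkage identity threshold (default 0.8).
#' @return `loci` with columns `subtype_label` and `unassigned_reason`.
#' @export
classify_subtypes <- function(loci, intron_prefix = 60, identity_min = 0.8) {
  n <- nrow(loci)
  if (n < 2) {
    loci$subtype_label <- rep("unassigned", n)
    loci$unassigned_reason <- rep(if (n) "single locus" else character(0), n)
    return(loci)
  }
  ## intron proper starts after the 2-nt donor
  introns <- substr(loci$downstream_seq, 3, 2 + intron_prefix)
  usable <- nchar(introns) >= 20
  idx <- which(usable)
  parent <- seq_along(idx)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_along(idx)) {
    for (b in seq_len(a - 1L)) {
      if (pair_identity(introns[idx[a]], introns[idx[b]]) >= identity_min) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_along(idx), find, integer(1))
  sizes <- table(comp)
  big <- names(sizes)[sizes >= 2]
  big <- big[order(-sizes[big], as.integer(big))]
  label <- rep("unassigned", n)
  reason <- ifelse(usable, NA_character_, "truncated")
  for (r in seq_along(big)) {
    label[idx[comp == as.integer(big[r])]] <- paste0("SL-", as.character(utils::as.roman(r)))
  }
  reason[usable & label == "unassigned"] <- "singleton"
  loci$subtype_label <- label
  loci$unassigned_reason <- reason
  loci
}

## end-gap-free identity: matches over the longer sequence, so a gap scores
## as a mismatch
pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) 1 - hamming(a, b) / nchar(a) else seq_identity(a, b)
}

#' Progressive alignment and conserved-block calling
#'
#' Aligns the sequences progressively (guide order by pairwise identity;
#' global alignment with match +1 / mismatch -1 / gap -2 per position),
#' computes per-column conservation as the modal-residue fraction among
#' non-gap rows, and reports the maximal conserved block anchored at the
#' exon start whose sliding-window mean conservation stays at or above
#' `conservation_min`.
#'
#' @param seqs character vector of locus sequences of one subtype, each
#'   starting at the exon's first base.
#' @param window sliding window (default 10 columns).
#' @param conservation_min window-mean conservation threshold (default 0.9).
#' @return list with `alignment` (character matrix, one row per input),
#'   `conservation` (per column) and `conserved_block` (`c(start, end)`
#'   column interval; `c(NA, NA)` when even the first window fails).
#' @export
align_and_conserved_block <- function(seqs, window = 10, conservation_min = 0.9) {
  if (length(seqs) < 3) stop("insufficient members: need at least 3 sequences")
  ord <- guide_order(seqs)
  aln <- matrix(strsplit(seqs[ord[1]], "")[[1]], nrow = 1)
  for (s in ord[-1]) {
    aln <- profile_add(aln, seqs[s])
  }
  aln <- aln[order(ord), , drop = FALSE]
  cons <- apply(aln, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(table(col)) / length(col)
  })
  ## occupancy-weighted variant (gaps count against the column): guards the
  ## block boundary against sparse aligner-artifact columns
  occ_cons <- apply(aln, 2, function(col) {
    nz <- col[col != "-"]
    if (!length(nz)) return(0)
    max(table(nz)) / length(col)
  })
  nc <- length(cons)
  if (nc < window) return(list(alignment = aln, conservation = cons,
                               conserved_block = c(NA_integer_, NA_integer_)))
  w <- vapply(window:nc, function(i) mean(cons[(i - window + 1):i]), numeric(1))
  fail <- which(w < conservation_min)
  if (length(fail) && fail[1] == 1)
    return(list(alignment = aln, conservation = cons,
                conserved_block = c(NA_integer_, NA_integer_)))
  end_col <- if (!length(fail)) nc else (window:nc)[fail[1]] - 1L
  ## window smoothing must not bleed the boundary: the block ends at the
  ## last column that itself meets the threshold with full-row support
  while (end_col > 0 && occ_cons[end_col] < conservation_min) end_col <- end_col - 1L
  list(alignment = aln, conservation = cons,
       conserved_block = c(1L, end_col))
}

## addition order: most central sequence (highest mean identity) first,
## then by decreasing mean identity
guide_order <- function(seqs) {
  n <- length(seqs)
  idm <- diag(1, n)
  for (a in 2:n) for (b in 1:(a - 1)) {
    idm[a, b] <- idm[b, a] <- pair_identity(seqs[a], seqs[b])
  }
  order(-colMeans(idm))
}

## align one sequence against the profile's consensus string and splice it in
profile_add <- function(aln, seq) {
  consensus <- apply(aln, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) "N" else names(which.max(table(col)))
  })
  cons_str <- paste(consensus, collapse = "")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(seq, cons_str, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ## subject gaps are insertions relative to the existing profile
  out <- matrix("-", nrow = nrow(aln) + 1, ncol = length(s))
  col_from <- cumsum(s != "-")
  for (j in seq_along(s)) {
    if (s[j] != "-") out[seq_len(nrow(aln)), j] <- aln[, col_from[j]]
  }
  out[nrow(out), ] <- p
  out
}

#' Map capped-read 5' ends onto an SL gene locus
#'
#' Aligns each read to the locus region, accepts alignments with identity at
#' least `min_identity` and aligned-length/read-length above `min_coverage`,
#' and records the locus coordinate of read base 1 as the TSS. Modal
#' positions are all positions with at least half the maximal count.
#'
#' @param reads a [seq_set()] of capped 5'-end reads.
#' @param region locus region sequence (exon plus context).
#' @param exon_pos position of the exon's first base within `region`
#'   (TSS positions are reported relative to it: exon start = +1, upstream
#'   negative, no 0).
#' @param min_identity,min_coverage acceptance thresholds.
#' @return a `tss_profile` list: `profile` (position/count data frame),
#'   `modal_positions`, `n_accepted`, `n_rejected`.
#' @export
map_tss <- function(reads, region, exon_pos = 1, min_identity = 0.95,
                    min_coverage = 0.9) {
  if (nchar(region) < 100) stop("locus region must provide >= 100 nt of context")
  tss <- integer(0)
  rej <- 0L
  if (nrow(reads)) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(reads$seq),
                                        region, type = "local")
    for (i in seq_len(nrow(reads))) {
      a <- pa[i]
      alen <- Biostrings::nchar(a)
      ident <- Biostrings::nmatch(a) / alen
      pr <- a@pattern@range
      cov <- (BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1) / nchar(reads$seq[i])
      if (ident >= min_identity && cov > min_coverage) {
        start_subj <- BiocGenerics::start(a@subject@range)
        t0 <- start_subj - (BiocGenerics::start(pr) - 1L)
        d <- t0 - exon_pos
        tss <- c(tss, if (d >= 0) d + 1L else d)
      } else rej <- rej + 1L
    }
  }
  if (length(tss)) {
    prof <- as.data.frame(table(tss), stringsAsFactors = FALSE)
    names(prof) <- c("position", "count")
    prof$position <- as.integer(prof$position)
    prof$count <- as.integer(prof$count)
  } else {
    prof <- data.frame(position = integer(0), count = integer(0))
  }
  modal <- if (nrow(prof)) prof$position[prof$count >= 0.5 * max(prof$count)] else integer(0)
  structure(list(profile = prof, modal_positions = modal,
                 n_accepted = length(tss), n_rejected = rej),
            class = "tss_profile")
}

motif_hit_df <- function(motif = character(0), start = integer(0),
                         end = integer(0), match = character(0), ...) {
  data.frame(motif = motif, start = start, end = end, match = match, ...,
             stringsAsFactors = FALSE)
}

#' Scan for the canonical polyadenylation signal AATAAA
#'
#' Exact scan downstream of `search_start` (typically the conserved-block
#' end); the offset is measured from `search_start` to the first base of the
#' hexamer. All hits are returned; the first is flagged primary.
#'
#' @param seq locus sequence.
#' @param search_start reference position the offset is measured from.
#' @return motif-hit data frame with `offset` and `primary` columns.
#' @export
find_polya_signal <- function(seq, search_start = 0) {
  pos <- find_all("AATAAA", seq)
  pos <- pos[pos > search_start]
  if (!length(pos)) return(motif_hit_df(offset = integer(0), primary = logical(0)))
  motif_hit_df(motif = "polya_signal", start = pos, end = pos + 5L,
               match = substring(seq, pos, pos + 5L),
               offset = pos - as.integer(search_start),
               primary = seq_along(pos) == 1)
}

#' Scan for pyrimidine-stretch terminators
#'
#' Maximal C/T runs of at least `min_len` nt containing a run of at least
#' `min_polyT` consecutive T (the protist-style SL RNA transcription
#' terminator element).
#'
#' @param seq sequence to scan.
#' @param min_len minimum stretch length (default 6).
#' @param min_polyT minimum consecutive-T run inside the stretch (default 3).
#' @return motif-hit data frame.
#' @export
find_pyrimidine_terminator <- function(seq, min_len = 6, min_polyT = 3) {
  s <- chartr("U", "T", toupper(seq))
  m <- gregexpr("[CT]+", s)[[1]]
  if (m[1] == -1) return(motif_hit_df())
  len <- attr(m, "match.length")
  keep <- len >= min_len
  pos <- as.integer(m)[keep]; len <- len[keep]
  if (!length(pos)) return(motif_hit_df())
  runs <- substring(s, pos, pos + len - 1)
  has_t <- grepl(strrep("T", min_polyT), runs, fixed = TRUE)
  pos <- pos[has_t]; len <- len[has_t]
  if (!length(pos)) return(motif_hit_df())
  motif_hit_df(motif = "pyrimidine_terminator", start = pos,
               end = pos + len - 1L, match = substring(seq, pos, pos + len - 1L))
}

#' Scan for the nematode 3'-box terminator element
#'
#' Exact and single-mismatch scan for GTTTAAAACAAGC.
#'
#' @param seq sequence to scan.
#' @return motif-hit data frame with a `mismatches` column.
#' @export
find_3prime_box <- function(seq) {
  box <- "GTTTAAAACAAGC"
  s <- chartr("U", "T", toupper(seq))
  if (nchar(s) < nchar(box)) return(motif_hit_df(mismatches = integer(0)))
  m <- Biostrings::matchPattern(box, Biostrings::DNAString(s),
                                max.mismatch = 1, fixed = TRUE)
  if (!length(m)) return(motif_hit_df(mismatches = integer(0)))
  st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
  motif_hit_df(motif = "three_prime_box", start = st, end = en,
               match = substring(seq, st, en),
               mismatches = vapply(seq_along(st), function(i)
                 mismatch_count(substr(s, st[i], en[i]), box), integer(1)))
}

#' Scan for the canonical Sm binding consensus
#'
#' Matches AAU(3-6)G(G/U) (trypanosome/nematode consensus); U and T are
#' equivalent. Overlapping occurrences are all reported, longest match at
#' each start.
#'
#' @param seq RNA or DNA sequence.
#' @return motif-hit data frame.
#' @export
find_canonical_sm <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  res <- motif_hit_df()
  for (i in seq_len(max(n - 6, 0))) {
    m <- regexpr("^AAT{3,6}G[GT]", substring(s, i))
    if (m == 1) {
      len <- attr(m, "match.length")
      res <- rbind(res, motif_hit_df(motif = "sm_canonical", start = i,
                                     end = i + len - 1L,
                                     match = substring(seq, i, i + len - 1L)))
    }
  }
  res
}

#' Scan for a relaxed (pyrimidine-rich) Sm binding site
#'
#' Candidate windows start with A, end with G, have an interior of at least
#' `interior_min` nt with pyrimidine fraction at least `pyrimidine_min_frac`,
#' and lie at least 80% in single-stranded (unpaired) positions of the
#' supplied secondary structure. Only maximal windows are reported.
#'
#' @param seq RNA or DNA sequence.
#' @param structure a `secondary_structure` covering `seq`.
#' @param pyrimidine_min_frac minimum interior pyrimidine fraction
#'   (default 0.8).
#' @param interior_min minimum interior length (default 8 nt).
#' @return motif-hit data frame.
#' @export
find_relaxed_sm <- function(seq, structure, pyrimidine_min_frac = 0.8,
                            interior_min = 8) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  if (nchar(structure$dotbracket) != n)
    stop("structure/sequence length mismatch")
  ch <- strsplit(s, "")[[1]]
  unpaired <- strsplit(structure$dotbracket, "")[[1]] == "."
  pyr <- ch %in% c("C", "T")
  cpyr <- cumsum(pyr); cun <- cumsum(unpaired)
  a_pos <- which(ch == "A"); g_pos <- which(ch == "G")
  cand <- list()
  for (i in a_pos) {
    for (j in g_pos[g_pos >= i + interior_min + 1]) {
      interior <- j - i - 1
      pf <- (cpyr[j - 1] - cpyr[i]) / interior
      if (pf < pyrimidine_min_frac) next
      uf <- (cun[j] - if (i > 1) cun[i - 1] else 0) / (j - i + 1)
      if (uf < 0.8) next
      cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  if (!length(cand)) return(motif_hit_df())
  iv <- do.call(rbind, cand)
  maximal <- vapply(seq_len(nrow(iv)), function(r) {
    !any(iv[, 1] <= iv[r, 1] & iv[, 2] >= iv[r, 2] &
         (iv[, 1] != iv[r, 1] | iv[, 2] != iv[r, 2]))
  }, logical(1))
  iv <- iv[maximal, , drop = FALSE]
  motif_hit_df(motif = "sm_relaxed", start = iv[, 1], end = iv[, 2],
               match = substring(seq, iv[, 1], iv[, 2]))
}

#' Infer poly(A) cleavage sites from polyadenylated cDNAs
#'
#' Strips each cDNA's terminal A-run (genomic-templated A's are retained:
#' only A's absent from the locus at the aligned position are treated as
#' tail), aligns the remainder's 3' end to the locus, and reports the
#' distance from the last base of the primary AATAAA to the last templated
#' base.
#'
#' @param locus_seq locus genomic sequence.
#' @param cdnas a [seq_set()] of polyadenylated cDNAs (terminal A-run of at
#'   least `min_tail`).
#' @param signal_end locus position of the last base of the primary poly(A)
#'   signal; located automatically when `NULL`.
#' @param min_tail minimum terminal A-run (default 8).
#' @param min_identity alignment identity below which a cDNA is skipped with
#'   a warning (default 0.9).
#' @return integer vector of cleavage offsets, one per usable cDNA.
#' @export
infer_cleavage_sites <- function(locus_seq, cdnas, signal_end = NULL,
                                 min_tail = 8, min_identity = 0.9) {
  if (is.null(signal_end)) {
    hit <- find_polya_signal(locus_seq, 0)
    if (!nrow(hit)) stop("no poly(A) signal in locus")
    signal_end <- hit$end[hit$primary][1]
  }
  offsets <- integer(0)
  for (i in seq_len(nrow(cdnas))) {
    s <- cdnas$seq[i]
    body <- sub("A+$", "", s)
    tail_len <- nchar(s) - nchar(body)
    if (tail_len < min_tail) {
      warning("cDNA ", cdnas$id[i], " lacks a terminal A-run >= ", min_tail,
              ": skipped")
      next
    }
    pa <- Biostrings::pairwiseAlignment(body, locus_seq, type = "local")
    ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    pr <- pa@pattern@range
    cov <- (BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1) / nchar(body)
    if (ident < min_identity || cov < 0.9) {
      warning("cDNA ", cdnas$id[i], " does not align to the locus: skipped")
      next
    }
    p <- BiocGenerics::end(pa@subject@range)
    ## re-extend through genomic-templated A's
    left <- tail_len
    while (left > 0 && p < nchar(locus_seq) &&
           substr(locus_seq, p + 1, p + 1) == "A") {
      p <- p + 1L
      left <- left - 1L
    }
    offsets <- c(offsets, p - as.integer(signal_end))
  }
  offsets
}
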