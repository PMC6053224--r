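#' Gene model for trans-splice validation
#'
#' Bundles the genomic sequence of one gene (with the declared position of
#' the ATG initiation codon, so positions can be expressed relative to it:
#' A of ATG = +1, upstream negative, no position 0), its mature mRNA, and
#' optional capped 5'-end reads.
#'
#' @param genomic genomic sequence string.
#' @param mrna mature mRNA sequence string.
#' @param atg_pos 1-based genomic position of the A of the ATG codon.
#' @param capped_reads optional [seq_set()] of capped 5'-end reads.
#' @param id gene identifier.
#' @return a `gene_model`.
#' @export
gene_model <- function(genomic, mrna, atg_pos, capped_reads = NULL, id = "gene") {
  genomic <- toupper(genomic); mrna <- toupper(mrna)
  if (substr(genomic, atg_pos, atg_pos + 2) != "ATG")
    stop("no ATG at the declared position")
  structure(list(id = id, genomic = genomic, mrna = mrna,
                 atg_pos = as.integer(atg_pos), capped_reads = capped_reads),
            class = "gene_model")
}

## gene-relative coordinate (A of ATG = +1, no 0)
gene_rel <- function(pos, atg) ifelse(pos >= atg, pos - atg + 1L, pos - atg)

#' Locate the trans-splice acceptor of a gene
#'
#' Strips the leader match from the mRNA 5' end (a suffix of the leader of
#' at least 12 nt with at most one mismatch), aligns the following mRNA
#' region to the genomic sequence, and calls the acceptor as the genomic
#' base preceding the aligned start, checking for the AG splice-acceptor
#' motif and a pyrimidine-rich outron. The cis/trans verdict comes from
#' [decide_cis_trans()].
#'
#' @param model a [gene_model()].
#' @param leader leader sequence (5'->3').
#' @param upstream_window window passed to [decide_cis_trans()].
#' @return a `trans_splice_call`: acceptor position (genomic and
#'   ATG-relative), leader-matched prefix length, outron interval,
#'   pyrimidine-tract hits, verdict, evidence notes.
#' @export
locate_acceptor <- function(model, leader, upstream_window = 5000) {
  lead_len <- leader_prefix_length(model$mrna, leader)
  if (is.na(lead_len)) stop("not leader-bearing: mRNA lacks a leader prefix")
  body <- substr(model$mrna, lead_len + 1, lead_len + 60)
  m <- Biostrings::matchPattern(body, Biostrings::DNAString(model$genomic),
                                max.mismatch = 3, fixed = TRUE)
  notes <- character(0)
  if (length(m) == 0) {
    return(new_ts_call(model, NA, lead_len, "indeterminate",
                       "mRNA body does not align to genomic sequence"))
  }
  mm <- vapply(seq_along(m), function(h)
    mismatch_count(as.character(m[[h]]), body), integer(1))
  best <- which(mm == min(mm))
  if (length(best) > 1) {
    return(new_ts_call(model, NA, lead_len, "indeterminate",
                       "ambiguous alignment: two equal placements"))
  }
  aln_start <- BiocGenerics::start(m)[best]
  acceptor <- aln_start - 1L
  ag_ok <- acceptor >= 2 &&
    substr(model$genomic, acceptor - 1, acceptor) == "AG"
  if (!ag_ok) notes <- c(notes, "no AG dinucleotide at predicted acceptor")
  outron_start <- max(1L, acceptor - 200L)
  tract <- find_pyrimidine_terminator(substr(model$genomic, outron_start, acceptor),
                                      min_len = 6)
  if (nrow(tract)) {
    tract$start <- tract$start + outron_start - 1L
    tract$end <- tract$end + outron_start - 1L
    notes <- c(notes, "pyrimidine-rich outron tract detected")
  }
  if (ag_ok) {
    ct <- decide_cis_trans(model, leader, acceptor, upstream_window = upstream_window)
    verdict <- ct$verdict
    notes <- c(notes, ct$notes)
  } else {
    verdict <- "indeterminate"
  }
  call <- new_ts_call(model, acceptor, lead_len, verdict, notes)
  call$outron <- c(outron_start, acceptor)
  call$pyrimidine_tract <- tract
  call
}

new_ts_call <- function(model, acceptor, lead_len, verdict, notes) {
  structure(list(gene = model$id,
                 acceptor_pos = if (is.na(acceptor)) NA_integer_ else as.integer(acceptor),
                 acceptor_rel = if (is.na(acceptor)) NA_integer_ else
                   gene_rel(acceptor, model$atg_pos),
                 leader_match_len = lead_len,
                 outron = c(NA_integer_, NA_integer_),
                 pyrimidine_tract = motif_hit_df(),
                 verdict = verdict, notes = notes),
            class = "trans_splice_call")
}

## longest suffix of `leader` matching the mRNA prefix with <= 1 mismatch
leader_prefix_length <- function(mrna, leader, min_len = 12, max_mismatch = 1) {
  M <- nchar(leader)
  for (L in min(M, nchar(mrna)):min_len) {
    if (mismatch_count(substring(leader, M - L + 1), substr(mrna, 1, L)) <=
        max_mismatch)
      return(L)
  }
  NA_integer_
}

#' Decide between trans-splicing and long-range cis-splicing
#'
#' The verdict is `trans` when (i) the leader is absent (within one
#' mismatch) from the genomic window upstream of the acceptor, and (ii) when
#' capped reads are supplied, no accepted TSS lies upstream of the outron
#' TSS cluster. Failure of (i) yields `cis_possible`; insufficient evidence
#' yields `indeterminate`.
#'
#' @param model a [gene_model()].
#' @param leader leader sequence.
#' @param acceptor genomic acceptor position (the G of AG).
#' @param upstream_window upstream span searched for a leader copy
#'   (default 5000 nt; truncated to the available sequence with a note).
#' @param tss_cluster_span TSSs within this many nt of the modal TSS form
#'   the outron TSS cluster (default 20).
#' @return list with `verdict` and `notes`.
#' @export
decide_cis_trans <- function(model, leader, acceptor, upstream_window = 5000,
                             tss_cluster_span = 20) {
  notes <- character(0)
  from <- acceptor - upstream_window
  if (from < 1) {
    from <- 1L
    notes <- c(notes, "upstream window truncated to available sequence")
  }
  if (acceptor <= 1) return(list(verdict = "indeterminate",
                                 notes = "no upstream sequence"))
  up <- substr(model$genomic, from, acceptor - 1)
  m <- Biostrings::matchPattern(leader, Biostrings::DNAString(up),
                                max.mismatch = 1, fixed = TRUE)
  if (length(m) > 0) {
    return(list(verdict = "cis_possible",
                notes = c(notes, "leader copy found upstream of acceptor")))
  }
  if (is.null(model$capped_reads) || nrow(model$capped_reads) == 0) {
    return(list(verdict = "trans", notes = c(notes, "TSS evidence absent")))
  }
  prof <- map_tss(model$capped_reads, model$genomic, exon_pos = acceptor + 1L)
  if (prof$n_accepted == 0) {
    return(list(verdict = "indeterminate",
                notes = c(notes, "no capped reads aligned")))
  }
  pos <- rep(prof$profile$position, prof$profile$count)
  modal <- prof$modal_positions[1]
  cluster_lo <- min(pos[abs(pos - modal) <= tss_cluster_span])
  if (any(pos < cluster_lo - tss_cluster_span)) {
    return(list(verdict = "indeterminate",
                notes = c(notes, "transcripts start upstream of the outron TSS cluster")))
  }
  list(verdict = "trans", notes = notes)
}

#' Count introns by spliced alignment of a cDNA to its gene
#'
#' Chains ordered exact anchors (>= `anchor_len` nt) between the cDNA and
#' the genomic sequence; genomic gaps of at least `min_intron` nt at a
#' cDNA-contiguous junction are called introns, with the splice points
#' placed to give GT...AG boundaries when possible (flagged noncanonical
#' otherwise).
#'
#' @param genomic genomic sequence (string or 1-row [seq_set()]).
#' @param cdna cDNA sequence (string or 1-row [seq_set()]).
#' @param min_intron minimum intron length (default 40 nt).
#' @param anchor_len exact anchor word length (default 20 nt).
#' @return data frame of introns (`start`, `end` genomic, `cdna_pos` of the
#'   junction, `canonical` flag); zero rows for an intron-less gene.
#' @export
count_introns <- function(genomic, cdna, min_intron = 40, anchor_len = 20) {
  g <- if (is.data.frame(genomic)) genomic$seq[1] else genomic
  c0 <- if (is.data.frame(cdna)) cdna$seq[1] else cdna
  g <- toupper(g); c0 <- toupper(c0)
  ## drop a poly(A) tail if present: it is not genome-templated
  c1 <- sub("A{8,}$", "", c0)
  nc <- nchar(c1)
  if (nc < anchor_len) stop("no alignment: cDNA too short")
  ## genomic word index
  gk <- kmers(g, anchor_len, unique = FALSE)
  tab <- table(gk)
  unique_words <- names(tab)[tab == 1]
  gpos <- setNames(match(gk, gk), gk)  # first occurrence position per word
  anchors <- list()
  for (i in seq_len(nc - anchor_len + 1)) {
    w <- substr(c1, i, i + anchor_len - 1)
    if (w %in% unique_words) {
      anchors[[length(anchors) + 1]] <- c(i, gpos[[w]])
    }
  }
  if (!length(anchors)) stop("no alignment: no exact anchors")
  an <- do.call(rbind, anchors)
  an <- an[order(an[, 1]), , drop = FALSE]
  ## keep the longest chain with strictly increasing genomic position and
  ## non-decreasing diagonal (no genomic back-jumps)
  keep <- rep(TRUE, nrow(an))
  last_g <- -Inf; last_d <- -Inf
  for (r in seq_len(nrow(an))) {
    d <- an[r, 2] - an[r, 1]
    if (an[r, 2] <= last_g || d < last_d) { keep[r] <- FALSE; next }
    last_g <- an[r, 2]; last_d <- d
  }
  an <- an[keep, , drop = FALSE]
  diags <- an[, 2] - an[, 1]
  cov <- (max(an[, 1]) + anchor_len - min(an[, 1])) / nc
  if (cov < 0.5) stop("no alignment: anchors cover too little of the cDNA")
  introns <- data.frame(start = integer(0), end = integer(0),
                        cdna_pos = integer(0), canonical = logical(0))
  bk <- which(diff(diags) != 0)
  for (b in bk) {
    d1 <- diags[b]; d2 <- diags[b + 1]
    ilen <- d2 - d1
    if (ilen < min_intron) next
    e1 <- an[b, 1] + anchor_len - 1L        # last anchored cDNA base, left exon
    s2 <- an[b + 1, 1]                      # first anchored cDNA base, right exon
    ## choose the cDNA split point t in [e1, s2) giving GT...AG boundaries
    t_range <- e1:(s2 - 1L)
    t_hit <- NA_integer_
    for (t in t_range) {
      if (substr(g, t + d1 + 1L, t + d1 + 2L) == "GT" &&
          substr(g, t + d2 - 1L, t + d2) == "AG") { t_hit <- t; break }
    }
    canonical <- !is.na(t_hit)
    t <- if (canonical) t_hit else e1
    introns <- rbind(introns, data.frame(
      start = t + d1 + 1L, end = t + d2, cdna_pos = t, canonical = canonical))
  }
  introns
}

#' Virtual PCR on a template
#'
#' Finds all exact forward-primer matches on the plus strand and
#' reverse-primer matches on the minus strand, and reports every ordered
#' pair (forward 5' end upstream of reverse 5' end) with product length up
#' to `max_product`.
#'
#' @param template template sequence (string or 1-row [seq_set()]).
#' @param fwd,rev primer sequences (>= 15 nt; `rev` given 5'->3' as ordered).
#' @param max_product maximum product length (default 5000 nt).
#' @param max_mismatch primer mismatches tolerated (default 0; matching is
#'   exact, as the assay is qualitative presence/absence).
#' @param name amplicon label.
#' @return an `amplicon_result`: data frame of products and a `present`
#'   flag.
#' @export
virtual_pcr <- function(template, fwd, rev, max_product = 5000,
                        max_mismatch = 0, name = "pair") {
  tpl <- if (is.data.frame(template)) template$seq[1] else template
  tpl <- toupper(tpl)
  if (nchar(fwd) < 15 || nchar(rev) < 15) stop("primers must be >= 15 nt")
  fpos <- primer_sites(tpl, toupper(fwd), max_mismatch)
  rpos <- primer_sites(tpl, revcomp(toupper(rev)), max_mismatch)
  products <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  for (f in fpos) {
    for (r in rpos) {
      r_end <- r + nchar(rev) - 1L
      if (f < r_end && r_end - f + 1L <= max_product && r >= f + nchar(fwd)) {
        products <- rbind(products, data.frame(
          start = f, end = r_end, length = r_end - f + 1L))
      }
    }
  }
  structure(list(pair = name, products = products,
                 present = nrow(products) > 0),
            class = "amplicon_result")
}

primer_sites <- function(template, primer, max_mismatch) {
  if (max_mismatch == 0) return(find_all(primer, template))
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                max.mismatch = max_mismatch, fixed = TRUE)
  BiocGenerics::start(m)
}

#' @export
print.amplicon_result <- function(x, ...) {
  cat(sprintf("<amplicon %s: %s (%d product%s)>\n", x$pair,
              if (x$present) "present" else "absent", nrow(x$products),
              if (nrow(x$products) == 1) "" else "s"))
  invisible(x)
}

#' Merge per-gene trans-splice evidence into a report
#'
#' One row per gene: acceptor call, cis/trans verdict, intron count, and the
#' virtual-PCR presence/absence pattern.
#'
#' @param calls named list of `trans_splice_call` objects (or `NULL` entries
#'   for genes without leader-bearing mRNA).
#' @param intron_counts named integer vector of intron counts per gene.
#' @param amplicons named list (per gene) of lists of `amplicon_result`s.
#' @return data frame, one row per gene.
#' @export
evidence_report <- function(calls, intron_counts = NULL, amplicons = NULL) {
  if (!length(calls))
    return(data.frame(gene = character(0), verdict = character(0),
                      acceptor_rel = integer(0), leader_match_len = integer(0),
                      n_introns = integer(0), pcr_pattern = character(0),
                      notes = character(0)))
  rows <- lapply(names(calls), function(g) {
    cl <- calls[[g]]
    amp <- amplicons[[g]]
    patt <- if (is.null(amp)) NA_character_ else
      paste(vapply(amp, function(a)
        paste0(a$pair, ":", if (a$present) "+" else "-"), character(1)),
        collapse = " ")
    ni <- if (!is.null(intron_counts) && g %in% names(intron_counts))
      unname(intron_counts[[g]]) else NA_integer_
    if (is.null(cl)) {
      data.frame(gene = g, verdict = "not_trans_spliced",
                 acceptor_rel = NA_integer_, leader_match_len = NA_integer_,
                 n_introns = ni, pcr_pattern = patt,
                 notes = "no leader-bearing mRNA", stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, verdict = cl$verdict,
                 acceptor_rel = cl$acceptor_rel,
                 leader_match_len = cl$leader_match_len,
                 n_introns = ni, pcr_pattern = patt,
                 notes = paste(cl$notes, collapse = "; "),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
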