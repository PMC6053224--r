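## Fixed default generator constants. The default leader is a synthetic
## 33-mer with the structural hallmarks of spliced leaders (UUU triplet,
## 3'-terminal G); it is NOT the leader of any real organism. The two intron
## templates are fixed unrelated sequences (global identity < 0.5) so that
## SL gene subtypes are separable by their intronic sequence.
SL_EXON_DEFAULT <- "TACCCGTTTAACGATGGTTAATCGGACTTCTGG"
INTRON_TEMPLATE_1 <- "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCA"
INTRON_TEMPLATE_2 <- "TTTACACTTAGGCGCGCATGAATGACTCTAGCGAAACTTCTTTGGAACACAGTCGGCGGCCTGCCTAAAAGTCTTTGTGCAACGGAATCT"

#' Simulation configuration
#'
#' Defines a synthetic study: a fragmented genome carrying two SL RNA gene
#' families (distinct introns, heterogeneous TSSs), recipient genes with
#' pyrimidine-rich outrons ending in AG, trans-splicing of a leader whose
#' attached length reflects the SL-donor TSS, AATAAA-directed cleavage, and a
#' 5'-anchored read pool with contaminants.
#'
#' @param seed integer seed controlling every random draw.
#' @param sl_exon leader exon, 5'->3', ending in G, containing a TTT triplet,
#'   length 16-52 nt.
#' @param n_sl1_copies,n_sl2_copies SL RNA gene copy numbers of the two
#'   subtypes (defaults 43 and 14).
#' @param intron_template_1,intron_template_2 subtype intron templates
#'   (global identity must be < 0.5).
#' @param copy_mutation_rate per-site substitution probability applied to
#'   each gene copy, in [0, 0.1]. The 20-nt conserved core and the donor GT
#'   are under purifying selection: core mutations are redrawn until at most
#'   2 substitutions remain.
#' @param sl1_tss_weights named numeric vector, probabilities of subtype-I
#'   TSSs at exon positions +1.. (default uniform over +1..+6, so a 33-nt
#'   exon donates leaders of 28-33 nt).
#' @param sl2_tss_position single subtype-II TSS (default +19).
#' @param n_recipient_genes number of trans-splice recipient genes.
#' @param transcripts_per_gene mature/premature transcripts drawn per gene.
#' @param n_cds_introns cis-introns per recipient gene.
#' @param intron_length_range,outron_length_range length ranges (nt).
#' @param pyrimidine_tract_length length of the C/T tract (containing TTT)
#'   placed near the acceptor.
#' @param trans_splice_fraction probability a mature mRNA is trans-spliced.
#' @param premature_fraction fraction of unspliced (outron- and
#'   intron-bearing) transcripts in the pool.
#' @param sl_rna_fraction fraction of the transcript pool that are SL RNA
#'   transcripts themselves (0 emulates a protein-gene-selected read set).
#' @param sl_rna_transcripts_per_locus SL RNA transcript draws per
#'   signal-bearing locus when `sl_rna_fraction > 0`.
#' @param polya_signal_fraction fraction of SL loci carrying a canonical
#'   AATAAA downstream of the conserved region (default 4/12).
#' @param polya_signal_offset nt from the conserved-region end to the first
#'   base of AATAAA (default 70).
#' @param cleavage_offset nt from the last base of AATAAA to the last
#'   templated base (default 14).
#' @param polya_tail_length poly(A) tail length appended at cleavage.
#' @param read_length_mean,read_length_sd read length distribution (nt).
#' @param read_error_rate per-base substitution error probability.
#' @param contaminant_fraction,rrna_fraction fractions of bacterial
#'   contaminant and rRNA reads in the pool.
#' @param n_reads total reads sampled.
#' @param cleavage_jitter logical; jitter the cleavage point by +/-2 nt.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       sl_exon = SL_EXON_DEFAULT,
                       n_sl1_copies = 43L, n_sl2_copies = 14L,
                       intron_template_1 = INTRON_TEMPLATE_1,
                       intron_template_2 = INTRON_TEMPLATE_2,
                       copy_mutation_rate = 0.01,
                       sl1_tss_weights = setNames(rep(1 / 6, 6), as.character(1:6)),
                       sl2_tss_position = 19L,
                       n_recipient_genes = 20L,
                       transcripts_per_gene = 20L,
                       n_cds_introns = 2L,
                       intron_length_range = c(60L, 120L),
                       outron_length_range = c(80L, 200L),
                       pyrimidine_tract_length = 12L,
                       trans_splice_fraction = 1.0,
                       premature_fraction = 0.05,
                       sl_rna_fraction = 0,
                       sl_rna_transcripts_per_locus = 5L,
                       polya_signal_fraction = 4 / 12,
                       polya_signal_offset = 70L,
                       cleavage_offset = 14L,
                       polya_tail_length = 30L,
                       read_length_mean = 136,
                       read_length_sd = 25,
                       read_error_rate = 0.005,
                       contaminant_fraction = 0.05,
                       rrna_fraction = 0.05,
                       n_reads = 2000L,
                       cleavage_jitter = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ex <- cfg$sl_exon
  if (nchar(ex) < 16 || nchar(ex) > 52)
    stop("sl_exon length must be in [16, 52]")
  if (substring(ex, nchar(ex)) != "G") stop("sl_exon must end with G")
  if (!grepl("TTT", ex)) stop("sl_exon must contain a TTT (UUU) triplet")
  if (seq_identity(cfg$intron_template_1, cfg$intron_template_2) >= 0.5)
    stop("intron templates must have global identity < 0.5")
  probs <- c(cfg$copy_mutation_rate, cfg$trans_splice_fraction,
             cfg$premature_fraction, cfg$sl_rna_fraction,
             cfg$polya_signal_fraction, cfg$read_error_rate,
             cfg$contaminant_fraction, cfg$rrna_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$copy_mutation_rate > 0.1) stop("copy_mutation_rate must be <= 0.1")
  if (abs(sum(cfg$sl1_tss_weights) - 1) > 1e-9)
    stop("sl1_tss_weights must sum to 1")
  if (cfg$contaminant_fraction + cfg$rrna_fraction >= 1)
    stop("contaminant + rRNA fractions must be < 1")
  invisible(cfg)
}

#' Scenario presets
#'
#' Three seeded study conditions: `"tiny"` (noiseless, 2 genes, for worked
#' examples and fast tests), `"default"` (20 recipient genes, 43+14 SL loci,
#' 2,000 reads at 0.5% error), and `"stress"` (more genes, 1% error, heavy
#' bacterial contamination).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_scenario <- function(name = c("default", "tiny", "stress"), seed = 7L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    tiny = list(n_sl1_copies = 3L, n_sl2_copies = 2L, n_recipient_genes = 2L,
                transcripts_per_gene = 10L, n_reads = 200L,
                copy_mutation_rate = 0, read_error_rate = 0,
                contaminant_fraction = 0, rrna_fraction = 0,
                premature_fraction = 0),
    default = list(),
    stress = list(n_recipient_genes = 40L, n_reads = 6000L,
                  copy_mutation_rate = 0.02, read_error_rate = 0.01,
                  contaminant_fraction = 0.3, rrna_fraction = 0.1))
  args$seed <- seed
  do.call(sim_config, utils::modifyList(args, list(...)))
}

## conserved 3'-terminal 20-mer of the leader exon (the genome-scan core)
leader_core <- function(sl_exon) substring(sl_exon, nchar(sl_exon) - 19)

## orient a contig onto the strand a feature lives on; truth coordinates are
## expressed on this oriented sequence
#' Extract the strand-oriented sequence of a contig
#'
#' Ground-truth coordinates are expressed along the feature's own strand;
#' this returns the contig sequence in that orientation.
#'
#' @param contigs a [seq_set()] of contigs.
#' @param contig_id contig identifier.
#' @param strand `"+"` or `"-"`.
#' @return a single sequence string.
#' @export
oriented_contig <- function(contigs, contig_id, strand) {
  s <- contigs$seq[match(contig_id, contigs$id)]
  if (is.na(s)) stop("unknown contig: ", contig_id)
  if (strand == "-") revcomp(s) else s
}

## remove cis-intron intervals (strand coordinates) from [from, to]
excise_introns <- function(cassette, from, to, introns) {
  if (!length(introns)) return(substr(cassette, from, to))
  keep <- character(0)
  cur <- from
  for (iv in introns) {
    if (iv[2] < from || iv[1] > to) next
    if (iv[1] > cur) keep <- c(keep, substr(cassette, cur, iv[1] - 1))
    cur <- iv[2] + 1
  }
  if (cur <= to) keep <- c(keep, substr(cassette, cur, to))
  paste(keep, collapse = "")
}

parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(p) {
    as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
  })
}

format_intervals <- function(ivs) {
  if (!length(ivs)) return("")
  paste(vapply(ivs, function(iv) paste0(iv[1], "-", iv[2]), character(1)),
        collapse = ";")
}

## mutate one SL gene copy: exon+intron mutate freely except that the
## conserved core tolerates at most `max_core_mut` substitutions (purifying
## selection on the functional core)
mutate_sl_copy <- function(exon, intron, rate, core_len = 20, max_core_mut = 2) {
  for (t in 1:100) {
    ex_m <- mutate_seq(exon, rate)
    core_start <- nchar(exon) - core_len + 1
    mm <- hamming(substring(ex_m, core_start), substring(exon, core_start))
    if (mm <= max_core_mut) {
      return(list(exon = ex_m, intron = mutate_seq(intron, rate), core_mismatches = mm))
    }
  }
  stop("could not draw a gene copy within the core mutation bound")
}

#' Generate a synthetic genome with SL RNA genes and recipient genes
#'
#' Plants `n_sl1_copies + n_sl2_copies` SL RNA gene loci (mutated leader exon
#' + GT donor + mutated subtype intron, a fraction carrying AATAAA at
#' `polya_signal_offset` past the conserved region) and `n_recipient_genes`
#' recipient genes (outron with pyrimidine tract ending in AG, 5'UTR, CDS
#' with cis-introns, AATAAA-directed cleavage), each on its own contig
#' (emulating a highly fragmented assembly), on a random strand. Background
#' sequence is i.i.d. uniform ACGT, screened so the leader core never occurs
#' by chance.
#'
#' @param cfg a [sim_config()].
#' @return list with `contigs` (a [seq_set()]) and `truth` (an `sl_truth`
#'   list of coordinate tables; also carries the contigs for downstream
#'   stages).
#' @export
build_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  core <- leader_core(cfg$sl_exon)
  exon_len <- nchar(cfg$sl_exon)
  n_loci <- cfg$n_sl1_copies + cfg$n_sl2_copies
  subtype <- rep(c(1L, 2L), c(cfg$n_sl1_copies, cfg$n_sl2_copies))

  ## which copies carry the poly(A) signal: a fixed rounded count per
  ## subtype, always including the first copy (the reference clone analogue)
  signal_flag <- logical(n_loci)
  for (st in 1:2) {
    idx <- which(subtype == st)
    k <- round(cfg$polya_signal_fraction * length(idx))
    if (length(idx) && k > 0) signal_flag[idx[seq_len(k)]] <- TRUE
  }

  loci <- vector("list", n_loci)
  locus_seqs <- character(n_loci)
  for (i in seq_len(n_loci)) {
    tmpl <- if (subtype[i] == 1) cfg$intron_template_1 else cfg$intron_template_2
    cp <- mutate_sl_copy(cfg$sl_exon, tmpl, cfg$copy_mutation_rate)
    flank <- random_dna_clean(40, forbid = core)
    exon_start <- nchar(flank) + 1
    exon_end <- exon_start + exon_len - 1
    donor <- exon_end + 1
    intron_len <- nchar(cp$intron)
    conserved_end <- donor + 1 + intron_len
    if (signal_flag[i]) {
      gap <- random_dna_clean(cfg$polya_signal_offset - 1,
                              forbid = c(core, "AATAAA"),
                              forbid_pyrimidine_run = TRUE)
      post <- random_dna_clean(cfg$cleavage_offset,
                               forbid = c(core, "AATAAA"),
                               forbid_pyrimidine_run = TRUE)
      tail_seq <- paste0(sample(c("C", "G", "T"), 1),
                         random_dna_clean(119, forbid = c(core, "AATAAA"),
                                          forbid_pyrimidine_run = TRUE))
      down <- paste0(gap, "AATAAA", post, tail_seq)
      signal_start <- conserved_end + cfg$polya_signal_offset
      signal_end <- signal_start + 5
      cleavage <- signal_end + cfg$cleavage_offset
    } else {
      down <- random_dna_clean(220, forbid = c(core, "AATAAA"),
                               forbid_pyrimidine_run = TRUE)
      signal_start <- NA_integer_; signal_end <- NA_integer_; cleavage <- NA_integer_
    }
    cassette <- paste0(flank, cp$exon, "GT", cp$intron, down)
    locus_seqs[i] <- cassette
    loci[[i]] <- data.frame(
      locus_id = sprintf("sl%03d", i), subtype = subtype[i],
      exon_start = exon_start, exon_end = exon_end, donor_pos = donor,
      conserved_end = conserved_end, has_polya_signal = signal_flag[i],
      signal_start = signal_start, signal_end = signal_end,
      cleavage_pos = cleavage, core_mismatches = cp$core_mismatches,
      exon_seq = cp$exon, stringsAsFactors = FALSE)
  }

  genes <- vector("list", cfg$n_recipient_genes)
  gene_seqs <- character(cfg$n_recipient_genes)
  for (j in seq_len(cfg$n_recipient_genes)) {
    flank <- random_dna_clean(60, forbid = core)
    outron_len <- sample(cfg$outron_length_range[1]:cfg$outron_length_range[2], 1)
    tract <- pyrimidine_tract(cfg$pyrimidine_tract_length)
    pre_len <- outron_len - cfg$pyrimidine_tract_length - 3
    if (pre_len < 0) stop("outron too short for pyrimidine tract")
    outron_core <- paste0(random_dna_clean(pre_len, forbid = core), tract,
                          random_dna_clean(3, forbid = core))
    utr5 <- random_dna_clean(25, forbid = c(core, "ATG"))
    cds <- random_cds(n_codons = 130, forbid = core)
    introns <- list()
    cds_genomic <- cds
    if (cfg$n_cds_introns > 0) {
      ## intron insertion points, kept >= 60 nt from the CDS ends and from
      ## each other so exact exon anchors always exist
      pts <- sort(sample(seq(60, nchar(cds) - 60, by = 1), cfg$n_cds_introns))
      while (length(pts) > 1 && min(diff(pts)) < 60) {
        pts <- sort(sample(seq(60, nchar(cds) - 60, by = 1), cfg$n_cds_introns))
      }
      offset <- 0L
      segs <- character(0)
      prev <- 1L
      for (p in pts) {
        ilen <- sample(cfg$intron_length_range[1]:cfg$intron_length_range[2], 1)
        iseq <- paste0("GT", random_dna_clean(ilen - 4, forbid = core), "AG")
        segs <- c(segs, substr(cds, prev, p), iseq)
        introns <- c(introns, list(c(p + offset + 1L, p + offset + nchar(iseq))))
        offset <- offset + nchar(iseq)
        prev <- p + 1L
      }
      segs <- c(segs, substr(cds, prev, nchar(cds)))
      cds_genomic <- paste(segs, collapse = "")
    }
    utr3 <- random_dna_clean(30, forbid = c(core, "AATAAA"))
    post <- random_dna_clean(cfg$cleavage_offset, forbid = c(core, "AATAAA"))
    tail_seq <- paste0(sample(c("C", "G", "T"), 1),
                       random_dna_clean(39, forbid = core))
    tss <- nchar(flank) + 1L
    acceptor <- nchar(flank) + outron_len + 2L
    utr5_start <- acceptor + 1L
    atg <- utr5_start + nchar(utr5)
    cds_start <- atg
    cds_end <- cds_start + nchar(cds_genomic) - 1L
    introns <- lapply(introns, function(iv) iv + cds_start - 1L)
    signal_start <- cds_end + nchar(utr3) + 1L
    signal_end <- signal_start + 5L
    cleavage <- signal_end + cfg$cleavage_offset
    if (cfg$cleavage_jitter) cleavage <- cleavage + sample(-2:2, 1)
    cassette <- paste0(flank, outron_core, "AG", utr5, cds_genomic, utr3,
                       "AATAAA", post, tail_seq)
    gene_seqs[j] <- cassette
    genes[[j]] <- data.frame(
      gene_id = sprintf("g%03d", j), tss_pos = tss, outron_start = tss,
      acceptor_pos = acceptor, atg_pos = atg, cds_start = cds_start,
      cds_end = cds_end, n_introns = length(introns),
      introns = format_intervals(introns), signal_start = signal_start,
      signal_end = signal_end, cleavage_pos = cleavage,
      cds_spliced = cds, stringsAsFactors = FALSE)
  }

  loci <- do.call(rbind, loci)
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0))

  ## each feature on its own contig (fragmented-assembly regime), random strand
  all_seqs <- c(locus_seqs, gene_seqs)
  n <- length(all_seqs)
  contig_ids <- sprintf("ctg%04d", sample(n))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  contig_seqs <- ifelse(strands == "-", revcomp(all_seqs), all_seqs)
  loci$contig <- contig_ids[seq_len(nrow(loci))]
  loci$strand <- strands[seq_len(nrow(loci))]
  if (nrow(genes)) {
    genes$contig <- contig_ids[nrow(loci) + seq_len(nrow(genes))]
    genes$strand <- strands[nrow(loci) + seq_len(nrow(genes))]
  }
  contigs <- seq_set(contig_ids, contig_seqs)
  contigs <- contigs[order(contigs$id), , drop = FALSE]
  class(contigs) <- c("seq_set", "data.frame")

  truth <- structure(list(loci = loci, genes = genes, contigs = contigs,
                          sl_exon = cfg$sl_exon),
                     class = "sl_truth")
  list(contigs = contigs, truth = truth)
}

## pyrimidine tract of length n with a guaranteed TTT run
pyrimidine_tract <- function(n) {
  stopifnot(n >= 6)
  repeat {
    s <- paste(sample(c("C", "T"), n, replace = TRUE), collapse = "")
    pos <- sample(n - 2, 1)
    s <- paste0(substr(s, 1, pos - 1), "TTT", substr(s, pos + 3, n))
    if (nchar(s) == n) return(s)
  }
}

## random CDS: ATG + non-stop codons + TAA, screened against forbidden motifs
random_cds <- function(n_codons, forbid = character(0)) {
  codons <- apply(expand.grid(DNA, DNA, DNA), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  for (t in 1:50) {
    s <- paste0("ATG", paste(sample(codons, n_codons - 2, replace = TRUE),
                             collapse = ""), "TAA")
    if (!any(vapply(c(forbid, revcomp(forbid)),
                    function(p) grepl(p, s, fixed = TRUE), logical(1))))
      return(s)
  }
  stop("could not generate CDS free of forbidden motifs")
}

#' Transcribe the simulated genome
#'
#' Emits the mature transcript pool: per recipient gene, mature mRNAs whose
#' outron is replaced by an SL leader (a suffix of the leader exon sampled
#' from the SL TSS distribution) with probability `trans_splice_fraction`,
#' with cis-introns removed and a poly(A) tail appended at the cleavage
#' position; premature (unspliced) forms at `premature_fraction`; and, when
#' `sl_rna_fraction > 0`, polyadenylated SL RNA transcripts from the
#' signal-bearing loci.
#'
#' @param cfg a [sim_config()].
#' @param truth the `sl_truth` from [build_genome()].
#' @return list with `transcripts` (a [seq_set()]) and `tx_truth` (per
#'   transcript: source, type, trans-spliced flag, attached leader length).
#' @export
transcribe <- function(cfg, truth) {
  set.seed(cfg$seed + 1L)
  exon_len <- nchar(cfg$sl_exon)
  tss_pos <- as.integer(names(cfg$sl1_tss_weights))
  recs <- list(); infos <- list()
  k <- 0L
  polyA <- strrep("A", cfg$polya_tail_length)
  for (j in seq_len(nrow(truth$genes))) {
    g <- truth$genes[j, ]
    cass <- oriented_contig(truth$contigs, g$contig, g$strand)
    if (substr(cass, g$acceptor_pos - 1, g$acceptor_pos) != "AG")
      stop("configuration error: gene ", g$gene_id, " lacks acceptor AG")
    introns <- parse_intervals(g$introns)
    for (t in seq_len(cfg$transcripts_per_gene)) {
      k <- k + 1L
      id <- sprintf("tx%05d", k)
      if (runif(1) < cfg$premature_fraction) {
        s <- paste0(substr(cass, g$tss_pos, g$cleavage_pos), polyA)
        infos[[k]] <- data.frame(tx_id = id, source = g$gene_id,
                                 type = "premature", trans_spliced = FALSE,
                                 leader_len = 0L, tss_used = NA_integer_)
      } else if (runif(1) < cfg$trans_splice_fraction) {
        tss <- sample(tss_pos, 1, prob = cfg$sl1_tss_weights)
        leader <- substring(cfg$sl_exon, tss)
        body <- excise_introns(cass, g$acceptor_pos + 1L, g$cleavage_pos, introns)
        s <- paste0(leader, body, polyA)
        infos[[k]] <- data.frame(tx_id = id, source = g$gene_id,
                                 type = "mature", trans_spliced = TRUE,
                                 leader_len = nchar(leader), tss_used = tss)
      } else {
        s <- paste0(excise_introns(cass, g$tss_pos, g$cleavage_pos, introns), polyA)
        infos[[k]] <- data.frame(tx_id = id, source = g$gene_id,
                                 type = "mature", trans_spliced = FALSE,
                                 leader_len = 0L, tss_used = NA_integer_)
      }
      recs[[k]] <- s
    }
  }
  if (cfg$sl_rna_fraction > 0) {
    sig <- truth$loci[truth$loci$has_polya_signal, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      l <- sig[i, ]
      cass <- oriented_contig(truth$contigs, l$contig, l$strand)
      for (t in seq_len(cfg$sl_rna_transcripts_per_locus)) {
        k <- k + 1L
        id <- sprintf("tx%05d", k)
        tss <- if (l$subtype == 1) sample(tss_pos, 1, prob = cfg$sl1_tss_weights)
               else cfg$sl2_tss_position
        s <- paste0(substr(cass, l$exon_start + tss - 1L, l$cleavage_pos), polyA)
        recs[[k]] <- s
        infos[[k]] <- data.frame(tx_id = id, source = l$locus_id,
                                 type = "sl_rna", trans_spliced = FALSE,
                                 leader_len = exon_len - tss + 1L, tss_used = tss)
      }
    }
  }
  tx_truth <- do.call(rbind, infos)
  list(transcripts = seq_set(tx_truth$tx_id, unlist(recs)), tx_truth = tx_truth)
}

#' Sample 5'-anchored reads from the transcript pool
#'
#' Every transcript-derived read starts at transcript position 1 (the
#' cap-anchored convention of a cap-trapper library), with per-base
#' substitution errors and lengths drawn from a truncated normal
#' distribution. Bacterial contaminant and rRNA reads (unanchored) are mixed
#' in at the configured fractions. Read ids encode nothing about the truth.
#'
#' @param transcripts a [seq_set()] of transcripts (from [transcribe()]).
#' @param cfg a [sim_config()].
#' @param tx_truth optional transcript truth table used to annotate reads.
#' @return list with `reads` (a FASTQ-ready [seq_set()]), `read_truth`,
#'   `contaminants` and `rrna` reference [seq_set()]s.
#' @export
sample_reads <- function(transcripts, cfg, tx_truth = NULL) {
  if (nrow(transcripts) == 0) stop("empty transcript pool")
  set.seed(cfg$seed + 2L)
  core <- leader_core(cfg$sl_exon)
  contam <- seq_set(sprintf("bact%02d", 1:3),
                    vapply(1:3, function(i) random_dna_clean(3000, forbid = core),
                           character(1)))
  rrna <- seq_set("rrna18S", random_dna_clean(1500, forbid = core))
  p_t <- 1 - cfg$contaminant_fraction - cfg$rrna_fraction
  cls <- sample(c("transcript", "contaminant", "rrna"), cfg$n_reads,
                replace = TRUE,
                prob = c(p_t, cfg$contaminant_fraction, cfg$rrna_fraction))
  seqs <- character(cfg$n_reads)
  src <- character(cfg$n_reads)
  off <- integer(cfg$n_reads)
  for (i in seq_len(cfg$n_reads)) {
    if (cls[i] == "transcript") {
      j <- sample(nrow(transcripts), 1)
      tpl <- transcripts$seq[j]
      src[i] <- transcripts$id[j]; off[i] <- 1L
      len <- max(30L, min(nchar(tpl), round(rnorm(1, cfg$read_length_mean,
                                                  cfg$read_length_sd))))
      s <- substr(tpl, 1, len)
    } else {
      refs <- if (cls[i] == "contaminant") contam else rrna
      j <- sample(nrow(refs), 1)
      tpl <- refs$seq[j]
      if (runif(1) < 0.5) tpl <- revcomp(tpl)
      src[i] <- refs$id[j]
      start <- sample(nchar(tpl) - 30L, 1)
      off[i] <- start
      len <- max(30L, min(nchar(tpl) - start + 1L,
                          round(rnorm(1, cfg$read_length_mean, cfg$read_length_sd))))
      s <- substr(tpl, start, start + len - 1L)
    }
    seqs[i] <- mutate_seq(s, cfg$read_error_rate)
  }
  ids <- sprintf("r%06d", seq_len(cfg$n_reads))
  read_truth <- data.frame(read_id = ids, class = cls, source = src,
                           offset5 = off, stringsAsFactors = FALSE)
  if (!is.null(tx_truth)) {
    m <- match(read_truth$source, tx_truth$tx_id)
    read_truth$trans_spliced <- !is.na(m) & tx_truth$trans_spliced[m]
    read_truth$leader_len <- ifelse(is.na(m), NA_integer_, tx_truth$leader_len[m])
    read_truth$gene <- ifelse(is.na(m), NA_character_, tx_truth$source[m])
  }
  reads <- seq_set(ids, seqs, qual = strrep("I", nchar(seqs)))
  list(reads = reads, read_truth = read_truth, contaminants = contam, rrna = rrna)
}

#' Generate and write a complete simulated dataset
#'
#' Orchestrates [build_genome()], [transcribe()] and [sample_reads()];
#' writes genome FASTA, reads FASTQ, transcript/contaminant/protein FASTA,
#' TSV truth tables and a JSON manifest of file paths plus a configuration
#' hash (seed-independent).
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return the manifest list, invisibly.
#' @export
emit_dataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("unwritable output path: ", outdir)
  gen <- build_genome(cfg)
  tx <- transcribe(cfg, gen$truth)
  rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)

  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    transcripts = file.path(outdir, "transcripts.fasta"),
    reads = file.path(outdir, "reads.fastq"),
    contaminants = file.path(outdir, "contaminants.fasta"),
    rrna = file.path(outdir, "rrna.fasta"),
    proteins = file.path(outdir, "proteins.fasta"),
    truth_loci = file.path(outdir, "truth_loci.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_transcripts = file.path(outdir, "truth_transcripts.tsv"),
    truth_reads = file.path(outdir, "truth_reads.tsv"),
    manifest = file.path(outdir, "manifest.json"))

  write_sequences(gen$contigs, paths$genome)
  write_sequences(tx$transcripts, paths$transcripts)
  write_sequences(rd$reads, paths$reads, format = "fastq")
  write_sequences(rd$contaminants, paths$contaminants)
  write_sequences(rd$rrna, paths$rrna)
  write_sequences(simulated_proteins(gen$truth), paths$proteins)
  write_annotations(gen$truth$loci, paths$truth_loci)
  write_annotations(gen$truth$genes[, setdiff(names(gen$truth$genes), "cds_spliced")],
                    paths$truth_genes)
  write_annotations(tx$tx_truth, paths$truth_transcripts)
  write_annotations(rd$read_truth, paths$truth_reads)

  manifest <- list(files = lapply(paths[names(paths) != "manifest"], normalizePath),
                   seed = cfg$seed, config_hash = config_hash(cfg))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Translated proteins of the simulated recipient genes
#'
#' Returns the protein sequences encoded by the spliced CDS of every
#' recipient gene; used as the reference set for the protein-proximal read
#' selection stage.
#'
#' @param truth an `sl_truth`.
#' @return a [seq_set()] of protein sequences.
#' @export
simulated_proteins <- function(truth) {
  g <- truth$genes
  prot <- vapply(g$cds_spliced, function(s) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    sub("\\*$", "", aa)
  }, character(1), USE.NAMES = FALSE)
  seq_set(paste0(g$gene_id, "_prot"), prot)
}

## hash of the configuration with the seed excluded, so re-seeding changes
## the data but not the design identity
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$seed <- NULL
  x <- x[order(names(x))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
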