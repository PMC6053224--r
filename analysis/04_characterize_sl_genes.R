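#!/usr/bin/env Rscript

## SL RNA gene characterization. Part A scans the default genome with the
## 22-nt query (20-nt conserved core + GT donor) and clusters the loci into
## subtypes by intron sequence. Part B works on the 12-copy reference family
## ("slfamily" dataset): TSS mapping of capped reads, the conserved block,
## poly(A) signal and cleavage geometry, Sm-site searches, and the
## secondary structure of the conserved region.

library(slseeker)

## ---- A: genome-wide census on the default dataset ------------------------
cfg <- sim_scenario("default", seed = 7L)
core <- substring(cfg$sl_exon, nchar(cfg$sl_exon) - 19)
contigs <- read_sequences("scratch/data/default/genome.fasta")
loci <- scan_loci(contigs, core)
cls <- classify_subtypes(loci)
cat("query:", paste0(core, "GT"), sprintf("(%d bp)\n", nchar(core) + 2))
cat("loci detected:", nrow(cls), "\n")
print(table(cls$subtype_label))

gff <- data.frame(seqid = cls$contig, type = "SL_RNA_gene",
                  start = pmin(cls$fwd_start, cls$fwd_end),
                  end = pmax(cls$fwd_start, cls$fwd_end),
                  strand = cls$strand,
                  attributes = paste0("ID=", cls$locus_id, ";subtype=",
                                      cls$subtype_label))
write_annotations(gff, "results/sl_loci.gff3", dialect = "gff3")
write_annotations(cls[, c("locus_id", "contig", "strand", "donor_pos",
                          "mismatches", "subtype_label")],
                  "results/sl_subtypes.tsv")

## ---- B: reference family characterization --------------------------------
fam_dir <- "scratch/data/slfamily"
cfg2 <- sim_config(seed = 11L, n_sl1_copies = 12L, n_sl2_copies = 3L,
                   copy_mutation_rate = 0, n_recipient_genes = 4L,
                   transcripts_per_gene = 10L, sl_rna_fraction = 0.5,
                   sl_rna_transcripts_per_locus = 20L, n_reads = 1500L,
                   contaminant_fraction = 0, rrna_fraction = 0)
gen2 <- build_genome(cfg2)   # deterministic re-derivation of the truth
tx2 <- transcribe(cfg2, gen2$truth)
reads2 <- read_sequences(file.path(fam_dir, "reads.fastq"))
contigs2 <- read_sequences(file.path(fam_dir, "genome.fasta"))

loci2 <- classify_subtypes(scan_loci(contigs2, core))
sl1 <- loci2[loci2$subtype_label == "SL-I", , drop = FALSE]
key2 <- paste(gen2$truth$loci$contig, gen2$truth$loci$strand,
              gen2$truth$loci$donor_pos)
sl1_truth <- gen2$truth$loci[match(paste(sl1$contig, sl1$strand, sl1$donor_pos),
                                   key2), ]
ref <- sl1[which(sl1_truth$has_polya_signal)[1], ]   # Sanger-clone analogue
ori <- oriented_contig(contigs2, ref$contig, ref$strand)

## TSS mapping of all capped reads onto the reference locus
up <- substr(ori, max(1, ref$exon_start - 50), ref$exon_start - 1)
region <- paste0(up, substr(ori, ref$exon_start, nchar(ori)))
prof <- map_tss(reads2, region, exon_pos = nchar(up) + 1)
write_annotations(prof$profile, "results/tss_profile_sl1.tsv")
modal <- prof$profile$position[prof$profile$count >= 0.5 * max(prof$profile$count)]
m0 <- min(modal)
tss_abs <- nchar(up) + 1 + if (m0 >= 1) m0 - 1 else m0
donor_abs <- nchar(up) + nchar(core) + 1
exon_len <- donor_abs - tss_abs
cat(sprintf("SL-I TSSs (rel. core match): %s -> leader length %d nt\n",
            paste(modal, collapse = ","), exon_len))

## conserved block across the family, anchored at the exon start
fam <- vapply(seq_len(nrow(sl1)), function(i) {
  o <- oriented_contig(contigs2, sl1$contig[i], sl1$strand[i])
  substr(o, sl1$donor_pos[i] - exon_len, nchar(o))
}, character(1))
ab <- align_and_conserved_block(fam)
cat(sprintf("conserved block: +1..+%d\n", ab$conserved_block[2]))

## 3'-end geometry of the reference copy
locus_seq <- substr(ori, ref$donor_pos - exon_len, nchar(ori))
ps <- find_polya_signal(locus_seq, search_start = ab$conserved_block[2])
cat(sprintf("poly(A) signal AATAAA %d nt downstream of the conserved block\n",
            ps$offset[ps$primary][1]))
tref <- gen2$truth$loci[match(paste(ref$contig, ref$strand, ref$donor_pos), key2), ]
ids <- tx2$tx_truth$tx_id[tx2$tx_truth$type == "sl_rna" &
                            tx2$tx_truth$source == tref$locus_id]
cdnas <- tx2$transcripts[tx2$transcripts$id %in% ids, , drop = FALSE]
offs <- infer_cleavage_sites(locus_seq, cdnas)
cat(sprintf("cleavage %s nt downstream of the signal (n = %d cDNAs)\n",
            paste(unique(offs), collapse = "/"), length(offs)))
nsig <- sum(vapply(seq_len(nrow(sl1)), function(i) {
  o <- oriented_contig(contigs2, sl1$contig[i], sl1$strand[i])
  s <- substr(o, sl1$donor_pos[i] - exon_len, nchar(o))
  nrow(find_polya_signal(s, search_start = ab$conserved_block[2])) > 0
}, logical(1)))
cat(sprintf("%d of %d SL-I copies carry the canonical signal\n", nsig, nrow(sl1)))

## terminator-style elements: none expected downstream of the block
down <- substring(locus_seq, ab$conserved_block[2] + 1)
cat("pyrimidine terminator hits:", nrow(find_pyrimidine_terminator(down)), "\n")
cat("3'-box hits:", nrow(find_3prime_box(locus_seq)), "\n")

## Sm sites and secondary structure of the conserved region
conserved <- substr(locus_seq, 1, ab$conserved_block[2])
cat("canonical Sm hits in conserved region:", nrow(find_canonical_sm(conserved)), "\n")
st <- fold(conserved)
sls <- find_stem_loops(st)
cat(sprintf("fold: %d pairs, %d stem-loops\n", nrow(st$pairs), length(sls)))
relaxed <- find_relaxed_sm(conserved, st)
cat("relaxed (pyrimidine-rich, single-stranded) Sm candidates:",
    nrow(relaxed), "\n")
writeLines(c(st$seq, st$dotbracket), "results/sl1_conserved_structure.txt")
write_annotations(ps, "results/sl1_polya_signal.tsv")
write_annotations(data.frame(offset = offs), "results/sl1_cleavage_offsets.tsv")
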