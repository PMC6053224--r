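#!/usr/bin/env Rscript

## De novo discovery of the shared 5' leader from the prepped reads:
## cluster reads by gene body, find 5'-enriched words, chain them into a
## consensus, call per-cluster junctions, and report the attached-leader
## length spectrum. Then collect all core-bearing reads and group them by
## their downstream (gene) sequence, the salvage step that recovers
## leader-bearing genes the protein filter discarded.

library(slseeker)

reads <- read_sequences("scratch/prepped_reads.fastq")
reads <- reads[nchar(reads$seq) >= 50, , drop = FALSE]
clusters <- cluster_by_gene(reads)
cat("clusters:", length(clusters), "\n")

cands <- detect_leader(clusters)
stopifnot(length(cands) > 0)
top <- cands[[1]]
print(top)
spectrum <- leader_length_spectrum(top, clusters)
cat("attached-leader length spectrum:\n")
print(table(spectrum))

## compare with the planted leader
cfg <- sim_scenario("default", seed = 7L)
cat("planted leader:        ", cfg$sl_exon, "\n")
cat("consensus is 3' segment:", endsWith(cfg$sl_exon, top$consensus), "\n")

cand_rows <- do.call(rbind, lapply(cands, function(x) data.frame(
  consensus = x$consensus, length = nchar(x$consensus), support = x$support,
  has_uuu = x$flags$has_uuu, terminal_g = x$flags$terminal_g,
  length_ok = x$flags$length_ok)))
write_annotations(cand_rows, "results/leader_candidates.tsv")
write_annotations(data.frame(cluster = names(top$junctions),
                             junction = unname(top$junctions)),
                  "results/leader_junctions.tsv")

## salvage: all reads carrying the conserved core, grouped by gene tail
core <- substring(top$consensus, nchar(top$consensus) - 19)
all_reads <- read_sequences("scratch/data/default/reads.fastq")
sl_reads <- collect_sl_reads(all_reads, core)
groups <- group_sl_tails(sl_reads, core)
cat(sprintf("core-bearing reads: %d, grouped into %d per-gene groups\n",
            nrow(sl_reads), length(groups)))
group_rows <- do.call(rbind, lapply(groups, function(g) data.frame(
  group = g$cluster_id, n_reads = length(g$member_ids),
  representative = g$representative_id)))
write_annotations(group_rows, "results/sl_read_groups.tsv")
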