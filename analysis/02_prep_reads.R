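#!/usr/bin/env Rscript

## Read-filtering cascade on the default dataset: length filter ->
## contaminant/rRNA k-mer screen -> selection of reads encoding protein
## N-termini. Mirrors a cap-trapper preprocessing pipeline; each stage logs
## a report so the cascade can be reconstructed Methods-style.

library(slseeker)

data_dir <- "scratch/data/default"
stopifnot(dir.exists(data_dir))
reads <- read_sequences(file.path(data_dir, "reads.fastq"))
contam <- read_sequences(file.path(data_dir, "contaminants.fasta"))
rrna <- read_sequences(file.path(data_dir, "rrna.fasta"))
proteins <- read_sequences(file.path(data_dir, "proteins.fasta"))

lf <- length_filter(reads, min_len = 30)
print(lf$report)
sc <- screen_references(lf$reads, rbind(contam, rrna))
print(sc$report)
pp <- select_protein_proximal(sc$kept, proteins)
print(pp$report)

## how good was the screen, against the generator's truth?
truth <- utils::read.delim(file.path(data_dir, "truth_reads.tsv"))
is_cont <- truth$class != "transcript"
cat(sprintf("screen sensitivity %.4f, FPR %.4f\n",
            mean(truth$read_id[is_cont] %in% sc$removed$id),
            mean(truth$read_id[!is_cont] %in% sc$removed$id)))

dir.create("results", showWarnings = FALSE)
reports <- do.call(rbind, lapply(list(lf$report, sc$report, pp$report),
  function(r) data.frame(stage = r$stage, input = r$input_count,
                         kept = r$kept_count, discarded = sum(r$discarded))))
write_annotations(reports, "results/filter_cascade.tsv")
write_sequences(pp$kept, "scratch/prepped_reads.fastq", format = "fastq")
cat("Kept", nrow(pp$kept), "reads ->", "scratch/prepped_reads.fastq\n")
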