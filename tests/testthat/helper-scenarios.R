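## shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## tiny noiseless scenario: 2 genes, 5 SL loci, 200 error-free reads
tiny_run <- function() {
  cached("tiny", {
    cfg <- sim_scenario("tiny", seed = 1)
    gen <- build_genome(cfg)
    tx <- transcribe(cfg, gen$truth)
    rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
    list(cfg = cfg, gen = gen, tx = tx, rd = rd)
  })
}

## the study's default conditions: 20 genes, 43+14 SL loci, 2,000 reads at
## 0.5% error, seed 7 — used by the recovery and acceptance checks
default_run <- function() {
  cached("default", {
    cfg <- sim_scenario("default", seed = 7)
    gen <- build_genome(cfg)
    tx <- transcribe(cfg, gen$truth)
    rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
    prot <- simulated_proteins(gen$truth)
    lf <- length_filter(rd$reads)
    sc <- screen_references(lf$reads, rbind(rd$contaminants, rd$rrna))
    pp <- select_protein_proximal(sc$kept, prot)
    kept <- pp$kept[nchar(pp$kept$seq) >= 50, , drop = FALSE]
    cl <- cluster_by_gene(kept)
    list(cfg = cfg, gen = gen, tx = tx, rd = rd, proteins = prot,
         screened = sc, selected = pp, clusters = cl)
  })
}

## locus-characterization conditions: 12 SL-I / 3 SL-II reference family at
## zero copy mutation, SL RNA reads in the pool for TSS mapping
char_run <- function() {
  cached("char", {
    cfg <- sim_config(seed = 11, n_sl1_copies = 12L, n_sl2_copies = 3L,
                      copy_mutation_rate = 0, n_recipient_genes = 4L,
                      transcripts_per_gene = 10L, sl_rna_fraction = 0.5,
                      sl_rna_transcripts_per_locus = 20L, n_reads = 1500L,
                      contaminant_fraction = 0, rrna_fraction = 0)
    gen <- build_genome(cfg)
    tx <- transcribe(cfg, gen$truth)
    rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
    list(cfg = cfg, gen = gen, tx = tx, rd = rd)
  })
}

scan_core <- function(cfg) substring(cfg$sl_exon, nchar(cfg$sl_exon) - 19)

## match scanned loci to planted truth by (contig, strand, donor)
locus_truth_match <- function(loci, truth_loci) {
  key_s <- paste(loci$contig, loci$strand, loci$donor_pos)
  key_t <- paste(truth_loci$contig, truth_loci$strand, truth_loci$donor_pos)
  list(recall = mean(key_t %in% key_s), precision = mean(key_s %in% key_t),
       truth_row = match(key_s, key_t))
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
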