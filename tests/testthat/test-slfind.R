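test_that("reads from one gene form one cluster; unrelated genes separate", {
  run <- tiny_run()
  rt <- run$rd$read_truth
  tx <- run$tx$tx_truth
  gene_of <- tx$source[match(rt$source, tx$tx_id)]
  reads <- run$rd$reads
  ## single gene, error-free: one cluster
  r1 <- reads[which(gene_of == "g001" & nchar(reads$seq) >= 50), , drop = FALSE]
  cl1 <- cluster_by_gene(r1)
  expect_length(cl1, 1)
  expect_setequal(cl1[[1]]$member_ids, r1$id)
  ## two genes: two clusters, partitioning the reads
  r2 <- reads[nchar(reads$seq) >= 50, , drop = FALSE]
  cl2 <- cluster_by_gene(r2)
  expect_length(cl2, 2)
  expect_setequal(unlist(lapply(cl2, function(x) x$member_ids)), r2$id)
  ## representative is the longest member
  for (cl in cl2) {
    expect_true(cl$representative_id %in% cl$member_ids)
    expect_equal(nchar(cl$representative),
                 max(nchar(r2$seq[r2$id %in% cl$member_ids])))
  }
  ## duplicated input clusters like deduplicated input
  cl3 <- cluster_by_gene(rbind(r2, r2))
  expect_equal(lapply(cl3, function(x) sort(x$member_ids)),
               lapply(cl2, function(x) sort(x$member_ids)))
})

test_that("planted leader is recovered across error rates with exact junctions", {
  for (err in c(0, 0.005, 0.01)) {
    cfg <- sim_scenario("default", seed = 21, read_error_rate = err,
                        n_reads = 1200L, contaminant_fraction = 0,
                        rrna_fraction = 0, premature_fraction = 0)
    gen <- build_genome(cfg)
    tx <- transcribe(cfg, gen$truth)
    rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
    reads <- rd$reads[nchar(rd$reads$seq) >= 50, , drop = FALSE]
    cl <- cluster_by_gene(reads)
    cands <- detect_leader(cl)
    expect_gt(length(cands), 0)
    top <- cands[[1]]
    expect_true(endsWith(cfg$sl_exon, top$consensus))
    expect_gte(nchar(top$consensus), 16)
    ## junction offsets equal the representatives' true attached-leader length
    reps <- setNames(vapply(cl, function(x) x$representative_id, character(1)),
                     vapply(cl, function(x) x$cluster_id, character(1)))
    truth_len <- rd$read_truth$leader_len[match(reps[names(top$junctions)],
                                                rd$read_truth$read_id)]
    expect_gte(mean(top$junctions == truth_len), 0.95)
  }
})

test_that("no leader candidate arises without trans-splicing (specificity, 10 seeds)", {
  for (seed in 1:10) {
    cfg <- sim_scenario("tiny", seed = seed, n_recipient_genes = 8L,
                        transcripts_per_gene = 8L, n_reads = 400L,
                        trans_splice_fraction = 0)
    gen <- build_genome(cfg)
    tx <- transcribe(cfg, gen$truth)
    rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
    cl <- cluster_by_gene(rd$reads[nchar(rd$reads$seq) >= 50, , drop = FALSE])
    expect_length(detect_leader(cl), 0)
  }
})

test_that("leader length spectrum reflects TSS heterogeneity exactly on clean data", {
  run <- default_run()
  cands <- detect_leader(run$clusters)
  expect_gt(length(cands), 0)
  top <- cands[[1]]
  sp <- leader_length_spectrum(top, run$clusters)
  expect_setequal(sort(unique(sp)), 28:33)
  expect_true(all(sp >= 1 & sp <= nchar(run$cfg$sl_exon)))
  ## single-TSS simulation gives a singleton spectrum
  cfg1 <- sim_scenario("tiny", seed = 4, n_recipient_genes = 6L,
                       sl1_tss_weights = stats::setNames(1, "1"))
  gen1 <- build_genome(cfg1)
  tx1 <- transcribe(cfg1, gen1$truth)
  rd1 <- sample_reads(tx1$transcripts, cfg1, tx1$tx_truth)
  cl1 <- cluster_by_gene(rd1$reads[nchar(rd1$reads$seq) >= 50, , drop = FALSE])
  c1 <- detect_leader(cl1)
  expect_gt(length(c1), 0)
  expect_equal(unique(leader_length_spectrum(c1[[1]], cl1)), 33L)
})

test_that("noiseless spectrum equals the truth multiset", {
  cfg <- sim_scenario("tiny", seed = 6, n_recipient_genes = 8L,
                      transcripts_per_gene = 12L, n_reads = 600L)
  gen <- build_genome(cfg)
  tx <- transcribe(cfg, gen$truth)
  rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
  reads <- rd$reads[nchar(rd$reads$seq) >= 50, , drop = FALSE]
  cl <- cluster_by_gene(reads)
  cands <- detect_leader(cl)
  expect_gt(length(cands), 0)
  sp <- leader_length_spectrum(cands[[1]], cl)
  member_ids <- unlist(lapply(cl[vapply(cl, function(x)
    x$cluster_id %in% names(cands[[1]]$junctions), logical(1))],
    function(x) x$member_ids))
  truth_sp <- rd$read_truth$leader_len[match(member_ids, rd$read_truth$read_id)]
  expect_equal(sort(sp), sort(truth_sp))
})

test_that("leader candidate flags mirror the hallmark features", {
  run <- default_run()
  top <- detect_leader(run$clusters)[[1]]
  expect_true(top$flags$has_uuu)
  expect_true(top$flags$terminal_g)
  expect_true(top$flags$length_ok)
})

test_that("core-bearing reads are collected strand-specifically with offsets", {
  core <- "ATGGTTAATCGGACTTCTGG"
  x <- random_dna_str(40)
  reads <- seq_set(c("lead", "mid", "rc", "absent"),
                   c(paste0(core, x), paste0(x, core),
                     revcomp(paste0(core, x)), x))
  out <- collect_sl_reads(reads, core)
  expect_setequal(out$id, c("lead", "mid"))
  expect_equal(out$core_offset[out$id == "lead"], 1L)
  expect_equal(out$core_offset[out$id == "mid"], 41L)
  ## on the default scenario, the collected count equals the truth count of
  ## reads whose attached leader covers the whole core and is long enough
  run <- default_run()
  sl <- collect_sl_reads(run$rd$reads, scan_core(run$cfg))
  rt <- run$rd$read_truth
  read_len <- nchar(run$rd$reads$seq)
  eligible <- !is.na(rt$leader_len) & rt$leader_len >= 20 & rt$trans_spliced &
    read_len >= rt$leader_len
  ## sequencing errors can break the exact 20-mer; collected reads must be a
  ## subset of eligible reads, recovering nearly all of them
  expect_true(all(sl$id %in% rt$read_id[eligible]))
  expect_gte(nrow(sl) / sum(eligible), 0.85)
})

test_that("grouping SL-read tails approximates per-gene contigs deterministically", {
  run <- tiny_run()
  core <- scan_core(run$cfg)
  sl <- collect_sl_reads(run$rd$reads, core)
  sl <- sl[nchar(sl$seq) - (sl$core_offset + 19) >= 30, , drop = FALSE]
  groups <- group_sl_tails(sl, core)
  rt <- run$rd$read_truth
  tx <- run$tx$tx_truth
  gene_of <- tx$source[match(rt$source, tx$tx_id)]
  names(gene_of) <- rt$read_id
  per_group <- lapply(groups, function(g) unique(gene_of[g$member_ids]))
  expect_true(all(lengths(per_group) == 1))
  expect_setequal(unique(unlist(per_group)), c("g001", "g002"))
  ## shuffled input produces the identical grouping after canonical sorting
  sh <- sl[sample(nrow(sl)), , drop = FALSE]
  groups2 <- group_sl_tails(sh, core)
  expect_equal(lapply(groups, function(x) sort(x$member_ids)),
               lapply(groups2, function(x) sort(x$member_ids)))
})
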