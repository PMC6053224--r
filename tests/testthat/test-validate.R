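## one simulated gene with its trans-spliced mRNA, shared across blocks
validation_case <- function(gene_idx = 1) {
  run <- tiny_run()
  g <- run$gen$truth$genes[gene_idx, ]
  cass <- oriented_contig(run$gen$contigs, g$contig, g$strand)
  tt <- run$tx$tx_truth
  mrna_id <- tt$tx_id[tt$source == g$gene_id & tt$trans_spliced][1]
  list(run = run, g = g, cass = cass,
       mrna = run$tx$transcripts$seq[run$tx$transcripts$id == mrna_id],
       leader_len = tt$leader_len[tt$tx_id == mrna_id])
}

test_that("acceptor localization recovers the planted AG junction", {
  vc <- validation_case()
  gm <- gene_model(vc$cass, vc$mrna, vc$g$atg_pos, id = vc$g$gene_id)
  call <- locate_acceptor(gm, vc$run$cfg$sl_exon)
  expect_equal(call$acceptor_pos, vc$g$acceptor_pos)
  expect_equal(call$leader_match_len, vc$leader_len)
  expect_equal(call$verdict, "trans")
  expect_gt(nrow(call$pyrimidine_tract), 0)
  ## ATG-relative coordinate follows the no-zero convention
  expect_equal(call$acceptor_rel, vc$g$acceptor_pos - vc$g$atg_pos)
  expect_lt(call$acceptor_rel, 0)
})

test_that("a mutated acceptor AG yields an indeterminate verdict", {
  vc <- validation_case()
  broken <- vc$cass
  substr(broken, vc$g$acceptor_pos, vc$g$acceptor_pos) <- "C"
  gm <- gene_model(broken, vc$mrna, vc$g$atg_pos)
  call <- locate_acceptor(gm, vc$run$cfg$sl_exon)
  expect_equal(call$verdict, "indeterminate")
  expect_true(any(grepl("no AG", call$notes)))
})

test_that("an mRNA without the leader is rejected as not leader-bearing", {
  vc <- validation_case()
  gm <- gene_model(vc$cass, substring(vc$mrna, vc$leader_len + 1), vc$g$atg_pos)
  expect_error(locate_acceptor(gm, vc$run$cfg$sl_exon), "not leader-bearing")
})

test_that("a leader copy planted upstream flips the verdict to cis_possible", {
  vc <- validation_case()
  adversarial <- paste0(vc$run$cfg$sl_exon, vc$cass)
  gm <- gene_model(adversarial, vc$mrna,
                   vc$g$atg_pos + nchar(vc$run$cfg$sl_exon))
  call <- locate_acceptor(gm, vc$run$cfg$sl_exon)
  expect_equal(call$verdict, "cis_possible")
})

test_that("verdict without capped reads is trans with a degradation note", {
  vc <- validation_case()
  gm <- gene_model(vc$cass, vc$mrna, vc$g$atg_pos)
  ct <- decide_cis_trans(gm, vc$run$cfg$sl_exon, vc$g$acceptor_pos)
  expect_equal(ct$verdict, "trans")
  expect_true(any(grepl("TSS evidence absent", ct$notes)))
})

test_that("intron counting finds both planted GT..AG introns and reconstructs the cDNA", {
  vc <- validation_case()
  ii <- count_introns(vc$cass, vc$mrna)
  truth_iv <- slseeker:::parse_intervals(vc$g$introns)
  expect_equal(nrow(ii), 2)
  expect_true(all(ii$canonical))
  expect_equal(ii$start, vapply(truth_iv, `[`, integer(1), 1))
  expect_equal(ii$end, vapply(truth_iv, `[`, integer(1), 2))
  ## intervals are disjoint and ordered
  expect_true(all(diff(ii$start) > 0))
  expect_true(all(ii$start[-1] > ii$end[-nrow(ii)]))
  ## excising the introns from the genomic gene span reconstructs the cDNA
  spliced <- slseeker:::excise_introns(vc$cass, vc$g$acceptor_pos + 1L,
                                       vc$g$cleavage_pos,
                                       lapply(seq_len(nrow(ii)), function(k)
                                         c(ii$start[k], ii$end[k])))
  body <- substring(vc$mrna, vc$leader_len + 1)
  body <- sub("A{30}$", "", body)
  expect_equal(spliced, body)
  ## an intron-less gene yields zero introns
  expect_equal(nrow(count_introns(paste0("CC", body, "GG"), body)), 0)
})

test_that("virtual PCR reproduces the junction-spanning presence/absence pattern", {
  vc <- validation_case()
  cfg <- vc$run$cfg
  a <- substring(cfg$sl_exon, 14)                       # in the leader
  b <- substr(vc$cass, vc$g$tss_pos + 20, vc$g$tss_pos + 39)  # outron, downstream of TSS
  c_ <- substr(vc$cass, 10, 29)                         # upstream of the TSS
  iv <- slseeker:::parse_intervals(vc$g$introns)
  d <- revcomp(substr(vc$cass, iv[[1]][2] + 10, iv[[1]][2] + 29))  # exon 2
  ## leader-junction pair: cDNA only
  expect_true(virtual_pcr(vc$mrna, a, d)$present)
  expect_false(virtual_pcr(vc$cass, a, d)$present)
  ## upstream-of-TSS pair: genomic only
  expect_true(virtual_pcr(vc$cass, c_, d)$present)
  expect_false(virtual_pcr(vc$mrna, c_, d)$present)
  ## outron pair: genomic and premature, absent from the mature mRNA
  expect_true(virtual_pcr(vc$cass, b, d)$present)
  expect_false(virtual_pcr(vc$mrna, b, d)$present)
  ## non-matching primer: empty result
  none <- virtual_pcr(vc$cass, strrep("ACG", 7), d)
  expect_false(none$present)
  expect_equal(nrow(none$products), 0)
  ## product length: genomic product spans both introns, cDNA-equivalent not
  gp <- virtual_pcr(vc$cass, c_, d)$products
  expect_equal(gp$length, gp$end - gp$start + 1)
})

test_that("virtual PCR agrees with all-pairs enumeration on random templates", {
  set.seed(23)
  for (i in 1:40) {
    tpl <- random_dna_str(2000)
    fs <- sample(1700, 1)
    f <- substr(tpl, fs, fs + 17)
    rs <- sample(setdiff(1:1900, fs), 1)
    r <- revcomp(substr(tpl, rs, rs + 17))
    got <- virtual_pcr(tpl, f, r)$products
    want <- oracle_pcr(tpl, f, r)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_setequal(paste(got$start, got$end),
                      paste(want[, 1], want[, 2]))
    }
  }
})

test_that("the evidence report merges verdicts, introns and PCR per gene", {
  vc1 <- validation_case(1); vc2 <- validation_case(2)
  calls <- list()
  introns <- integer(0)
  for (vc in list(vc1, vc2)) {
    gm <- gene_model(vc$cass, vc$mrna, vc$g$atg_pos, id = vc$g$gene_id)
    calls[[vc$g$gene_id]] <- locate_acceptor(gm, vc$run$cfg$sl_exon)
    introns[vc$g$gene_id] <- nrow(count_introns(vc$cass, vc$mrna))
  }
  amp <- list(g001 = list(virtual_pcr(vc1$mrna, substring(vc1$run$cfg$sl_exon, 14),
                                      revcomp(substr(vc1$mrna, 100, 119)),
                                      name = "a-d")))
  rep <- evidence_report(calls, introns, amp)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$verdict, c("trans", "trans"))
  expect_equal(rep$n_introns, c(2L, 2L))
  expect_match(rep$pcr_pattern[1], "a-d:\\+")
  ## gene without a leader-bearing mRNA
  rep2 <- evidence_report(list(g009 = NULL))
  expect_equal(rep2$verdict, "not_trans_spliced")
  ## empty input: header only
  expect_equal(nrow(evidence_report(list())), 0)
})
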