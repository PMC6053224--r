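CORE20 <- "ATGGTTAATCGGACTTCTGG"

test_that("locus scan finds planted cores with donor GT on either strand", {
  set.seed(31)
  x <- random_dna_str(80); y <- random_dna_str(300)
  fwd <- seq_set("c1", paste0(x, CORE20, "GT", y))
  loci <- scan_loci(fwd, CORE20)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$strand, "+")
  expect_equal(loci$exon_start, 81)
  expect_equal(loci$exon_end, 100)
  expect_equal(loci$donor_pos, 101)
  expect_false(loci$truncated)
  ## the same cassette reverse-complemented is found on the minus strand
  rc <- seq_set("c1", revcomp(paste0(x, CORE20, "GT", y)))
  loci_rc <- scan_loci(rc, CORE20)
  expect_equal(loci_rc$strand, "-")
  expect_equal(loci_rc$exon_seq, CORE20)
  ## core without the donor is not a locus
  no_gt <- seq_set("c2", paste0(x, CORE20, "CC", y))
  expect_equal(nrow(scan_loci(no_gt, CORE20)), 0)
  ## truncation flagged when the contig ends inside the downstream window
  short <- seq_set("c3", paste0(x, CORE20, "GT", substr(y, 1, 50)))
  expect_true(scan_loci(short, CORE20)$truncated)
})

test_that("locus scan recovers all planted loci at 1% copy mutation (recall = precision = 1)", {
  run <- default_run()
  loci <- scan_loci(run$gen$contigs, scan_core(run$cfg))
  m <- locus_truth_match(loci, run$gen$truth$loci)
  expect_equal(m$recall, 1.0)
  expect_equal(m$precision, 1.0)
})

test_that("subtype classification recovers the two planted families exactly (ARI = 1)", {
  run <- default_run()
  loci <- scan_loci(run$gen$contigs, scan_core(run$cfg))
  cls <- classify_subtypes(loci)
  m <- locus_truth_match(loci, run$gen$truth$loci)
  truth_sub <- run$gen$truth$loci$subtype[m$truth_row]
  expect_equal(mclust::adjustedRandIndex(cls$subtype_label, truth_sub), 1.0)
  expect_equal(sort(unique(cls$subtype_label)), c("SL-I", "SL-II"))
  ## SL-I is the larger family by construction
  expect_gt(sum(cls$subtype_label == "SL-I"), sum(cls$subtype_label == "SL-II"))
})

test_that("subtype edge cases: identical introns collapse, lone locus unassigned", {
  set.seed(5)
  intr <- random_dna_str(80)
  mk <- function(n) {
    seq_set(sprintf("c%d", 1:n),
            vapply(1:n, function(i)
              paste0(random_dna_str(30), CORE20, "GT", intr,
                     random_dna_str(250)), character(1)))
  }
  loci3 <- classify_subtypes(scan_loci(mk(3), CORE20))
  expect_equal(unique(loci3$subtype_label), "SL-I")
  loci1 <- classify_subtypes(scan_loci(mk(1), CORE20))
  expect_equal(loci1$subtype_label, "unassigned")
  ## truncated downstream (< 20 nt after the donor) cannot be classified
  tr <- seq_set("t", paste0(random_dna_str(30), CORE20, "GT", substr(intr, 1, 10)))
  both <- rbind(scan_loci(mk(2), CORE20), scan_loci(tr, CORE20))
  cls <- classify_subtypes(both)
  expect_equal(cls$subtype_label[cls$contig == "t"], "unassigned")
  expect_equal(cls$unassigned_reason[cls$contig == "t"], "truncated")
})

test_that("conserved block calling needs 3 members and respects a mutation boundary", {
  expect_error(align_and_conserved_block(c("ACGT", "ACGT")), "insufficient members")
  ## zero-mutation family: the block spans the entire shared region
  set.seed(8)
  shared <- random_dna_str(200)
  fam0 <- vapply(1:6, function(i) paste0(shared, random_dna_str(100)), character(1))
  ab0 <- align_and_conserved_block(fam0)
  expect_lte(abs(ab0$conserved_block[2] - 200), 10)
  ## family mutated only beyond position 130: block ends at 130 +/- window
  mut_tail <- function(s) {
    head <- substr(s, 1, 130)
    tail_chars <- strsplit(substring(s, 131), "")[[1]]
    flip <- runif(length(tail_chars)) < 0.3
    tail_chars[flip] <- vapply(tail_chars[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste0(head, paste(tail_chars, collapse = ""))
  }
  fam <- vapply(1:8, function(i) mut_tail(shared), character(1))
  ab <- align_and_conserved_block(fam)
  expect_lte(abs(ab$conserved_block[2] - 130), 10)
})

test_that("TSS mapping recovers the planted start-site multiset on noiseless reads", {
  cfg <- sim_config(seed = 13, n_sl1_copies = 4L, n_sl2_copies = 2L,
                    copy_mutation_rate = 0, n_recipient_genes = 2L,
                    transcripts_per_gene = 5L, sl_rna_fraction = 0.5,
                    sl_rna_transcripts_per_locus = 30L, n_reads = 800L,
                    read_error_rate = 0, contaminant_fraction = 0,
                    rrna_fraction = 0, polya_signal_fraction = 1)
  gen <- build_genome(cfg)
  tx <- transcribe(cfg, gen$truth)
  rd <- sample_reads(tx$transcripts, cfg, tx$tx_truth)
  l <- gen$truth$loci[1, ]
  ori <- oriented_contig(gen$contigs, l$contig, l$strand)
  region <- substr(ori, l$exon_start - 40, nchar(ori))
  ## reads attributed to this locus by the truth table
  ids <- tx$tx_truth$tx_id[tx$tx_truth$source == l$locus_id]
  sel <- rd$reads[rd$read_truth$source %in% ids, , drop = FALSE]
  prof <- map_tss(sel, region, exon_pos = 41)
  planted <- tx$tx_truth$tss_used[match(rd$read_truth$source[rd$read_truth$read_id %in% sel$id],
                                        tx$tx_truth$tx_id)]
  expect_equal(sort(rep(prof$profile$position, prof$profile$count)),
               sort(planted))
  expect_true(all(prof$modal_positions %in% 1:6))
  expect_equal(prof$n_rejected, 0)
})

test_that("an SL-II-style single TSS at +19 yields one modal position", {
  set.seed(77)
  region <- paste0(random_dna_str(50), CORE20, "GT", random_dna_str(120))
  ## reads all starting at +19 of a 33-nt exon whose last 20 nt are the
  ## core: the exon +1 sits 13 nt before the core match (position 38), so
  ## +19 is absolute position 56
  reads <- seq_set(sprintf("r%02d", 1:20),
                   rep(substr(region, 56, 170), 20))
  prof <- map_tss(reads, region, exon_pos = 38)
  expect_equal(prof$modal_positions, 19)
  ## a read failing coverage is excluded
  bad <- seq_set("bad", paste0(substr(region, 56, 100), random_dna_str(60)))
  prof2 <- map_tss(bad, region, exon_pos = 38)
  expect_equal(prof2$n_accepted, 0)
})

test_that("poly(A) signal scan reports offsets from the reference point", {
  set.seed(12)
  before <- random_dna_str(130)
  gap69 <- gsub("AATAAA", "CCTAAA", random_dna_str(69), fixed = TRUE)
  s <- paste0(before, gap69, "AATAAA", random_dna_str(40))
  hits <- find_polya_signal(s, search_start = 130)
  expect_equal(nrow(hits), sum(unlist(gregexpr("AATAAA", s)) > 130))
  expect_equal(hits$offset[hits$primary][1], 70)
  expect_equal(nrow(find_polya_signal("CCCGGG", 0)), 0)
  two <- paste0(strrep("C", 10), "AATAAA", strrep("G", 10), "AATAAA")
  h2 <- find_polya_signal(two, 0)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$primary, c(TRUE, FALSE))
})

test_that("pyrimidine terminator needs length and a poly(T) core", {
  expect_equal(nrow(find_pyrimidine_terminator("AAATTTCCCAAA")), 1)
  expect_equal(find_pyrimidine_terminator("AAATTTCCCAAA")$match, "TTTCCC")
  expect_equal(nrow(find_pyrimidine_terminator("AACCCCCCAA")), 0)  # no poly(T)
  expect_equal(nrow(find_pyrimidine_terminator("TTTCC")), 0)        # too short
})

test_that("3'-box scan tolerates exactly one mismatch", {
  box <- "GTTTAAAACAAGC"
  s0 <- paste0("ACGTACGTAC", box, "ACGTACGT")
  expect_equal(nrow(find_3prime_box(s0)), 1)
  one_mm <- paste0("ACGTACGTAC", sub("^G", "A", box), "ACGTACGT")
  expect_equal(find_3prime_box(one_mm)$mismatches, 1)
  two_mm <- paste0("ACGTACGTAC", sub("^GT", "AC", box), "ACGTACGT")
  expect_equal(nrow(find_3prime_box(two_mm)), 0)
})

test_that("canonical Sm consensus matches AAU(3-6)G(G/U) and nothing shorter", {
  expect_equal(nrow(find_canonical_sm("AAUUUUGG")), 1)
  expect_equal(find_canonical_sm("AAUUUUGG")$match, "AAUUUUGG")
  expect_equal(nrow(find_canonical_sm("AAUUGG")), 0)  # only two U
  expect_equal(nrow(find_canonical_sm("CCAATTTGTCC")), 1)  # DNA alphabet works
})

test_that("relaxed Sm search requires single-strandedness", {
  sm <- "ACCUCUCCCUUCUCUUCG"
  ## flanks chosen so no larger A..G window stays pyrimidine-rich
  seq1 <- paste0("GGGGGG", sm, "AAAAAA")
  open <- as_secondary_structure(seq1, strrep(".", nchar(seq1)))
  hit <- find_relaxed_sm(seq1, open)
  expect_true(sm %in% hit$match)
  ## the tunicate-style site with one interior purine still passes at 0.8
  sm2 <- "AACUCUCUCCUAUCCCUCUCG"
  seq2 <- paste0("GGGGGG", sm2, "AAAAAA")
  hit2 <- find_relaxed_sm(seq2, as_secondary_structure(seq2, strrep(".", nchar(seq2))))
  expect_true(any(vapply(hit2$match, function(m) grepl(sm2, m, fixed = TRUE) ||
                           grepl(m, sm2, fixed = TRUE), logical(1))))
  ## the same pyrimidine window fully base-paired in a hairpin: no hit
  arm <- "ACTCTTCTCTG"
  hp <- paste0(arm, "AAAA", revcomp(arm))
  st <- as_secondary_structure(hp, paste0(strrep("(", 11), "....",
                                          strrep(")", 11)))
  expect_equal(nrow(find_relaxed_sm(hp, st)), 0)
  expect_gt(nrow(find_relaxed_sm(hp, as_secondary_structure(
    hp, strrep(".", nchar(hp))))), 0)
})

test_that("cleavage-site inference honours the templated-A rule", {
  set.seed(44)
  before <- random_dna_str(100)
  post <- "GCTCGTCCGTCTGC"  # 14 nt, ends at the cleavage point, no A
  locus <- paste0(before, "AATAAA", post, "CGGATC", random_dna_str(30))
  cdna <- paste0(substring(before, 40), "AATAAA", post, strrep("A", 20))
  offs <- infer_cleavage_sites(locus, seq_set("c1", cdna), signal_end = 106)
  expect_equal(offs, 14L)
  ## genomic A at the cleavage point: stripped by the tail trim, restored by
  ## the templated-A rule
  post2 <- "GCTCGTCCGTCTGA"  # templated A at offset 14
  locus2 <- paste0(before, "AATAAA", post2, "CGGATC", random_dna_str(30))
  cdna2 <- paste0(substring(before, 40), "AATAAA", post2, strrep("A", 20))
  offs2 <- infer_cleavage_sites(locus2, seq_set("c1", cdna2), signal_end = 106)
  expect_equal(offs2, 14L)
  ## a cDNA without a poly(A) tail is skipped with a warning
  expect_warning(
    out <- infer_cleavage_sites(locus, seq_set("c2", substr(cdna, 1, 60)),
                                signal_end = 106),
    "skipped")
  expect_length(out, 0)
})

test_that("simulated SL RNA cDNAs reproduce the planted cleavage geometry", {
  run <- char_run()
  ref <- run$gen$truth$loci[1, ]
  expect_true(ref$has_polya_signal)
  ori <- oriented_contig(run$gen$contigs, ref$contig, ref$strand)
  locus_seq <- substr(ori, ref$exon_start, nchar(ori))
  ids <- run$tx$tx_truth$tx_id[run$tx$tx_truth$type == "sl_rna" &
                                 run$tx$tx_truth$source == ref$locus_id]
  cdnas <- run$tx$transcripts[run$tx$transcripts$id %in% ids, , drop = FALSE]
  offs <- infer_cleavage_sites(locus_seq, cdnas)
  expect_true(all(offs == run$cfg$cleavage_offset))
  expect_equal(length(offs), nrow(cdnas))
})
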