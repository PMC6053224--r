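---
title: "Methods: discovering and characterizing spliced-leader trans-splicing from 5'-end reads"
author: "slseeker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing spliced-leader trans-splicing from 5'-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spliced-leader (SL) trans-splicing replaces the 5' end of a pre-mRNA with a
short leader (16–52 nt) donated by an SL RNA. Three observable signatures
identify it from sequence data alone:

1. **A shared 5' word.** Capped 5'-end (cap-trapper style) reads from many
   unrelated genes begin with the same short sequence, with a common 3' end
   (the splice junction) and ragged 5' starts (heterogeneous transcription
   start sites, TSSs, on the SL RNA gene). In the system this package
   models, a 33-nt exon with TSSs at +1..+6 donates leaders of 28–33 nt.
2. **A donor gene family.** The genome carries multiple SL RNA gene copies:
   leader exon, GT splice donor, and an intron-like remainder. Copies fall
   into subtypes by their intronic sequence.
3. **A genomic absence.** At each recipient gene, the genome shows an
   acceptor AG preceded by a pyrimidine-rich outron where the mRNA shows
   the leader, and the leader is not encoded anywhere upstream — ruling
   out long-range cis-splicing.

`slseeker` implements the full chain: a generative simulator with ground
truth, the read-filtering cascade, de novo leader discovery, genome-wide SL
RNA gene annotation (subtypes, TSSs, 3'-end motifs, secondary structure),
and per-gene genomic validation including virtual PCR. The numbered scripts
under `analysis/` run it end to end; every number they print is computed at
run time.

## The synthetic-data generator

The generator (`sim_config()`, `build_genome()`, `transcribe()`,
`sample_reads()`) defines the study conditions; its defaults are the
conditions the analysis is tested under, chosen once:

* **Leader exon**: a synthetic 33-mer ending in G with a UUU (TTT) triplet —
  the structural hallmarks of spliced leaders. It is *not* the leader of
  any real organism, and nothing in this package should be read as a real
  SL sequence.
* **Donor family**: 43 SL-I and 14 SL-II gene copies with unrelated intron
  templates (global identity < 0.5, so subtypes are separable), each copy
  mutated at 1% per site. The 20-nt conserved core and the GT donor are
  under purifying selection: a copy is redrawn until the core carries at
  most 2 substitutions. This mirrors the near-invariant core seen in real
  SL gene alignments and is the condition under which a 2-mismatch genome
  scan attains recall 1.0.
* **TSSs**: SL-I uniform over +1..+6 (leaders 28–33 nt); SL-II fixed at
  +19. The +1..+6 span is what the observed 28–33-nt leader spectrum of a
  33-nt exon implies.
* **3' end geometry**: a canonical AATAAA placed so its first base sits 70
  nt past the end of the conserved region (exon + donor + intron template),
  with the last templated base 14 nt past the signal's last base, followed
  by a fixed 30-nt poly(A) tail. One third of copies (4 of 12 in the
  reference family) carry the signal; the first copy (the Sanger-clone
  analogue) always does. The downstream region is screened free of AATAAA,
  pyrimidine-stretch terminators and chance copies of the core, so the
  planted geometry is the only signal present.
* **Recipient genes**: promoter spacer, outron (80–200 nt) ending in a
  12-nt C/T tract (containing TTT) followed by the acceptor AG, a 25-nt
  5'UTR, a 393-nt CDS with two GT..AG cis-introns (60–120 nt), and an
  AATAAA-directed 3' end with the same 70/14 geometry.
* **Genome shape**: every locus and gene sits on its own contig, on a
  random strand — emulating a highly fragmented shotgun assembly and
  forcing reverse-complement handling everywhere.
* **Reads**: anchored at transcript base 1 (the cap-trapper convention),
  lengths Normal(136, 25) truncated to [30, transcript length], 0.5%
  per-base substitution errors, 5% bacterial contaminant and 5% rRNA reads
  (unanchored, either strand). Read ids encode nothing about the truth.
* **SL RNA transcripts** enter the read pool only when `sl_rna_fraction >
  0`. The default discovery pool excludes them because the discovery
  cascade selects reads encoding protein N-termini, which removes ncRNA
  reads; the characterization dataset (`analysis/01`, "slfamily") switches
  them on to provide TSS and 3' RACE-style evidence.

What the generator does **not** emulate: indel sequencing errors, realistic
base composition or repeats (background is i.i.d. uniform ACGT),
expression-level realism beyond simple per-transcript multiplicities,
paired-end reads, and assembly artifacts other than fragmentation. Passing
tests on this material shows the algorithms recover what was planted under
the stated noise; it does not certify performance on real libraries, where
adapter chemistry, coverage bias and paralogy add failure modes the
simulator does not contain.

## Pipeline stages and the parameters that matter

**Read preparation.** Linker/adapter trimming (`trim_adapters()`: 5' match
within `max_mismatch` at the read start; leftmost 3' suffix match of at
least `min_overlap` = 5 nt), length filter (< 30 nt discarded), contaminant
screen, protein-proximal selection. The screen removes a read when at least
`containment_min` = 0.5 of its k-mers (k = 15, either strand) occur in the
reference k-mer set. The threshold sits deliberately between the expected
k-mer survival of a true contaminant read, (1−e)^k ≈ 0.93 at e = 0.5%
error, and the chance containment of an unrelated read (~4^−15 per k-mer):
at 0.5 the decision is insensitive to sequencing error; at 0.8 two
scattered errors in a 136-nt read already drop containment below threshold
and sensitivity collapses to ~0.85. Protein selection keeps a read if any
of its six reading frames (split at stop codons) shares an exact 8-residue
seed with the first 50 residues of any reference protein, extended ungapped
under BLOSUM62 to a score of 40 — thresholds that give < 1% false positives
on random reads while keeping every read that genuinely covers an
N-terminus. E-value-calibrated alignment screening, as a practitioner would
run with BLAST, is deliberately out of scope; the `table` mode of
`screen_references()` lets an external aligner's hit list stand in.

**Leader discovery.** `cluster_by_gene()` greedily clusters reads on the
k-mer set of their body (after the first 40 nt, so a shared leader cannot
glue genes together); input is sorted by descending length, making the
greedy pass deterministic, and the representative is the longest member.
`detect_leader()` collects 12-mers occurring in the first 40 nt of at least
half the representatives, chains overlapping words into a consensus, and
anchors the consensus 3' end in each representative. Two numerical choices
matter here:

* The junction anchor base must match *exactly*; only interior mismatches
  (≤ 1) are tolerated. Otherwise the tolerance silently absorbs a one-base
  consensus overrun into downstream sequence that happens to be shared by
  chance, shifting every junction by one.
* The per-read "last consensus-matching base" is computed for a few
  trailing trims of the consensus, and the consensus is cut at the modal
  value — so a chance overrun is removed by majority evidence rather than
  per-read heuristics.

Ties between equal-support candidates break by longer consensus, then
lexicographically. The consensus recovers the leader's 3'-terminal segment;
its 5' extent is limited by the enrichment threshold, since a position p of
the exon is present only in reads whose TSS lies at or before p (about
p/6 of them under the default TSS weights).

**Genome scan and subtypes.** The scan query is the conserved 20-nt core
plus an exact GT donor, with up to 2 core mismatches; overlapping
placements keep the lowest-mismatch one (ties: plus strand, then leftmost).
Subtypes are single-linkage clusters at 80% identity over the first 60 nt
of intron (end-gap-free; gaps count as mismatches), named SL-I, SL-II, …
by descending copy number — the naming rule is ours; size order is the
natural reading of a "major" and "minor" family. Singletons and loci with
under 20 nt of intron context stay `unassigned`, which also covers scan
hits that belong to neither family.

**Conserved block and 3' geometry.** Family members are aligned
progressively (guide order by mean pairwise identity; match +1, mismatch
−1, gap −2 per position). Per-column conservation is the modal-residue
fraction among non-gap rows; the block is the maximal run anchored at the
exon start whose 10-column window mean stays ≥ 0.9, then trimmed back to
the last column that meets the threshold with *full-row* support (gaps
counting against it). Without that trim, window smoothing and sparse
aligner-artifact columns bleed the boundary by 1–3 columns, which matters
because the poly(A) signal offset is measured from the block end. Endpoint
conventions, fixed here and used consistently by simulator and scanners:
signal offset = first base of AATAAA minus block end (70 means 69
intervening bases); cleavage offset = last templated base minus last base
of AATAAA. With these conventions the zero-mutation reference family
yields block +1..+132, offset 70 and cleavage 14 exactly.

**TSS mapping.** Reads align locally to the locus region and are accepted
at ≥ 95% identity with aligned-length/read-length > 0.9; the TSS is the
locus coordinate of read base 1; modal positions are those with at least
half the maximal count. Positions are reported relative to the exon start
with no position 0 (+1 is the first exon base, −1 the base before). The
locus "leader length" is the distance from the 5'-most modal TSS to the
base before the donor — sequence plus TSS evidence, not an annotation.

**Folding.** `fold()` maximizes Watson–Crick + GU pairs (Nussinov dynamic
programming, hairpin loops ≥ 3 nt) with a deterministic traceback: prefer
leaving base i unpaired, otherwise pair it with its smallest admissible
partner. Base-pair maximization is a combinatorial stand-in for
thermodynamic folding and will not always reproduce an MFE structure;
`as_secondary_structure()` accepts an externally computed dot-bracket
(e.g. from an MFE folder) anywhere a structure is consumed, and validates
it (balanced brackets, WC/GU pairs, loop length). One property worth
noting: the maximal pair count is invariant under sequence *reversal*, but
not under reverse complementation — GU pairs map to CA, which cannot pair —
so no such symmetry is asserted or relied on.

**Validation.** `locate_acceptor()` strips the mRNA's leader match (longest
suffix of the leader, ≥ 12 nt, ≤ 1 mismatch), places the next 60 nt in the
genome (≤ 3 mismatches; two equally good placements ⇒ indeterminate), and
checks the AG ending at the base before the alignment. Long-range
cis-splicing is rejected operationally: verdict `trans` requires the leader
(≤ 1 mismatch) absent from a finite upstream window (default 5 kb — contigs
are finite; the window is configurable) and, when capped reads are given,
no accepted TSS upstream of the outron TSS cluster; a planted upstream
leader copy yields `cis_possible`, missing evidence `indeterminate`, and
absent capped reads degrade to `trans` with an explicit note.
`count_introns()` chains unique exact 20-mer anchors on a common diagonal,
calls genomic gaps ≥ 40 nt at cDNA-contiguous junctions as introns, and
slides the splice point within the anchor-free ambiguity zone to a GT..AG
solution when one exists (flagged noncanonical otherwise). `virtual_pcr()`
is exact-match and qualitative by default because the assay it mirrors is a
presence/absence pattern, not a quantification.

## Degenerate inputs and tie-breaks

Empty read sets, empty motif scans and empty cluster lists return empty
(zero-row) results, not errors; fewer than `min_clusters` supporting
clusters returns no leader candidate. Fewer than 3 family members is an
error for the progressive alignment (a conserved block over 2 sequences is
not meaningful). Contig ends inside the downstream window set a
`truncated` flag rather than dropping the locus. All randomness flows from
the single config seed (stages derive fixed offsets from it), so identical
configs are byte-identical end to end.

## Problem sizes

The shipped conditions are desk-scale by design: 2,000 reads, 57 SL gene
copies and 20 recipient genes for discovery; a 12-copy reference family
with 1,500 reads for characterization; 10 reseeded negative controls.
These sizes put every recovery statistic (recall, precision, ARI, junction
accuracy) at its ceiling under the stated noise, which is the point of the
exercise: deviations flag implementation defects, not sampling noise.
Scaling the generator up is a matter of configuration, not code.

## Known limitations

* The leader, intron templates and all genomic background are synthetic;
  printed-geometry recoveries (33/70/14/22 bp, 4-of-12) demonstrate
  self-consistency of conventions, not agreement with any deposited
  sequence.
* Greedy k-mer clustering approximates per-gene grouping, not assembly;
  deep paralogy or shared domains between genes would merge clusters.
* The internal fold ignores thermodynamics; stem-loop counts on real SL
  RNAs should be taken from an external MFE structure supplied through
  `as_secondary_structure()`.
* Screening and protein selection use k-mer/seed heuristics in place of
  E-value-calibrated alignment; on real data, substitute aligner output
  via the `table` mode where fidelity matters.
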