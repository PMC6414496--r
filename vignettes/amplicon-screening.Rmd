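---
title: "Flank-anchored amplicon screening: method, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flank-anchored amplicon screening: method, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The problem

Targeted amplicon deep sequencing is the workhorse readout for CRISPR
editing experiments: a PCR amplicon spanning the cut site is sequenced at
depth, one demultiplexed FASTQ file per sample (a pool of cells, a
single-cell-derived clone, a founder animal's tail snip). The analysis
question is always the same — per sample, what fraction of reads carries
which indel, which donor-programmed modification, which base edit — and it
has to be answerable for hundreds of wells at once, locally, without
uploading data.

`ampedit` answers it with exact-substring text search rather than
alignment. That trade is deliberate: exact matching is fast, trivially
auditable, strand- and allele-specific, and robust to the dominant
Illumina error mode (substitutions), at the cost of discarding reads whose
anchors are disrupted. The package's QC ratios exist precisely to make that
discard visible.

## The procedure

Given a reference amplicon `ref_seq` and two anchors `seq_start`,
`seq_end`:

1. **Reference frame.** Each anchor must occur exactly once in `ref_seq`
   (a repeated anchor would make the frame ambiguous and is a fatal
   configuration error). The wild-type inner length $L_{wt}$ is the number
   of bases strictly between the anchors.
2. **Classification.** A read is a *seq_match* iff it contains `seq_start`
   and, strictly after the end of that match, `seq_end`. Its indel size is
   $\Delta = L - L_{wt}$ where $L$ is the observed inner length.
3. **Indel spectrum.** Frequencies divide by the seq_match count;
   `Total_indel` is the percentage with $\Delta \neq 0$.
4. **Test sequences.** Each named query is counted at most once per
   seq_match, within the flank-to-flank anchored region, each test
   independently of the others.
5. **QC.** `SNP_test` = raw reads containing `seq_start` / raw reads
   containing `seq_end`; `raw_wt_test` = raw reads containing the first
   test sequence / seq_matches containing it.

### Assumptions

- Reads are single-strand and match the strand of all user inputs; R1 and
  R2 files are independent samples.
- Indels are inferred purely from length. A balanced
  insertion-plus-deletion between the anchors that preserves length scores
  as $\Delta = 0$; catching such alleles is what wild-type-site test
  sequences are for.
- Substitution errors dominate sequencing noise; indel errors are ~100×
  rarer. The method is quality-agnostic: quality strings are parsed and
  ignored, because exact binning already isolates error reads into
  low-count bins.
- Reads that lose an anchor (large deletions, SNPs in the anchor,
  translocations) silently leave every denominator; interpretation must
  lean on `SNP_test` / `raw_wt_test` when those ratios stray from 1.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `seq_start`, `seq_end` | — | Anchors (bp). 10–20 bp is typical: long enough to be unique, short enough that per-base noise rarely breaks them (at 0.3%/base a 10-mer survives 97% of reads). |
| `top_indels` | 8 | Ranked indel sizes per CSV row. Eight covers the realistic allele count of a clone or mosaic animal; more would bloat a thousand-row summary. |
| `top_reads` | 10 | Exact-read bins per sample in the TXT report — enough to see every true allele plus the leading error bins. |
| `test_match_scope` | `seq_match` | Where test sequences are counted: within the anchored region (default) or anywhere in the raw read of a seq_match. See "Open design points". |

## What the simulator emulates — and what it does not

`scenario()` describes a sample as an allele mixture (full amplicon
sequences with proportions summing to 1), a read count, and a per-base
substitution rate. Reads are allocated to alleles by **largest-remainder**
rounding, not multinomial draws, so realized counts are exact: a zero-noise
simulation must be recovered *exactly* by the engine, which turns
round-trip tests into sharp equalities rather than statistical checks.
Noise remains stochastic under the scenario seed; an optional per-base
1-bp indel-error rate (default 0, reflecting its ~100×-lower real-world
rate) supports robustness tests.

The simulator deliberately omits: PCR chimeras and amplification bias
toward shorter amplicons, quality-score structure, paired-end overlap, and
context-dependent error hotspots. Passing tests therefore demonstrate
algorithmic correctness on idealized reads, not freedom from the
amplification biases that affect any amplicon assay; on real data, relative
frequencies of length-divergent alleles can be biased toward shorter
amplicons regardless of analysis method.

Simulation scenarios in the test suite use 100–10,000 reads per sample and
up to 96 wells per run — sizes chosen so that zero-noise recovery is exact
and noisy-recovery checks have per-mille-scale binomial standard errors,
while a full suite run stays interactive.

## Numerical and degenerate-input choices

- **Undefined frequencies.** A sample with zero seq_matches has undefined
  percentages: reported as `NA` cells, the sample flagged, never fatal.
- **QC 0/0.** Both QC ratios report 0 when numerator and denominator are
  both 0 — the expected signature of a total-knockout clone when the first
  test sequence is the wild-type gRNA site — and `NA` (flagged) when only
  the denominator is 0. A defined `raw_wt_test` below 1 is flagged as
  internally inconsistent (the raw-read superset should contain the
  seq_match subset).
- **Ranking ties.** Indel ranks sort by read count descending; ties break
  by |size| ascending, then deletion before insertion. Smaller indels are
  a priori likelier, and the deterministic order makes reports
  byte-reproducible.
- **TXT ties** break lexicographically by sequence (C locale), again for
  byte-stable output.
- **Rounding.** Percentages print with one decimal; QC ratios with two;
  full precision is kept internally and in all computations.
- **Empty rank cells.** When a sample has fewer distinct indel sizes than
  `top_indels`, the surplus CSV cells are empty, not zero — a zero would
  assert an observation that was never made.

## Open design points and the choices made

The underlying procedure leaves several behaviors unspecified; the package
fixes them as follows.

- **Occurrence choice.** `seq_start` anchors at its *first* occurrence in
  the read, `seq_end` at its first occurrence strictly after it — the
  semantics of a single left-to-right scan, guaranteeing a well-formed
  anchored region. Reads where `seq_end` appears only before `seq_start`
  (inverted amplicons) are non-matches, not errors.
- **Read binning key.** TXT bins key on the anchored region, not the full
  read, so index/adapter length variation outside the anchors cannot split
  biologically identical alleles into separate bins.
- **Test-sequence scope.** Tests are counted within the anchored region by
  default (consistent with counting *seq_matches that contain* the
  modification); `test_match_scope = "raw_read"` switches to whole-read
  matching for users whose test sequences extend beyond the anchors.
- **`SNP_test` direction.** The ratio is directional (upstream/downstream
  rather than min/max): 0.5 vs 2.0 tells the user *which* anchor is losing
  reads.
- **Directory discovery** is non-recursive, case-sensitive on the four
  extensions (`.fastq`, `.fq`, plus `.gz` variants), natural-sorted by
  stripped stem (`a2` before `a10`, matching plate/well naming), and fails
  fast on duplicate stems across extension variants — silently analyzing
  `x.fastq` and `x.fq.gz` as two samples named `x` would corrupt the
  summary.
- **Config files** replace in-script variable editing: the same information
  content (`id`, `ref_seq`, `seq_start`, `seq_end`, `test_list`,
  `fastq_dir`) in a validated YAML file, so misconfiguration fails before
  any FASTQ data is read.

## Known limitations

- Alleles disrupting either anchor are invisible except through QC ratios;
  the remedy is re-running with different anchors (possibly allele-specific
  ones, which the exact-match design supports directly).
- Length-preserving complex alleles score as wild-type length.
- No translocation, large-deletion-beyond-amplicon, or off-target
  analysis; no paired-end merging, trimming, or demultiplexing — the input
  contract starts at demultiplexed single-strand FASTQ.
- `Total_indel` on real data includes polymerase-slippage background; a
  negative control sample in every run is the recommended baseline.
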