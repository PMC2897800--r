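---
title: "Detecting small indels from soft-clipped reads: methods and design"
author: "ClipIndel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small indels from soft-clipped reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClipIndel)
```

## The problem

Short-read mappers assign heavy penalties to gaps inside an alignment, so a
read that spans a small (< 10 nt) insertion or deletion is usually not
aligned with an internal gap. Instead, the mapper anchors the read by its
longest ungapped end and leaves the bases beyond the indel breakpoint
unaligned — in SAM terms, a *soft clip* at one end of the read. A single
clipped read is weak evidence (clips also arise from sequencing and mapping
artifacts), but many reads clipped at the *same* reference position are the
signature of a real event. ClipIndel turns that signature into indel calls
with inferred variant sequences, and pairs it with a simple pileup-based
single-base caller, because the two workflows share their filtering logic
in targeted (exome-capture) experiments.

## The breakpoint statistic

Let p be a reference position adjacent to a clip, on the side the clip
falls (for a right clip, p is the last aligned base and its relevant
neighbour is p+1; for a left clip, p is the first aligned base and the
neighbour is p-1). Define

* N(p): the number of reads whose aligned span covers p,
* N(p±1): the number covering the neighbour,
* N(p&p±1): the number covering both,

and

$$ r = \frac{N(p \,\&\, p\pm1)}{N(p) + N(p\pm1) - N(p\,\&\,p\pm1)} $$

— the Jaccard index of the two read sets. Crucially, *clipped bases do not
count as coverage*: a read clipped at p covers p but not p+1, so a genuine
breakpoint drives r toward 0, while ordinary positions sit near 1. When
both sets are empty we define r = 1 (no reads, no evidence of a
breakpoint). A candidate requires r below 0.35 (strict) and at least 5
clipped reads at the site (inclusive). Both thresholds are exposed in
`filterConfig()`.

Two monotonicity properties follow directly from the definition and are
enforced by property tests: adding a read that covers both positions never
decreases r, and adding a read that covers only p never increases r.

## Tail consensus and classification

The clipped tails at a site are stored *outward* from p (left-clip tails
reversed), so offset i of every tail corresponds to reference offset i
beyond p in the clip direction. `gapConsensus()` takes the per-offset
plurality, with lexicographic tie-breaks for determinism, and truncates at
the first offset where fewer than `minSupport` tails still extend or the
plurality fraction drops below `agreement` (default 0.5).

`minSupport` defaults to 1: the consensus extends as far as any read does,
and the per-offset agreement fractions are returned so downstream code can
judge how deeply each base is supported. This choice is deliberate. At the
design depth of ~40x with 50 nt reads and clips capped at 20 % (10 nt),
the expected number of reads whose tail reaches offset k is roughly
0.8·(11−k): requiring 5 extending reads would truncate every consensus near
4 nt and make an insertion of 5 nt — a size this method is explicitly
meant to recover, sequence included — unclassifiable, because an insertion
of length i can only be recognised once the consensus extends i bases plus
a comparison span. The site-level support filter (≥ 5 clipped reads) is
unaffected.

`classifyIndel()` scans three hypothesis families against the reference
continuation beyond p:

* **deletion of d** (d = 1..9): the consensus should match the reference
  starting d bases further out;
* **insertion of i**: the consensus *after* its first i bases should match
  the reference continuation directly, the skipped prefix being the
  inserted sequence;
* **null**: the consensus matches the continuation as-is (the clip is
  noise).

Each hypothesis is scored by per-base identity over its compared span and
must reach identity ≥ 0.9 over a span of ≥ 2 bases. The winner maximises
identity, then compared span, then prefers the smaller hypothesis length
(null counts as 0) and deletions before insertions. The span-first
tie-break matters: for a real deletion of d bases the deletion hypothesis
matches over the whole consensus while a spurious short-insertion
hypothesis can match a shorter suffix perfectly, and preferring the longer
span picks the right call. A winning null hypothesis, or no qualifying
hypothesis, leaves the site `"unresolved"`; unresolved candidates are kept
in the report for audit but fail the `resolved` filter, so they are never
PASS calls. The 9 nt ceiling reflects the method's scope — it detects small
indels only, not structural variants.

The minimum consensus length to attempt classification is 4, and the
comparison span minimum is 2; both are arguments of `classifyIndel()`. A
span of 2 matched at 25 % per-base chance gives a 1/16 coincidence per
hypothesis, acceptable because classification only runs at sites that
already carry clip evidence, and misclassifications must additionally beat
the true hypothesis's longer span.

Left- and right-direction candidates whose resolved calls imply the same
variant (same type and length, implied genomic start within 9 positions)
are merged with summed support: a deletion's two breakpoints flank the
deleted span, and seeing it from both sides is corroboration, not two
events.

## The filter stack

Filters *annotate* candidates rather than delete them; the TSV report keeps
failed candidates with their failure sets, and PASS output is a projection.
Each filter is evaluated independently, so annotation is idempotent and
order-free:

* `r`: r < 0.35, strict;
* `support`: clipped-read support ≥ 5, inclusive;
* `known`: the affected interval (deleted span, or the two bases flanking
  an insertion breakpoint) intersects a known polymorphic position —
  excluded because mapping artifacts concentrate around known variants;
* `boundary`: p lies at a capture-target start/end (exactly, plus an
  optional `boundaryWindow`); target boundaries are artifact-prone, and
  the exact start/end positions are additionally excluded at candidate
  generation. The window defaults to 0 because no principled width exists
  without platform-specific calibration; widening it is opt-in.
* `resolved`: the classification produced an insertion or deletion call;
* `recurrent`: candidates at one position in more than `maxSamplesIndel`
  samples (default 1) — across independent samples, a recurring signal at
  one position is a systematic artifact of capture, sequencing or mapping.
  The recurrence key is the *position* (the merged candidate's implied
  variant start, which is direction-invariant), not the allele.

## The single-base caller

`pileupCounts()` tallies aligned bases per position — soft-clipped bases
never count, and reads whose CIGAR carries internal indel operators are
skipped because this alignment model (aligned span + end clips) cannot
place their bases per-position; their spans still count for breakpoint
coverage. `callSnvs()` emits a candidate where depth ≥ 3 and the plurality
non-reference base exceeds 75 % of the depth, strictly: 3 of 4 reads is
exactly 75 % and does not call. The sub-100 % consensus requirement
reflects tumour samples with a small normal-cell fraction; no explicit
purity model is attempted. N bases count in the depth denominator (they are
sequenced observations that failed to support the alternate) but are never
an alternate allele; a tie between two alternates yields no call. Known
polymorphic positions are excluded by exact position, and the same
cross-sample recurrence filter is applied with a bound of 2 (keep
candidates seen in fewer than 3 samples).

`annotateConsequence()` classifies coding candidates as synonymous or
non-synonymous by translating the containing codon with and without the
alternate, strand- and frame-aware, against the standard nuclear code
(single codons are never treated as initiators). Codons truncated by an
interval edge are reported `"unknown"` rather than guessed.

## The simulator

`simulateDataset()` generates the conditions the pipeline is designed for:
a uniform-random reference (default 100 kb) with 20 non-overlapping
targets of 250–350 nt, each flanked by at least one read length of
non-target sequence; planted variants placed ≥ 15 bases inside target
boundaries and ≥ 2 read lengths apart (so truth matching is unambiguous);
50 nt single-end reads at a mean depth of 42 (40 in the recovery designs
below) with 1 % uniform base error; 12 samples by default.

Mapping is emulated deterministically rather than by running an aligner:
each read is placed at its true coordinate, and if it crosses a planted
indel breakpoint it is anchored by its longer ungapped side with the
remainder soft-clipped — unless the clip would exceed 20 % of the read
length, in which case the read is emitted unclipped at the anchor
placement, where its far side becomes mismatches and the mapping filters
(NM ≤ 2) remove it, mimicking a mapper rejecting a long end gap. QUAL is
constant; no quality model, GC bias, capture-efficiency variation or
duplicate reads are simulated. Because clips arise *only* at true
breakpoints, the simulator understates the clip noise of real data;
passing recovery tests therefore demonstrates the statistic's and
classifier's correctness under the stated read model, not the
false-positive behaviour of a real capture run — on real data the filter
stack (r, support, known, boundary, recurrence) carries that burden.

Reproducibility is byte-exact: all randomness flows through R's RNG from a
single seed, and every writer uses fixed ordering and formatting.

## Problem sizes and numerical choices

The recovery analyses use a 100 kb reference with 20 targets at depth 40
(error-free, and 1 % error over three replicates), and the recurrence
analysis uses 20 kb with 8 targets across 12 samples — large enough that
every target carries hundreds of reads and each breakpoint ~16 expected
clip events, small enough that the full suite runs in minutes on one CPU.
Recovery is scored with a breakpoint tolerance of 1 position; in practice
resolved calls land exactly.

Degenerate inputs are handled explicitly: sites whose neighbour falls
outside the reference are flagged non-evaluable rather than skipped;
empty alignment sets produce empty (header-only) reports; r at an
uncovered site is 1 by convention; and reference windows truncated by a
sequence end shorten the classification span, falling back to
`"unresolved"` below the minimum.

## Known limitations

* Indels of 10 nt or more, and structural variants generally, are out of
  scope by construction.
* Length-1 indels are recoverable but fragile: their consensus evidence is
  a single-base offset, and the minimum consensus length (4) already
  dominates the signal.
* Homopolymer and tandem-repeat contexts can make insertion, deletion and
  null hypotheses genuinely indistinguishable; ties resolve
  deterministically but not necessarily biologically.
* The mapping-quality notion of "uniquely mapped" is mapper-specific; the
  MAPQ ≥ 1 default is a pragmatic stand-in and is configurable.
* The 75 % / depth-3 single-base thresholds assume roughly 1 % base error
  and mostly-pure samples; other designs should recalibrate.
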