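---
title: "Reference-free breakpoint detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free breakpoint detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(directvc)
```

## The model

`directvc` treats variant calling as a disagreement-detection problem
between two read sets rather than an alignment problem against a
reference. The object of inference is the *breakpoint*: a genomic position
at which the normal and mutated sequences begin to differ. Any variant —
SNV, insertion, deletion, inversion, or a composite of these — manifests
as one breakpoint per strand orientation, flanked on its left by sequence
common to both samples.

The detection device is the sorted suffix list. If both samples cover a
breakpoint, then among all read suffixes of length at least *d* there is a
set sharing their first *d* bases (the 30 bp immediately left of the
breakpoint, the *anchor*) and diverging at column *d* + 1, with the normal
reads on one side of the divergence and the variant-carrying mutated reads
on the other. Lexicographic sorting brings exactly these suffixes together
as a contiguous run, so a single linear scan of the sorted list finds every
candidate breakpoint. Divergence is required at exactly column *d* + 1,
not merely somewhere beyond the anchor: a divergence at column *d* + *j*
re-appears at column *d* + 1 of the cluster anchored *j* − 1 bases
downstream, so the exact-column rule is what prevents every breakpoint
from being registered once per upstream anchor.

Working assumptions inherited by everything downstream:

* both groups sequence the same genome apart from the variants sought, at
  coverage high enough that `cmin` reads per group span each breakpoint;
* reads are ACGT-only after upstream demultiplexing/trimming — base
  qualities are deliberately never used, and reads containing N are
  dropped at load (the 2-bit code cannot represent them, and fabricating a
  base could fabricate a breakpoint);
* errors are rare enough that a cluster's divergence column separates the
  groups rather than the error process (the q window does the policing).

## Memory layout

Reads are 2-bit packed (A/C/G/T → 00/01/10/11) in blocks of 64 reads with
a 2-byte in-block offset per read, i.e. 2 + 8/64 = 2.125 index bytes per
read — the scheme `index_overhead_bytes()` accounts for. Suffixes are
never materialised globally: each of the 4^*k* prefix partitions is
enumerated, sorted, scanned and released before the next one is built, so
peak memory is bounded by one partition (about 1/4^*k* of all suffixes).
In this R implementation the packed store is the canonical container and
sequences are decoded to native strings on demand for the vectorised sort;
the partition-at-a-time contract is what keeps the working set small.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `d` | 30 bp | anchor / minimum suffix length. Shorter anchors collide by chance (4^-d genome-wide); longer ones cost sensitivity near read ends and near neighbouring variants. |
| `k` | 3 | partition prefix length; 64 partitions. Purely a memory/time knob — the call set is invariant in `k` (tested for k = 0..3). |
| `cmin`, `cmax` | 6, 28 | per-group support bounds. `cmin` rejects error-driven and undercovered clusters; `cmax` rejects repeat-collapsed ones. |
| `qmin`, `qmax` | 0.9–1.0 (pure) / 0.35–0.6 (het) | window on the variant fraction q among mutated-group reads covering the divergence column; matches the expected allele dosage of the sample. |
| `pnorm_max` | 0.05 | tolerated fraction of normal-group reads carrying a non-majority base at the divergence column (contamination of the normal sample is expected to be rare). |
| `m` | 10 bp | confirmation length for typing: bases that must match beyond a candidate event. |
| `L` | 15 bp | window length for strand-mirror recognition and the minimum exact overlap for consensus stitching. |
| `max_edit_runs` | 5 | most edit runs a complex breakpoint may contain and still be decomposed. |

The q denominator is the mutated-group reads that *cover* the divergence
column: a member whose suffix is exactly `d` long has no base there and
cannot express either allele, so counting it would deflate q for
breakpoints near read ends.

## Consensus and typing: numerical choices

* **Voting.** A column is decided by a strict majority (> 50%) of the ≥ 2
  reads covering it; ties halt extension (a tie is precisely "cannot be
  determined"). For the mutated consensus only variant-carrying reads
  vote — in a heterozygous sample the reference-like half of the mutated
  group would otherwise vote the consensus back to reference. The q filter
  guarantees this subpopulation is substantial.
* **Left-flank trim.** The two consensus left flanks are trimmed to their
  common suffix (always ≥ the anchor) so the pair satisfies the breakpoint
  definition even when a *neighbouring* variant sits within leftward
  voting range.
* **Typing order and confirmation.** Types are tested in the fixed order
  deletion/insertion (smallest gap first; deletion on a tie, a deterministic
  convention), SNV, inversion (smallest length first), complex. Each test
  must confirm the event with a run of matching bases beyond it: `m` when
  the extents allow, otherwise the window shrinks to the available extent
  with a floor of 5 matched bases for indels and inversions and 3 for
  SNVs. The shrink matters: a cluster detected on only one strand (its
  mirror lost to a neighbouring variant inside the anchor, or to `cmin`)
  has a right extent of roughly `read_length − d − 1` ≈ 19 bp minus
  coverage luck, which can never confirm a 10 bp indel at the full
  `g + m`; with the floor such events are still typed, at the measured
  cost of about 1 in 100 SNV clusters being mis-typed as a small indel by
  a coincidental short-window match.
* **Complex decomposition.** A global unit-cost edit script is computed
  over the full remaining extents (insertions/deletions cost 1.01 so that
  contiguous SNVs decompose as substitutions rather than equal-cost
  insert+delete pairs). The script is accepted if it has ≤ `max_edit_runs`
  edit runs and *ends in a matched run of ≥ m bases* — the terminal-match
  rule is what stops a truncated inversion or long indel from being
  shredded into spurious SNVs. Accepted scripts are decomposed into one
  SNV per substituted base plus one call per indel run, and the components
  are reported as individual variants.
* **Strand merging and re-typing.** Mirror clusters are recognised when a
  15 bp breakpoint-spanning window of one call's normal consensus occurs
  reverse-complemented among the other's, and likewise for the mutated
  consensus. The merged call keeps the typed side when exactly one side
  was typed, otherwise the side with the lexicographically smaller anchor
  (a pure tie-break convention). If both sides are unassigned the two
  pairs are stitched on a unique exact overlap of ≥ 15 bases and re-typed;
  an ambiguous or absent overlap leaves the call unassigned rather than
  guessing.

## Locating and reporting

The built-in locator searches each call's consensus normal sequence as an
exact substring of a reference on both strands: a unique hit yields a
1-based position and re-orients alleles to the forward strand; zero or
several hits are reported as `unmapped`/`ambiguous` instead of being
forced. Exact matching is a deliberate desk-scale surrogate for external
alignment — consensus sequences carrying a consensus error will come back
`unmapped` here, whereas a mapper would place them; `export_consensus_fasta()`
is the escape hatch for that workflow. TSV output carries the full
evidence per call; VCF 4.2 output left-anchors indels on the preceding
reference base per convention.

## What the simulator emulates — and what it does not

`simulate_benchmark()` reproduces the structure of the paper-scale
benchmark at desk scale: an i.i.d. random reference (default GC 0.41),
variants implanted as a chain with inter-variant spacing uniform in
25–50 bp (the spacing regime of the original benchmark's downsampled
variant set — deliberately hostile, since a 30 bp anchor then often
overlaps a neighbour), and paired-end 50 bp reads with fragment length
N(200, 10) drawn uniformly from either strand, substitution errors i.i.d.
at 0.001 per base, constant quality characters. Heterozygous samples draw
each mutated-group fragment from the mutated haplotype with probability
1/2.

Not emulated: position- and cycle-dependent error profiles, indel
sequencing errors, PCR duplicates, coverage waves, repetitive genome
structure, and real variant size distributions. Passing tests on this
generator therefore demonstrate the algorithm's correctness under its own
model — clean anchors, uniform coverage, rare independent errors — not
robustness to real-library artefacts; on real data the support and q
filters carry correspondingly more weight.

## Problem sizes used by the test suite

The bundled checks run the full pipeline on a 100 kb reference with 100
SNVs and 30 indels at 30× coverage per group (about 2 × 120,000 reads,
~5 million suffixes, a minute of CPU), plus a 10 kb fixture for the
k-invariance check, 4 kb single-locus fixtures for exact parameter
recovery, and ≤ 50-read micro-fixtures for the brute-force oracle
comparison. These sizes were chosen so the entire suite exercises every
stage — including the strand-merge and re-typing paths — while staying
comfortably interactive.

## Known limitations

* Sensitivity degrades when variants sit closer together than the anchor
  length: a neighbour inside the 30 bp anchor suppresses that orientation's
  cluster (measured ~4–6% of variants lose both orientations at 25–50 bp
  spacing). This is intrinsic to requiring an exact shared anchor.
* Indel and inversion breakpoints in repetitive context are reported at
  the leftmost divergence column, which may be shifted from the implanted
  coordinate by the length of the repeated prefix; the evaluator's
  position/length tolerances (5 bp) absorb this representational
  ambiguity.
* Translocations are not typed: a consensus pair spanning a translocation
  junction remains `unassigned`.
* The caller is sequential by design; partitions are independent, so the
  loop parallelises trivially, but no threading is built in.
* Support counts cap at `cmax` per group, so very high coverage must be
  downsampled or `cmax` raised accordingly.
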