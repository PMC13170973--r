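---
title: "Evaluating nanopore adaptive-sampling runs with poreSight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating nanopore adaptive-sampling runs with poreSight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreSight)
```

## The problem

Oxford Nanopore adaptive sampling (AS) decides in real time, from the first
few hundred bases of signal, whether to keep sequencing a strand or to eject
it from the pore by reversing the voltage. A common experimental design
splits one flow cell into two channel groups — one half running AS depletion
of an abundant taxon, the other half sequencing normally — so that test and
control share the same library, flow cell and run. Evaluating whether the
depletion *worked* then requires post-run analytics: per-taxon coverage
depth and breadth under each condition, read-length distributions (ejected
strands are short), and the time course of the pore-level decisions.

poreSight implements this evaluation as three stages:

1. **filter** — subset reads by criteria evaluated against the basecaller's
   sequencing-summary table (channel range, length, Q score, start time,
   duration, end reason). The canonical use is the channel split:
   `filterCriteria(min_ch = 1, max_ch = 256)` for the AS half and
   `min_ch = 257, max_ch = 512` for the control half of a 512-channel flow
   cell.
2. **analyze** — validate and QC-filter the FASTQ, map to a multi-sequence
   reference, and emit a per-read *sample manifest* and a per-taxon *sample
   manifest summary*, plus reference-free genome-size/coverage estimates
   from a MinHash sketch of the raw reads.
3. **plot** — compare two analyze outputs: violin and bar charts, a
   rendered comparative summary table, and (for AS runs) time-binned
   decision charts.

## Statistics computed

For each reference sequence ("taxon" — chromosome, plasmid or strain) with
length $L$, using **primary alignments only** (secondary 0x100 and
supplementary 0x800 records excluded, so each mapped read counts once):

* per-position depth $d_i$ = number of alignments whose M/=/X CIGAR
  operations cover position $i$. Deletions (D/N) are spanned but not
  covered; insertions and clips contribute nothing.
* mean coverage depth $= \sum_i d_i / L$, where $\sum_i d_i$ equals the
  summed aligned reference span of the alignments (a conservation law the
  tests assert exactly).
* breadth at threshold $X$ = $100 \cdot |\{i : d_i \ge X\}| / L$ per cent
  (inclusive comparison; $X$ defaults to 1 and renames the output columns,
  e.g. `taxon_%_covered_bases_5X`).
* mean read length = mean of *full* read lengths of the reads whose primary
  alignment is to the taxon — not aligned span — so AS-truncated reads
  depress it visibly.

Reference-free community statistics come from a bottom-$s$ MinHash sketch
of canonical k-mers (lexicographic minimum of each k-mer and its reverse
complement), $k = 27$, $s = 1000$. K-mers are hashed with a fixed
splitmix64 finalizer truncated to 53 bits so every hash value is an exact
double; the hash-space size is $H = 2^{53}$. With $h_s$ the largest of the
$s$ smallest hashes over distinct retained k-mers, the distinct-k-mer
cardinality — which for $k$ well above the repeat scale approximates the
community genome size in bases — is estimated by the k-minimum-values
formula

$$\widehat{N} = (s - 1)\, H / h_s,$$

and an unsaturated sketch simply returns the exact distinct count. The mean
multiplicity of the retained k-mers estimates the per-k-mer sequencing
depth, which tracks base depth up to the read-edge factor $(L_r - k + 1)/L_r$.
For read input the copy threshold defaults to $m = 2$: sequencing-error
k-mers are overwhelmingly singletons and would otherwise dominate the
distinct count. For assembled (FASTA) input use $m = 1$. Exact numeric
parity with external sketching tools is not claimed; the estimator is
property-tested against planted truth instead.

### Decision classes

The sequencing summary does not store the ReadUntil API's decisions, so the
`end_reason` column is mapped to three approximate classes:

| end_reason | class | meaning |
|---|---|---|
| `signal_positive` | `stop_receiving` | sequenced to completion (accept) |
| `data_service_unblock_mux_change` | `unblocked` | actively ejected (reject) |
| `signal_negative`, `unblock_mux_change` | `no_decision` | no explicit action |

Matching is case-insensitive with whitespace trimmed — both spellings occur
in real summary files. Any other token (e.g. `mux_change`) is counted as
`unknown` and excluded from percentage denominators, since the three-class
scheme is explicitly approximate. Decision distributions are computed in
left-closed right-open time bins of the read **start time** (binning on end
time was the alternative; start time was chosen because the decision is
made at the start of the strand, and it is documented here once). Each
summary row is an event: a strand re-evaluated twice contributes twice,
consistent with the manifest's `is_uniq` flag. The cumulative variant
re-aggregates bins 1..i, so its final bin equals the whole-run tally — an
invariant under test.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `minimumCoverage` (X) | 1 | fold | breadth threshold; renames output columns |
| QC `qualified_phred` | 15 | phred | standard read-filter default |
| QC `max_unqualified_fraction` | 0.40 | — | standard default |
| QC `max_n_bases` | 5 | bases | standard default |
| QC `min_length` | 15 | bases | standard default |
| QC `dedup` | TRUE | — | exact-sequence duplicate removal, first kept |
| aligner preset | `long_read_ont` | — | `map-ont` for ONT; `sr` for paired short reads |
| aligner k-mer | 15 | bases | community-standard seed size for noisy long reads |
| sketch k / s / m | 27 / 1000 / 2 | — | see above |
| decision bin width | 15 | minutes | typical reporting granularity for multi-hour runs |

The QC filter reimplements the default behaviour of the common
quality-filtering tool it mirrors (the four rules above plus `-D`-style
deduplication) rather than shelling out to it; adapter trimming is omitted
deliberately because rapid-kit long reads are trimmed upstream. This keeps
the filter's verdicts testable rule by rule. Deduplication is exact string
identity — at desk scale no hashing approximation is observable.

## What the simulator emulates — and what it does not

`generateRun()` produces a complete, internally consistent synthetic run:
reference FASTA, reads FASTQ, sequencing summary and a truth SAM with the
generating coordinates. The default scenario freezes the study conditions
used throughout validation: a four-taxon log-distributed mock community
with the depletion target at 80% relative abundance, 6000 reads with
log-normal lengths (median 2 kb), 2% substitution errors, per-read mean Q
around 19, 512 channels with AS on 1–256, a planted unblock rate of 60% of
AS-channel events, ~400 bp truncation of unblocked reads (a ~1 s decision
window at 400 b/s), a 5% undecided-event rate, 2% of reads given a second
(re-evaluation) summary row, and a 2 h run clock. Where the emulated
experimental design did not pin a value (read count, genome sizes, Q-score
level, run length), values were chosen once at desk scale — large enough
for stable percentages, small enough that the full pipeline runs in tens of
seconds — and are not revisited per test.

It emulates: abundance-weighted read origin, AS truncation confined to
target reads on AS channels, end-reason annotation consistent with the
planted decisions, FASTQ/summary agreement (lengths, mean Q), and
re-evaluated strands. It does **not** emulate nanopore signal-level error
structure (homopolymer errors, quality autocorrelation), indels, barcode
structure, pore exhaustion over time, or inter-genome homology — genomes
are i.i.d. uniform random sequences so mapping truth is unambiguous (a
homology knob would be needed to study misassignment of short reads between
related taxa, which these fixtures deliberately avoid). Passing tests
therefore demonstrate correctness of the analytics on well-posed inputs,
not robustness to every pathology of real flow cells.

Note one consequence of counting per *event*: with 2% re-evaluation rows in
the denominator, a planted 60% per-read unblock rate is recovered as ~58–59%
of events; the ±3-point recovery check accounts for this.

## Numerical and design choices

* **Validation gate.** FASTQ parsing is strict and happens before any
  output file is created: a record without `@` on line 1 or `+` on line 3,
  or with sequence/quality length mismatch, aborts the analyze stage with
  nothing written. Wrapped (multi-line) FASTQ is rejected: basecaller
  output is 4-line, and the validity rules presume it.
* **Read identity** is the first whitespace-delimited header token,
  matching aligner and summary-file conventions; gzip is detected from
  magic bytes, never the extension.
* **Filter semantics.** All bounds are inclusive; channels start at 1, so
  `min_ch = 0` and `min_ch = 1` are equivalent and both accepted. A read
  with several summary rows matches if *any* row matches (subsetting is
  all-or-nothing per read). The length criterion uses the summary's
  `sequence_length_template`, keeping the filter purely summary-driven;
  `duration` is the per-read sequencing time, with the start-time window a
  separate criterion. The decision criterion matches raw tokens, not
  derived classes.
* **Coordinates.** SAM is 1-based closed externally; interval arithmetic
  is delegated to IRanges internally. Depth is accumulated by coverage on
  the M/=/X reference ranges of each CIGAR — equivalent to a difference
  array — and tested for exact equality against a per-base oracle.
* **Counting.** No MAPQ floor is applied, and paired-end mates count
  independently; with primary-only selection this keeps every total
  conserved per read.
* **Rounding is a rendering concern.** Manifest files carry full
  precision. The manifest-summary presentation rounds depth and breadth to
  two significant digits and mean read length to integers; the comparative
  summary table rounds depth to two decimals and the rest to integers.
  Tests pin the rendering rules against worked examples.
* **Reports.** Every chart is written twice: an HTML file with the
  embedded figure (the mean-coverage chart embeds both linear and log axis
  configurations with a client-side toggle) and a plain CSV of exactly the
  plotted values. The CSVs are the stable, diff-able test surface; chart
  bytes are not. Violin inputs are downsampled to at most 100,000 reads
  per condition under a fixed seed; summary statistics at desk scale are
  unaffected.
* **Degenerate inputs.** Empty FASTQ yields empty outputs, not errors; a
  reference sequence with no alignments gets an all-zero row; the unmapped
  row is labelled `*` and always sorts last; sketches of data with no
  k-mer reaching the copy threshold raise an explicit "insufficient
  k-mers" error.

## Problem sizes used in validation

The test suite generates everything programmatically: unit fixtures of a
few reads to a few thousand, a shared 1200-read/30 kb-community run for the
pipeline tests, and for the recovery experiments a 100 kb genome read
error-free at 15× (20 seeds; median genome size within ±10% and depth
within ±20% of truth) plus the full 6000-read depletion scenario end to
end. These sizes are the package's validation choices; all stages scale to
real runs since the per-read work is linear and the sketch is compiled
code.

## Known limitations

* The decision classes are a retrospective proxy; runs that produce the
  optional AS decision log could be classified exactly, which this package
  does not yet ingest.
* Older basecaller versions used different summary column headers; only
  the modern header set is recognised, and a missing required column is a
  named error rather than a guess.
* Short-read (paired) input is supported through the `sr` preset but the
  pore-level analytics do not apply to it.
* BEDGRAPH/WIG position-resolved coverage tracks, barcode demultiplexing
  and workflow-manager wrappers are out of scope.
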