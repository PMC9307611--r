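---
title: "Profiling longitudinal genome instability from variant callsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling longitudinal genome instability from variant callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(svdynamics)
```

## The problem

A heterozygous loss-of-function mutation in a homologous-recombination
gene such as *Brca1* predisposes a genome to instability long before any
tumor appears. Whole-genome sequencing of the same animals across
developmental timepoints — embryonic days through adulthood — turns that
question into a data-analysis problem: given per-sample callsets of
structural variants (SVs), copy-number variants (CNVs) and indels, how do
we (i) clean them to a trustworthy set, (ii) read the double-strand-break
repair pathway off each SV junction, (iii) locate where in the genome
breakage concentrates, and (iv) describe how the burden and the affected
genes change with developmental time, separating events inherited from
the strain background from those arising de novo?

`svdynamics` implements that downstream pipeline as composable functions
over plain data frames, together with a synthetic-cohort generator whose
ground truth is exact, so every stage is testable at desk scale without
sequencing data.

## Coordinate and breakend conventions

All internal coordinates are 0-based half-open; every 1-based external
format (VCF, RepeatMasker `.out`, GTF, CNVnator tables) is shifted
exactly once on read and once on write, and unknown chromosomes are an
error rather than a warning — a silent contig mismatch is the worst
failure mode a coordinate pipeline can have.

A breakend is an oriented breakpoint side. Orientation `"right"` means
the retained sequence lies left of (and including) the position, with the
junction following it; `"left"` means the retained sequence starts at the
position. A deletion is then `(right, left)`, a tandem duplication
`(left, right)`, and an inversion junction has matching orientations.
BND (translocation) records in bracket notation are collapsed to one
record per mate pair, keyed on `MATEID` with a fallback to the
ALT-encoded coordinate.

## Junction microhomology and repair-pathway classes

For each junction we take 50 bp of reference sequence on each side of
each breakend, in derived-chromosome reading order (segments joining from
the reverse strand are reverse-complemented). Microhomology is defined as
the total breakpoint-placement ambiguity: the longest common suffix of
the two sequences immediately upstream of the junction plus the longest
common prefix of the two sequences immediately downstream, capped at the
flank length. This equals the number of positions the breakpoint can
slide while producing an identical derived chromosome, and matches the
`HOMLEN` convention SV callers emit. The test suite checks this equality
against a brute-force oracle that literally rebuilds the derived
chromosome for every shift in ±50 bp, on every junction of a synthetic
cohort.

Lengths map to repair pathways as 1–5 bp NHEJ, 6–25 bp MMEJ, and >25 bp
SSA; 0 bp junctions are blunt and excluded from repair-event totals,
since the classes start at 1 bp. Design choices worth stating:

* Microhomology is recomputed from reference flanks rather than from
  clipped-read `SA` tags; for junctions representable against the
  reference the two are equivalent, and reference flanks make the
  computation testable without alignments.
* Both the upstream and downstream ambiguity components are counted
  (`mode = "total"`); `mode = "upstream"` restricts to the suffix
  component for comparison with callers that report only one side.
* A record carrying non-templated inserted sequence at the junction is
  forced to 0 bp: templated homology cannot span an insertion.
* Base comparison is case-insensitive and `N` never matches, so
  soft-masked references do not alter results.

## Hard filters and callset algebra

The SV quality filter removes records with median MAPQ below 40 (40
itself is kept — the inequality is strict), discordant reads in the
paired normal, or a library-artifact flag; each removed record carries
exactly one reason, assigned in that order, and kept plus removed always
partition the input. The CNV filter keeps calls with q0 < 0.5, length
strictly above 1 kb, e-value < 0.05, and a read depth consistent with the
call (losses < 0.4, gains > 1.6 of diploid).

Panel subtraction, baseline (de novo / accumulated) separation and
replicate merging all reduce to one primitive: two records match when
both breakends agree within a window on the same chromosomes, with type
and orientation equality required by default. The window defaults to
100 bp — no tolerance is stated for the emulated study, and 100 bp is
conservative against typical caller confidence intervals — and is
configurable everywhere. Replicate merging uses union semantics (a
record seen in one replicate of two is kept with count 1), because the
per-timepoint frequencies are computed as combined counts divided by the
replicate number, which is an average over a union, not an intersection.

## Hotspots, burden profiles, presence patterns

Hotspot detection is single-linkage positional chaining: sorted
breakends on one chromosome join a cluster while consecutive gaps stay
at or below `max_gap`, and chains below `min_events` are dropped. The
method in the emulated study is unstated, so chaining was chosen as the
simplest deterministic, permutation-invariant rule. The default
`max_gap` is 4 kb with `min_events = 5`. That value is scaled to the
synthetic genomes this package simulates (hundreds of breakends over
tens of megabases): it was derived before the acceptance suite was
written from the run-length statistics of uniform background breakpoints
— the expected number of ≥5-member chains among ~400 breakends on 20 Mb
is well below 0.05 at 4 kb — and frozen. On a real mammalian genome at
~30× WGS breakpoint density the equivalent choice is of megabase order
and must be set explicitly; the defaults are not meant for full-genome
coordinates.

Burden profiles divide each variant type's combined per-timepoint count
by the replicate number, then normalize by the median of the series
across timepoints, so types with different base rates plot on one axis.
A series whose median is zero has no defined normalization and is
reported as missing with a flag rather than silently dropped.
Presence patterns over the ordered timepoints are classified
exhaustively and mutually exclusively: `persistent` (present at every
timepoint), `recurrent` (present, absent, then present again), and
`transient` (everything else non-empty).

Group comparison is the classic pooled-variance unpaired two-sided
Student's t test (`stats::t.test(var.equal = TRUE)` underneath; Welch
behind a flag). Zero pooled variance is resolved explicitly — equal
means give t = 0, p = 1; unequal means give p = 0 with a degenerate
flag — because silent `NaN`s from a variance of zero are a classic
pipeline failure.

The repeat-enrichment comparison (observed in-repeat breakpoint fraction
vs the genomic repeat fraction) is attached to an exact one-sided
binomial test. The emulated study reports the comparison descriptively;
the test is this package's extension and is labelled as such. Likewise
over-representation analysis is a plain hypergeometric upper tail over
user-supplied gene sets, reporting raw p-values by default (matching a
plain p < 0.05 call) with Benjamini–Hochberg as an option.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the study design as its defaults: six
timepoints (10.5E, 16.5E, 1M, 4M, 8M, 12M) with two replicates each, a
genome at 45% repeat content, breakpoints placed inside repeats with
probability 0.54, two thirds of events inherited (present in a
kidney-like baseline), hotspot clusters on a subset of chromosomes, a
wildtype panel present in every sample, and noise records that fail each
of the three SV quality reasons and each of the four CNV thresholds.
Two deliberate exactness devices replace sampling noise with
construction:

* **Microhomology is implanted by sequence editing.** For an event with
  designed length `m + k`, the `m` bases upstream and `k` bases
  downstream of the junction are copied between the two sides and the
  adjacent base on each side is forced to mismatch. Detection equals
  design for 100% of junctions, so detector tests are equality tests,
  not tolerance tests.
* **Quota sampling.** Inherited/de novo status and in-repeat placement
  are assigned by exact counts (`round(fraction * n)`), not independent
  Bernoulli draws, so the acceptance checks on those fractions are
  exact. Cluster breakends are placed deterministically, evenly spaced
  in the central 70% of each designed span, and background breakends
  avoid the spans plus a chaining margin, so designed clusters are
  recoverable with exact membership.

The dynamics model is a documented free choice (no quantitative
appearance/disappearance model is reported for the emulated system): an
event is persistent with probability 0.3, otherwise present per
timepoint with probabilities rising from 0.35 to 0.75, re-drawn until
non-empty — which produces the increasing burden trend and a mixture of
transient and recurrent event patterns.

Equally important is what the generator does **not** emulate: read-level
evidence (no FASTQ/BAM, no caller artifacts beyond the injected flags),
sequence-defined repeats (repeat intervals are annotation-defined over a
uniform-random genome; there is no sequence homology between repeat
copies), realistic SV length distributions (background breakends are
placed independently, so intra-chromosomal spans are large — one visible
consequence is that gene-level presence matrices saturate toward
`persistent` at desk scale), linked or overlapping rearrangements, and
germline/somatic allele fractions. Passing tests therefore demonstrate
the correctness of the downstream computations under known truth — not
the end-to-end accuracy of any upstream caller on real sequencing data.

## Problem sizes and numerical choices

The default synthetic design uses four 5-Mb chromosomes with 240 SV
events; the test suite mostly runs two 300-kb chromosomes with 30
events, and the whole-pipeline checks use the default design once. These
sizes keep every property checkable by brute force (all-pairs matching,
full derived-chromosome reconstruction) while leaving the per-chromosome
structure — clusters, repeats, genes — non-trivial. Ties in repeat-class
assignment break to the lexicographically smallest label; all RNG flows
from the single configuration seed, and two runs of any generator or
pipeline entry point with one seed are byte-identical (verified file by
file in the tests).

## Known limitations

* Matching is window-based and greedy; no probabilistic or graph-based
  callset integration is attempted (deliberately out of scope).
* Fusion annotation handles single-transcript gene models; multi-isoform
  phase arithmetic is not implemented.
* The microhomology cap equals the flank length (50 bp by default), so
  tracts longer than the flank are reported as the cap — consistent with
  the SSA class being open-ended.
* Indel wildtype subtraction matches by position and allele exactly; a
  windowed mode for indels is not provided.
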