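# svdynamics

Downstream analysis of longitudinal whole-genome variant callsets for
genome-instability studies — the kind of design where the same
individuals (e.g. mice carrying a heterozygous *Brca1* knockout) are
sequenced at successive developmental timepoints and the questions are:
which structural variant (SV), copy-number (CNV) and indel calls survive
quality filtering; which double-strand-break repair pathway produced
each SV junction; where breakage clusters in the genome; how the
mutation burden and the affected genes change over time; and which
events are inherited from the strain background rather than arising de
novo.

The package is aimed at bioinformaticians who already have per-sample
caller output (DELLY-style SV VCFs or BEDPE, CNVnator-style CNV tables,
indel VCFs) and want the post-caller analysis as tested, composable R
functions rather than one-off scripts. A deterministic synthetic-cohort
generator with exact ground truth stands in for sequencing data, so
every stage is verifiable at desk scale.

## What it computes

**Junction microhomology and repair pathway.** For each SV junction,
50-bp reference flanks are taken on each side of both breakends in
derived-chromosome orientation. The microhomology length is the total
breakpoint-placement ambiguity

```
mh = |longest common suffix of the two upstream sequences|
   + |longest common prefix of the two downstream sequences|   (≤ flank)
```

— the number of positions the breakpoint can slide while producing an
identical derived chromosome (the `HOMLEN` convention). Lengths classify
the implied repair pathway: 1–5 bp NHEJ (non-homologous end joining),
6–25 bp MMEJ (microhomology-mediated end joining), >25 bp SSA
(single-strand annealing); 0 bp is blunt.

**Hard filters.** SVs are removed for median MAPQ < 40, discordant
reads in the paired normal, or library-artifact flags; CNVs are kept iff
q0 < 0.5, length > 1 kb, e-value < 0.05, and normalized read depth
< 0.4 (losses) or > 1.6 (gains). Every removed record carries its
reason.

**Callset algebra.** Wildtype-panel subtraction, replicate merging with
union semantics (per-timepoint frequency = combined count / replicates),
and separation of accumulated vs de novo events against a baseline
(kidney-like) callset, all under a configurable breakpoint match window
(default 100 bp, type- and orientation-strict).

**Annotation.** Repeat-class overlap of the 50-bp breakend windows with
an exact binomial enrichment test against the genomic repeat fraction;
fragile-site intersection; gene disruption; fusion candidates with
reading-frame classification (in-frame iff donor and acceptor CDS phases
agree mod 3); hypergeometric over-representation of disrupted genes.

**Dynamics.** Breakpoint hotspot clusters by single-linkage positional
chaining; median-normalized per-timepoint burden profiles per variant
type; presence-pattern classification (persistent / transient /
recurrent); pooled-variance unpaired two-sided Student's t test between
groups.

## Worked example

The `analysis/` directory is a numbered workflow over the package. With
the default design (four 5-Mb chromosomes, 45% repeats, 240 SV events in
six timepoints × two replicates, two thirds inherited, four designed
hotspots):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_filter_callsets.R
Rscript analysis/03_repair_pathways.R
Rscript analysis/04_breakpoint_annotation.R
Rscript analysis/05_hotspots_dynamics.R
Rscript analysis/06_denovo_and_groups.R
```

prints, among other output:

```
rejected 207 SV records; reasons: discordant reads in paired normal 69, library artifact 64, median MAPQ < 40 74
repair events (non-blunt): 230 | NHEJ 196, MMEJ 33, SSA 1
NHEJ share of repair events: 85.2%
breakends in repeats: 259/480 (54.0%) vs 45% background, p = 5.07e-05
hotspot clusters: 4
overall accumulated fraction: 0.645
group burden comparison: t = 0.659, df = 22, p = 0.517
```

Read: the injected quality-failing records are all caught with their
reasons; NHEJ dominates the repair-event spectrum as expected for an
HR-deficient design; breakpoints overlap repeats at 54% against a 45%
genomic background (exact binomial p ≈ 5×10⁻⁵); all four designed
hotspot clusters are recovered; about two thirds of events match the
baseline callset (the inherited fraction built into the design); and
two cohorts simulated under the same design do not differ in burden
(p = 0.52), as a null comparison should.

Tables land under `results/` (merged callsets, microhomology table,
annotation tables, clusters, burden profile, de novo split). The methods
vignette (`vignettes/genome-instability-profiling.Rmd`) documents the
model, conventions, parameter defaults and the generator's exactness
devices.

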