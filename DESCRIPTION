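Package: svdynamics
Title: Longitudinal Genome-Instability Profiling from Structural Variant Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of whole-genome variant callsets from
    longitudinal cohorts: hard quality filtering of structural variant (SV)
    and copy-number (CNV) calls, wildtype-panel subtraction, replicate
    merging, separation of de novo from inherited events against a baseline
    tissue callset, breakpoint-junction microhomology computation with
    repair-pathway classification (blunt/NHEJ/MMEJ/SSA), repeat-element and
    fragile-site breakpoint annotation with enrichment testing, gene
    disruption and fusion reading-frame annotation, hotspot cluster
    detection, median-normalized per-timepoint burden profiles,
    presence-pattern classification, and group comparison. Includes a
    deterministic synthetic-cohort generator with exact ground truth so
    every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    fgsea,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
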