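#!/usr/bin/env Rscript
# Breakpoint-junction microhomology and repair-pathway classification.
# All merged SVs are combined across timepoints, duplicate junctions
# removed, 50-bp flanks taken from the reference on each side of the
# junction, and the placement-ambiguity microhomology length computed and
# classed as blunt (0), NHEJ (1-5 bp), MMEJ (6-25 bp) or SSA (>25 bp).

suppressMessages(library(svdynamics))

cfg <- sim_config(seed = 1L)
genome <- read_fasta("results/cohort/genome.fa")
merged <- readRDS("results/filtered_callsets.rds")$merged

all_sv <- do.call(rbind, unname(merged))
key <- paste(all_sv$chrom1, all_sv$pos1, all_sv$ori1,
             all_sv$chrom2, all_sv$pos2, all_sv$ori2)
combined <- all_sv[!duplicated(key), ]

hom <- junction_homology(genome, combined)
s <- summarize_pathways(hom)

utils::write.table(
  hom[, c("sv_id", "chrom1", "pos1", "chrom2", "pos2", "mh_length",
          "mh_sequence", "pathway")],
  "results/microhomology.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("unique junctions:", s$total, "\n")
cat(sprintf("repair events (non-blunt): %d | NHEJ %d, MMEJ %d, SSA %d\n",
            s$non_blunt, s$counts["NHEJ"], s$counts["MMEJ"], s$counts["SSA"]))
cat(sprintf("NHEJ share of repair events: %.1f%%\n",
            100 * s$counts["NHEJ"] / s$non_blunt))
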