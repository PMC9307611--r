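#!/usr/bin/env Rscript
# Annotate the combined breakpoints: repeat-class overlap of the 50-bp
# breakend windows (with an exact binomial enrichment test against the
# genomic repeat fraction), fragile-site intersections, disrupted genes,
# fusion candidates with reading frame, and hypergeometric
# over-representation of disrupted genes in the supplied gene sets.

suppressMessages(library(svdynamics))

cfg <- sim_config(seed = 1L)
repeats <- read_repeatmasker_out("results/cohort/repeats.out")
fragile <- read_bed("results/cohort/fragile.bed")
genes <- read_gene_models("results/cohort/genes.gtf")
sets <- read_gmt("results/cohort/gene_sets.gmt")
merged <- readRDS("results/filtered_callsets.rds")$merged

all_sv <- do.call(rbind, unname(merged))
key <- paste(all_sv$chrom1, all_sv$pos1, all_sv$ori1,
             all_sv$chrom2, all_sv$pos2, all_sv$ori2)
combined <- all_sv[!duplicated(key), ]

ra <- annotate_repeats(combined, repeats)
k <- sum(!is.na(ra$breakends$repeat_class))
p_enrich <- repeat_enrichment_test(k, nrow(ra$breakends), cfg$repeat_fraction)
cat(sprintf("breakends in repeats: %d/%d (%.1f%%) vs %.0f%% background, p = %.2e\n",
            k, nrow(ra$breakends), 100 * ra$fraction,
            100 * cfg$repeat_fraction, p_enrich))
cat("top repeat classes:",
    paste(names(sort(table(ra$breakends$repeat_class), decreasing = TRUE)),
          collapse = ", "), "\n")

fh <- intersect_fragile_sites(combined, fragile)
cat("fragile-site hits:", nrow(fh), "at",
    paste(unique(fh$fragile_gene), collapse = ", "), "\n")

ga <- annotate_genes(combined, genes)
cat("disrupted genes:", length(unique(ga$disrupted$gene_id)),
    "| fusion candidates:", nrow(ga$fusions), "\n")

ora <- ora_test(unique(ga$disrupted$gene_id), sets,
                unique(genes$models$gene_id))
cat("gene sets below alpha = 0.05:", sum(ora$significant), "of",
    nrow(ora), "\n")

utils::write.table(ra$breakends, "results/breakend_repeat.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(fh, "results/fragile_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ga$disrupted, "results/gene_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ga$fusions, "results/fusions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ora, "results/ora.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
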