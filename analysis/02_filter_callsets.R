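#!/usr/bin/env Rscript
# Post-caller hard filtering and cohort assembly: remove SVs with median
# MAPQ < 40, discordant paired-normal support, or library-artifact flags;
# subtract the wildtype panel; apply the CNV hard filters (q0 < 0.5,
# length > 1 kb, e < 0.05, loss rd < 0.4 / gain rd > 1.6); merge the two
# replicates per timepoint with union semantics. Writes the merged
# per-timepoint callsets and a reject ledger under results/.

suppressMessages(library(svdynamics))

cfg <- sim_config(seed = 1L)
contigs <- cfg$genome_sizes
dir.create("results", showWarnings = FALSE)

panel <- read_sv_vcf("results/cohort/panel_sv.vcf", contigs = contigs)
policy <- match_policy()

rejects <- list()
merged_all <- list()
for (t in cfg$timepoints) {
  reps <- lapply(1:2, function(r) {
    sv <- read_sv_vcf(sprintf("results/cohort/sv_%s_rep%d.vcf", t, r),
                      contigs = contigs,
                      sample_id = sprintf("%s_rep%d", t, r), timepoint = t)
    qf <- quality_filter_svs(sv)
    rejects[[length(rejects) + 1L]] <<- qf$removed
    subtract_panel(qf$kept, panel, policy)$kept
  })
  merged_all[[t]] <- merge_replicates(reps, policy)$merged
  cat(sprintf("%6s: %3d merged SVs (replicate counts %s)\n", t,
              nrow(merged_all[[t]]),
              paste(table(merged_all[[t]]$replicate_count), collapse = "/")))
}

cnv_kept <- list()
for (t in cfg$timepoints) for (r in 1:2) {
  cnv <- read_cnv_table(sprintf("results/cohort/cnv_%s_rep%d.tsv", t, r),
                        sample_id = sprintf("%s_rep%d", t, r), timepoint = t)
  cnv_kept[[paste(t, r)]] <- filter_cnvs(cnv)$kept
}

saveRDS(list(merged = merged_all, cnv_kept = cnv_kept),
        "results/filtered_callsets.rds")
rej <- do.call(rbind, rejects)
utils::write.table(rej, "results/sv_rejects.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("rejected", nrow(rej), "SV records; reasons:",
    paste(names(table(rej$reason)), table(rej$reason), collapse = ", "), "\n")
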