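# End-to-end orchestration: simulate -> read back through the format layer
# -> quality filter -> panel subtraction -> replicate merge -> de novo
# split -> microhomology -> annotation -> dynamics -> report bundle.

#' Pipeline configuration
#'
#' One auditable home for every threshold, each defaulting to the value
#' the analysis is built around: SV removal below median MAPQ 40; CNV
#' q0 < 0.5, length > 1 kb, e-value < 0.05, loss/gain read depth 0.4/1.6;
#' 50-bp junction flanks; microhomology classes 1-5/6-25/>25 bp; breakpoint
#' match window 100 bp; desk-scale hotspot chaining (4 kb gap, 5 events).
#'
#' @param sim [sim_config()] for the synthetic cohort.
#' @param min_median_mapq SV quality threshold.
#' @param policy [match_policy()] for subtraction/merging/de novo matching.
#' @param flank junction flank bp.
#' @param bounds [pathway_bounds()].
#' @param max_gap,min_events hotspot chaining parameters.
#' @param alpha ORA significance cutoff.
#' @param compare_null also simulate a second, identically parameterized
#'   cohort (derived seed) and run the group comparison on per-sample
#'   burdens.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), min_median_mapq = 40L,
                            policy = match_policy(), flank = 50L,
                            bounds = pathway_bounds(), max_gap = 4000L,
                            min_events = 5L, alpha = 0.05,
                            compare_null = TRUE) {
  structure(list(sim = sim, min_median_mapq = as.integer(min_median_mapq),
                 policy = policy, flank = as.integer(flank), bounds = bounds,
                 max_gap = as.integer(max_gap),
                 min_events = as.integer(min_events), alpha = alpha,
                 compare_null = compare_null),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, writes its files, reads the SV callsets back
#' through the VCF layer, then runs quality filtering, wildtype-panel
#' subtraction, replicate merging, de novo/accumulated separation,
#' junction microhomology with pathway summary, breakpoint annotation
#' (repeats, fragile sites, genes, fusions, over-representation), and
#' dynamics (hotspots, burden profile, presence patterns, optional null
#' group comparison). Every stage's record counts are logged to a
#' machine-readable manifest; reruns with one seed are byte-identical.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory for the report bundle; `NULL` keeps
#'   everything in memory.
#' @return list with the per-stage tables, `summary` quantities and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  sim <- config$sim
  tps <- sim$timepoints
  n_rep <- sim$replicates_per_timepoint
  input_dir <- if (is.null(out_dir)) tempfile("svdyn_inputs") else
    file.path(out_dir, "inputs")
  cohort <- simulate_cohort(sim, dir = input_dir)
  contigs <- sim$genome_sizes
  manifest <- list(seed = sim$seed, stages = list())
  log_stage <- function(name, n_in, n_out) {
    manifest$stages[[name]] <<- list(n_in = n_in, n_out = n_out)
  }

  # read callsets back through the format layer
  sv_in <- list()
  n_read <- 0L
  for (t in tps) {
    sv_in[[t]] <- list()
    for (r in seq_len(n_rep)) {
      path <- file.path(input_dir, sprintf("sv_%s_rep%d.vcf", t, r))
      sv_in[[t]][[r]] <- read_sv_vcf(path, contigs = contigs,
                                     sample_id = sprintf("%s_rep%d", t, r),
                                     timepoint = t)
      n_read <- n_read + nrow(sv_in[[t]][[r]])
    }
  }
  baseline <- read_sv_vcf(file.path(input_dir, "baseline_sv.vcf"),
                          contigs = contigs, sample_id = "kidney")
  panel <- read_sv_vcf(file.path(input_dir, "panel_sv.vcf"), contigs = contigs)
  log_stage("read", n_read, n_read)

  # quality filter + panel subtraction per sample
  n_q <- 0L; n_p <- 0L
  rejects <- list()
  for (t in tps) for (r in seq_len(n_rep)) {
    qf <- quality_filter_svs(sv_in[[t]][[r]], config$min_median_mapq)
    rejects[[length(rejects) + 1L]] <- qf$removed
    ps <- subtract_panel(qf$kept, panel, config$policy)
    sv_in[[t]][[r]] <- ps$kept
    n_q <- n_q + nrow(qf$kept)
    n_p <- n_p + nrow(ps$kept)
  }
  log_stage("quality_filter", n_read, n_q)
  log_stage("subtract_panel", n_q, n_p)
  baseline <- subtract_panel(quality_filter_svs(baseline,
                                                config$min_median_mapq)$kept,
                             panel, config$policy)$kept

  # replicate merge per timepoint
  merged <- list()
  n_m <- 0L
  freq_rows <- list()
  for (t in tps) {
    mg <- merge_replicates(sv_in[[t]], config$policy, n_rep)
    merged[[t]] <- mg$merged
    n_m <- n_m + nrow(mg$merged)
    fr <- mg$frequency
    fr$timepoint <- t
    freq_rows[[t]] <- fr
  }
  log_stage("merge_replicates", n_p, n_m)

  # de novo vs accumulated per timepoint
  denovo <- list()
  for (t in tps) {
    sp <- split_de_novo(merged[[t]], baseline, config$policy)
    denovo[[t]] <- sp
  }
  acc_n <- sum(vapply(denovo, function(x) nrow(x$accumulated), 0L))
  log_stage("split_de_novo", n_m, acc_n +
              sum(vapply(denovo, function(x) nrow(x$de_novo), 0L)))

  # combined unique SV set across timepoints (repeated junctions dropped)
  all_sv <- do.call(rbind, unname(merged))
  key <- paste(all_sv$chrom1, all_sv$pos1, all_sv$ori1,
               all_sv$chrom2, all_sv$pos2, all_sv$ori2)
  combined <- all_sv[!duplicated(key), , drop = FALSE]

  # microhomology and pathway summary
  homology <- junction_homology(cohort$genome, combined, config$flank,
                                config$bounds)
  pathway_summary <- summarize_pathways(homology)
  log_stage("microhomology", nrow(combined), nrow(homology))

  # annotation
  rep_ann <- annotate_repeats(combined, cohort$repeats, config$flank)
  k_in <- sum(!is.na(rep_ann$breakends$repeat_class))
  enrich_p <- repeat_enrichment_test(k_in, nrow(rep_ann$breakends),
                                     sim$repeat_fraction)
  fragile_hits <- intersect_fragile_sites(combined, cohort$fragile,
                                          config$flank)
  gene_ann <- annotate_genes(combined, cohort$genes)
  universe <- unique(cohort$genes$models$gene_id)
  ora <- ora_test(intersect(unique(gene_ann$disrupted$gene_id), universe),
                  cohort$gene_sets, universe, config$alpha)
  log_stage("annotation", nrow(combined), nrow(rep_ann$breakends))

  # dynamics
  clusters <- cluster_breakpoints(combined, config$max_gap, config$min_events)
  counts <- sv_burden_counts(merged, cohort, tps)
  profile <- burden_profile(counts, n_rep, tps)
  gene_hits <- do.call(rbind, lapply(tps, function(t) {
    g <- annotate_genes(merged[[t]], cohort$genes)$disrupted
    if (nrow(g) == 0) return(NULL)
    data.frame(entity = g$gene_id, timepoint = t, stringsAsFactors = FALSE)
  }))
  presence <- if (!is.null(gene_hits) && nrow(gene_hits) > 0) {
    presence_matrix(gene_hits, tps)
  } else list(matrix = matrix(FALSE, 0, length(tps)),
              patterns = data.frame(entity = character(),
                                    pattern_class = character()))
  log_stage("dynamics", nrow(combined), nrow(clusters))

  comparison <- NULL
  if (isTRUE(config$compare_null)) {
    burdens_a <- per_sample_burdens(sv_in, tps, n_rep)
    sim_b <- sim
    sim_b$seed <- sim$seed + 1009L
    cohort_b <- simulate_cohort(sim_b)
    sv_b <- list()
    for (t in tps) {
      sv_b[[t]] <- lapply(seq_len(n_rep), function(r) {
        subtract_panel(
          quality_filter_svs(cohort_b$callsets$sv[[t]][[r]],
                             config$min_median_mapq)$kept,
          cohort_b$panel, config$policy)$kept
      })
    }
    burdens_b <- per_sample_burdens(sv_b, tps, n_rep)
    comparison <- compare_groups(burdens_a, burdens_b)
  }

  summary <- list(
    pathway_counts = as.list(pathway_summary$counts),
    non_blunt_events = pathway_summary$non_blunt,
    repeat_breakend_fraction = rep_ann$fraction,
    repeat_enrichment_p = enrich_p,
    n_fragile_hits = nrow(fragile_hits),
    n_disrupted_genes = length(unique(gene_ann$disrupted$gene_id)),
    n_fusions = nrow(gene_ann$fusions),
    n_clusters = nrow(clusters),
    accumulated_fraction = if (acc_n + sum(vapply(denovo, function(x)
      nrow(x$de_novo), 0L)) > 0) {
      acc_n / (acc_n + sum(vapply(denovo, function(x) nrow(x$de_novo), 0L)))
    } else NA_real_,
    comparison = comparison)
  manifest$summary <- summary[!vapply(summary, is.null, NA)]

  result <- list(cohort = cohort, filtered = sv_in, baseline = baseline,
                 merged = merged, denovo = denovo, combined = combined,
                 homology = homology, pathway_summary = pathway_summary,
                 repeat_annotation = rep_ann, fragile_hits = fragile_hits,
                 gene_annotation = gene_ann, ora = ora, clusters = clusters,
                 profile = profile, presence = presence,
                 frequency = do.call(rbind, freq_rows),
                 rejects = do.call(rbind, rejects),
                 comparison = comparison, summary = summary,
                 manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

# combined per-timepoint counts for SV/CNV/indel burden series
sv_burden_counts <- function(merged, cohort, tps) {
  rows <- lapply(tps, function(t) {
    sv_raw <- sum(merged[[t]]$replicate_count)
    cnv_raw <- sum(vapply(cohort$callsets$cnv[[t]], function(x) {
      nrow(filter_cnvs(x)$kept)
    }, 0L))
    ind_raw <- sum(vapply(cohort$callsets$indel[[t]], nrow, 0L))
    data.frame(timepoint = t, variant_type = c("SV", "CNV", "indel"),
               raw = c(sv_raw, cnv_raw, ind_raw), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

per_sample_burdens <- function(sv_sets, tps, n_rep) {
  unlist(lapply(tps, function(t) {
    vapply(seq_len(n_rep), function(r) nrow(sv_sets[[t]][[r]]), 0L)
  }))
}

#' Write the pipeline report bundle
#'
#' Tab-separated tables (commented header naming columns and version) plus
#' `manifest.json`.
#' @param result output of [run_pipeline].
#' @param out_dir directory.
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", paste(names(df), collapse = "\t"),
                      "\tsvdynamics=", utils::packageVersion("svdynamics")),
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  wt(result$homology[, c("sv_id", "chrom1", "pos1", "chrom2", "pos2",
                         "mh_length", "mh_sequence", "pathway")],
     "microhomology.tsv")
  wt(result$repeat_annotation$breakends, "breakend_repeat.tsv")
  wt(result$fragile_hits, "fragile_hits.tsv")
  wt(result$gene_annotation$disrupted, "gene_hits.tsv")
  wt(result$gene_annotation$fusions, "fusions.tsv")
  wt(result$ora, "ora.tsv")
  wt(result$clusters, "clusters.tsv")
  wt(result$profile, "profile.tsv")
  wt(result$presence$patterns, "presence.tsv")
  wt(result$frequency, "frequency.tsv")
  wt(result$rejects, "rejects.tsv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
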