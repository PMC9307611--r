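# Longitudinal callset emission with exact ground truth: inherited/de novo
# quota, per-timepoint presence dynamics, replicate masks, wildtype-panel
# records present in every sample, and quality-failing noise records that
# exercise the hard filters.

#' Assign temporal dynamics and inheritance to truth events
#'
#' An exact quota of `round(inherited_fraction * n)` events is marked
#' inherited (present in the baseline callset). Each event is persistent
#' (present at all timepoints) with probability `p_persistent`; otherwise
#' present at timepoint t with probability `p_present[t]`, re-drawn until
#' non-empty.
#'
#' @param truth placement table ([place_breakpoints]).
#' @param config [sim_config()].
#' @return truth with added `inherited` and logical `at_<timepoint>`
#'   presence columns plus `rep_<timepoint>` replicate masks ("12", "1",
#'   "2" or "").
#' @export
assign_dynamics <- function(truth, config) {
  n <- nrow(truth)
  tps <- config$timepoints
  quota <- round(config$inherited_fraction * n)
  inherited <- rep(FALSE, n)
  if (quota > 0) inherited[sample.int(n, quota)] <- TRUE
  truth$inherited <- inherited

  dm <- config$dynamics_model
  pres <- matrix(FALSE, n, length(tps))
  for (i in seq_len(n)) {
    if (stats::runif(1) < dm$p_persistent) {
      pres[i, ] <- TRUE
    } else {
      repeat {
        v <- stats::runif(length(tps)) < dm$p_present
        if (any(v)) break
      }
      pres[i, ] <- v
    }
  }
  reps <- matrix("", n, length(tps))
  for (i in seq_len(n)) {
    for (t in seq_along(tps)) {
      if (!pres[i, t]) next
      reps[i, t] <- if (config$replicates_per_timepoint == 1L) "1"
        else if (stats::runif(1) < config$p_both_replicates) {
          paste(seq_len(config$replicates_per_timepoint), collapse = "")
        } else {
          as.character(sample.int(config$replicates_per_timepoint, 1))
        }
    }
  }
  for (t in seq_along(tps)) {
    truth[[paste0("at_", tps[t])]] <- pres[, t]
    truth[[paste0("rep_", tps[t])]] <- reps[, t]
  }
  truth
}

truth_to_sv <- function(truth, sample_id = NA_character_,
                        timepoint = NA_character_) {
  if (nrow(truth) == 0) return(empty_sv_table())
  sv_table(data.frame(
    sv_id = truth$event_id, sv_type = truth$sv_type,
    chrom1 = truth$chrom1, pos1 = truth$pos1, ori1 = truth$ori1,
    chrom2 = truth$chrom2, pos2 = truth$pos2, ori2 = truth$ori2,
    median_mapq = truth$median_mapq, support_reads = truth$support_reads,
    normal_discordant = FALSE, artifact_flag = FALSE,
    sample_id = sample_id, timepoint = timepoint,
    stringsAsFactors = FALSE))
}

# strain-background (wildtype panel) events: clean quality, everywhere
generate_panel <- function(config, pools) {
  n <- config$n_panel
  if (n == 0) return(empty_sv_table())
  rows <- lapply(seq_len(n), function(i) {
    chrom <- sample(names(config$genome_sizes), 1)
    pool <- pools[[chrom]]
    repeat {
      p1 <- sample_pool_position(pool, stats::runif(1) < 0.5)
      p2 <- sample_pool_position(pool, stats::runif(1) < 0.5)
      if (!is.na(p1) && !is.na(p2) && abs(p2 - p1) > 400L) break
    }
    type <- sample(c("DEL", "DUP", "INV"), 1)
    oris <- sv_orientations(type)
    data.frame(sv_id = sprintf("panel%03d", i), sv_type = type,
               chrom1 = chrom, pos1 = min(p1, p2), ori1 = oris[1],
               chrom2 = chrom, pos2 = max(p1, p2), ori2 = oris[2],
               median_mapq = sample(45:60, 1), normal_discordant = FALSE,
               artifact_flag = FALSE, support_reads = sample(5:40, 1),
               stringsAsFactors = FALSE)
  })
  sv_table(do.call(rbind, rows))
}

# quality-failing records cycling through the three removal reasons
generate_noise_svs <- function(n, config, prefix) {
  if (n == 0) return(empty_sv_table())
  sizes <- config$genome_sizes
  rows <- lapply(seq_len(n), function(i) {
    chrom <- sample(names(sizes), 1)
    p1 <- sample.int(sizes[[chrom]] - 6000L, 1) + 500L
    p2 <- p1 + sample(500:5000, 1)
    mode <- (i - 1L) %% 3L
    data.frame(sv_id = sprintf("%s%03d", prefix, i), sv_type = "DEL",
               chrom1 = chrom, pos1 = p1, ori1 = "right",
               chrom2 = chrom, pos2 = p2, ori2 = "left",
               median_mapq = if (mode == 0L) sample(0:39, 1) else sample(40:60, 1),
               normal_discordant = mode == 1L,
               artifact_flag = mode == 2L,
               support_reads = sample(2:10, 1),
               stringsAsFactors = FALSE)
  })
  sv_table(do.call(rbind, rows))
}

generate_cnv_truth <- function(config) {
  n <- config$n_cnv
  sizes <- config$genome_sizes
  if (n == 0) return(cnv_table(data.frame(chrom = character(), start = integer(),
    end = integer(), cnv_type = character(), normalized_rd = numeric(),
    e_value = numeric(), q0 = numeric(), stringsAsFactors = FALSE)))
  chrom <- sample(names(sizes), n, replace = TRUE)
  len <- sample(2000:50000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(sizes[[chrom[i]]] - len[i] - 1L, 1)
  }, 0L)
  type <- sample(c("gain", "loss"), n, replace = TRUE)
  cnv_table(data.frame(
    cnv_id = sprintf("cnv%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + len, cnv_type = type,
    normalized_rd = ifelse(type == "loss", stats::runif(n, 0.05, 0.35),
                           stats::runif(n, 1.7, 3.0)),
    e_value = 10^stats::runif(n, -8, -2),
    q0 = stats::runif(n, 0, 0.4),
    stringsAsFactors = FALSE))
}

# CNV noise: each record fails exactly one of the four hard filters
generate_noise_cnvs <- function(n, config, prefix) {
  sizes <- config$genome_sizes
  if (n == 0) return(generate_cnv_truth(sim_config_zero_cnv(config)))
  chrom <- sample(names(sizes), n, replace = TRUE)
  len <- sample(2000:20000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(sizes[[chrom[i]]] - len[i] - 1L, 1)
  }, 0L)
  mode <- (seq_len(n) - 1L) %% 4L
  len[mode == 1L] <- sample(200:1000, sum(mode == 1L), replace = TRUE)
  df <- data.frame(
    cnv_id = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = chrom, start = start, end = start + len,
    cnv_type = sample(c("gain", "loss"), n, replace = TRUE),
    q0 = ifelse(mode == 0L, stats::runif(n, 0.5, 1), stats::runif(n, 0, 0.4)),
    e_value = ifelse(mode == 2L, stats::runif(n, 0.05, 1), 10^stats::runif(n, -8, -2)),
    stringsAsFactors = FALSE)
  df$normalized_rd <- ifelse(df$cnv_type == "loss",
                             stats::runif(n, 0.05, 0.35),
                             stats::runif(n, 1.7, 3.0))
  bad_rd <- mode == 3L
  df$normalized_rd[bad_rd] <- ifelse(df$cnv_type[bad_rd] == "loss",
                                     stats::runif(sum(bad_rd), 0.45, 1.2),
                                     stats::runif(sum(bad_rd), 0.8, 1.55))
  cnv_table(df)
}

sim_config_zero_cnv <- function(config) {
  config$n_cnv <- 0L
  config
}

generate_indel_truth <- function(config, seqs) {
  n <- config$n_indel
  sizes <- config$genome_sizes
  if (n == 0) {
    return(indel_table(data.frame(chrom = character(), start = integer(),
      ref = character(), alt = character(), stringsAsFactors = FALSE)))
  }
  rows <- lapply(seq_len(n), function(i) {
    chrom <- sample(names(sizes), 1)
    pos <- sample.int(sizes[[chrom]] - 100L, 1) + 20L
    L <- sample(1:10, 1)
    anchor <- substr(seqs[[chrom]], pos + 1L, pos + 1L)
    if (stats::runif(1) < 0.5) {
      ref <- substr(seqs[[chrom]], pos + 1L, pos + 1L + L)
      alt <- anchor
    } else {
      ref <- anchor
      alt <- paste0(anchor, random_dna(L))
    }
    data.frame(indel_id = sprintf("ind%04d", i), chrom = chrom, start = pos,
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  })
  indel_table(do.call(rbind, rows))
}

#' Generate a complete synthetic longitudinal cohort
#'
#' Runs the full generator under `config$seed`: genome and annotation
#' tracks, breakpoint placement, microhomology implantation, dynamics and
#' inheritance assignment, CNV/indel truth with their own presence masks,
#' wildtype panel, and (optionally) all files on disk. Two runs with the
#' same configuration are byte-identical.
#'
#' @param config [sim_config()].
#' @param dir optional output directory; when given, every external-format
#'   file plus the truth table and a JSON configuration echo are written
#'   (see [write_cohort]).
#' @return list: config, genome, repeats, fragile, genes, gene_sets,
#'   truth (SV truth with dynamics columns), cnv_truth, indel_truth
#'   (with `at_<tp>`/`rep_<tp>` columns), panel, baseline (SV table),
#'   and callsets: `sv[[tp]][[rep]]`, `cnv[[tp]][[rep]]`,
#'   `indel[[tp]][[rep]]` tables including noise records.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  gen <- generate_genome(config)          # seeds the RNG with config$seed
  truth <- place_breakpoints(gen, config)
  genome <- implant_junctions(gen$genome, truth, config$flank)
  truth$median_mapq <- sample(40:60, nrow(truth), replace = TRUE)
  truth$support_reads <- sample(4:60, nrow(truth), replace = TRUE)
  truth <- assign_dynamics(truth, config)

  seqs <- stats::setNames(as.list(as.character(genome)), names(genome))
  cnv_truth <- assign_dynamics(generate_cnv_truth(config), config)
  indel_truth <- assign_dynamics(generate_indel_truth(config, seqs), config)
  pools <- build_pools(config$genome_sizes, gen$repeats, config$flank)
  panel <- generate_panel(config, pools)
  gene_sets <- synthetic_gene_sets(gen$genes)

  tps <- config$timepoints
  n_rep <- config$replicates_per_timepoint
  sv_sets <- list(); cnv_sets <- list(); indel_sets <- list()
  for (t in tps) {
    sv_sets[[t]] <- list(); cnv_sets[[t]] <- list(); indel_sets[[t]] <- list()
    for (r in seq_len(n_rep)) {
      sample_id <- sprintf("%s_rep%d", t, r)
      in_rep <- grepl(as.character(r), truth[[paste0("rep_", t)]], fixed = TRUE)
      sv <- truth_to_sv(truth[in_rep, , drop = FALSE], sample_id, t)
      sv <- rbind(sv, panel_with_labels(panel, sample_id, t))
      n_noise <- round(config$noise_fraction * nrow(sv))
      noise <- generate_noise_svs(n_noise, config,
                                  sprintf("noise_%s_r%d_", t, r))
      noise$sample_id <- rep(sample_id, nrow(noise))
      noise$timepoint <- rep(t, nrow(noise))
      sv_sets[[t]][[r]] <- rbind(sv, noise)

      in_rep_c <- grepl(as.character(r), cnv_truth[[paste0("rep_", t)]], fixed = TRUE)
      cnv <- cnv_truth[in_rep_c, cnv_table_columns, drop = FALSE]
      cnv$sample_id <- rep(sample_id, nrow(cnv))
      cnv$timepoint <- rep(t, nrow(cnv))
      cnoise <- generate_noise_cnvs(max(2L, round(config$noise_fraction * nrow(cnv))),
                                    config, sprintf("cnoise_%s_r%d_", t, r))
      cnoise$sample_id <- rep(sample_id, nrow(cnoise))
      cnoise$timepoint <- rep(t, nrow(cnoise))
      cnv_sets[[t]][[r]] <- rbind(cnv, cnoise)

      in_rep_i <- grepl(as.character(r), indel_truth[[paste0("rep_", t)]], fixed = TRUE)
      ind <- indel_truth[in_rep_i, indel_table_columns, drop = FALSE]
      ind$sample_id <- rep(sample_id, nrow(ind))
      ind$timepoint <- rep(t, nrow(ind))
      indel_sets[[t]][[r]] <- ind
    }
  }
  baseline <- rbind(
    truth_to_sv(truth[truth$inherited, , drop = FALSE], "kidney", "baseline"),
    panel_with_labels(panel, "kidney", "baseline"))

  cohort <- list(config = config, genome = genome, repeats = gen$repeats,
                 fragile = gen$fragile, genes = gen$genes,
                 gene_sets = gene_sets, truth = truth,
                 cnv_truth = cnv_truth, indel_truth = indel_truth,
                 panel = panel, baseline = baseline,
                 callsets = list(sv = sv_sets, cnv = cnv_sets,
                                 indel = indel_sets))
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

panel_with_labels <- function(panel, sample_id, timepoint) {
  if (nrow(panel) == 0) return(panel)
  panel$sample_id <- sample_id
  panel$timepoint <- timepoint
  panel
}

#' Write a simulated cohort to disk in external formats
#'
#' FASTA genome, RepeatMasker-style repeat annotation, fragile-site BED,
#' gene-model GTF, GMT gene sets, per-timepoint-replicate SV/indel VCFs and
#' CNV tables, baseline and panel SV VCFs, the truth table (TSV) and the
#' configuration echo (JSON).
#' @param cohort output of [simulate_cohort].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contigs <- cohort$config$genome_sizes
  write_fasta(cohort$genome, file.path(dir, "genome.fa"))
  write_repeatmasker_out(cohort$repeats, file.path(dir, "repeats.out"))
  write_bed(cohort$fragile, file.path(dir, "fragile.bed"))
  write_gene_models(cohort$genes, file.path(dir, "genes.gtf"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  for (t in cohort$config$timepoints) {
    for (r in seq_len(cohort$config$replicates_per_timepoint)) {
      tag <- sprintf("%s_rep%d", t, r)
      write_sv_vcf(cohort$callsets$sv[[t]][[r]],
                   file.path(dir, paste0("sv_", tag, ".vcf")), contigs)
      write_cnv_table(cohort$callsets$cnv[[t]][[r]],
                      file.path(dir, paste0("cnv_", tag, ".tsv")))
      write_indel_vcf(cohort$callsets$indel[[t]][[r]],
                      file.path(dir, paste0("indel_", tag, ".vcf")), contigs)
    }
  }
  write_sv_vcf(cohort$baseline, file.path(dir, "baseline_sv.vcf"), contigs)
  write_sv_vcf(cohort$panel, file.path(dir, "panel_sv.vcf"), contigs)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$genome_sizes <- as.list(cfg$genome_sizes)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
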