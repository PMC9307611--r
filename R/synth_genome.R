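# Synthetic reference genome with designed repeat coverage, fragile-site
# intervals and simple single-transcript gene models. The repeat annotation
# carries the designed coverage exactly (interval lengths are drawn and then
# trimmed to the per-chromosome target), while the underlying sequence is
# uniform random: repeats here are annotation-defined, which is what the
# breakpoint-overlap analyses consume.

REPEAT_CLASSES <- c("Simple_repeat", "LINE/L1", "LTR/ERVK", "SINE/B1")
FRAGILE_NAMES <- c("Astn2", "Il1rapl1", "Rev3l", "Thsd7a", "Wwox",
                   "Fhit", "Dmd", "Grid2")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# alternating gap/repeat layout whose repeat total equals the target
chrom_repeat_layout <- function(len, target, min_gap = 60L) {
  if (target <= 0) return(data.frame(start = integer(), end = integer()))
  lens <- integer()
  remaining <- target
  while (remaining > 0) {
    L <- sample(150:1200, 1)
    if (L > remaining) L <- remaining
    lens <- c(lens, L)
    remaining <- remaining - L
  }
  n_gap <- length(lens) + 1L
  gap_total <- len - sum(lens)
  if (gap_total < n_gap * min_gap) {
    stop("repeat placement failure: repeat_fraction too high for chromosome length")
  }
  w <- stats::runif(n_gap, 0.2, 1)
  gaps <- floor((gap_total - n_gap * min_gap) * w / sum(w)) + min_gap
  gaps[n_gap] <- gap_total - sum(gaps[-n_gap])
  # interleave gap1, rep1, gap2, rep2, ...
  starts <- integer(length(lens))
  pos <- 0L
  for (i in seq_along(lens)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  data.frame(start = starts, end = starts + lens)
}

#' Generate a synthetic reference genome and annotation tracks
#'
#' Draws a uniform-random genome, a repeat annotation whose realized
#' coverage equals the configured `repeat_fraction` (per chromosome, up to
#' integer rounding), a fragile-site track of gene-named intervals, and
#' single-transcript gene models whose CDS lengths are divisible by 3.
#' Fully deterministic under `config$seed`.
#'
#' @param config [sim_config()].
#' @return list: `genome` (DNAStringSet), `repeats`, `fragile` (annotation
#'   tracks), `genes` (gene-models list as in [read_gene_models]).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  sizes <- config$genome_sizes
  seqs <- lapply(sizes, random_dna)
  repeats <- list()
  for (chrom in names(sizes)) {
    target <- round(config$repeat_fraction * sizes[[chrom]])
    layout <- chrom_repeat_layout(sizes[[chrom]], target)
    if (nrow(layout) > 0) {
      repeats[[chrom]] <- annotation_track(
        chrom = chrom, start = layout$start, end = layout$end,
        class = sample(REPEAT_CLASSES, nrow(layout), replace = TRUE,
                       prob = c(0.3, 0.3, 0.2, 0.2)))
    }
  }
  repeats <- if (length(repeats) > 0) do.call(rbind, c(repeats, make.row.names = FALSE))
             else annotation_track()
  fragile <- generate_fragile_sites(sizes, config$n_fragile)
  genes <- generate_gene_models(sizes, config$n_genes)
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(sizes)
  list(genome = genome, repeats = repeats, fragile = fragile, genes = genes)
}

generate_fragile_sites <- function(sizes, n_fragile) {
  if (n_fragile == 0) return(annotation_track())
  nms <- rep_len(FRAGILE_NAMES, n_fragile)
  chroms <- sample(names(sizes), n_fragile, replace = TRUE)
  width <- min(80000L, as.integer(min(sizes) %/% 4L))
  starts <- vapply(chroms, function(c) {
    sample.int(sizes[[c]] - width, 1)
  }, 0L)
  tr <- annotation_track(chroms, starts, starts + width, nms)
  tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

# single-transcript genes, 2-4 all-coding exons, CDS length divisible by 3
generate_gene_models <- function(sizes, n_genes) {
  if (n_genes == 0) return(gene_models(data.frame(
    gene_id = character(), chrom = character(), strand = character(),
    feature = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE)))
  per_chrom <- table(factor(sample(names(sizes), n_genes, replace = TRUE),
                            levels = names(sizes)))
  rows <- list()
  gi <- 0L
  for (chrom in names(sizes)) {
    k <- per_chrom[[chrom]]
    if (k == 0) next
    # lay genes out left to right with random spacing
    slot <- floor(sizes[[chrom]] / (k + 1))
    for (j in seq_len(k)) {
      gi <- gi + 1L
      gene_id <- sprintf("gene%03d", gi)
      strand <- sample(c("+", "-"), 1)
      n_exon <- sample(2:4, 1)
      exon_len <- sample(150:600, n_exon, replace = TRUE)
      excess <- sum(exon_len) %% 3L
      exon_len[n_exon] <- exon_len[n_exon] - excess
      intron_len <- sample(200:2000, n_exon - 1, replace = TRUE)
      start0 <- (j - 1L) * slot + sample.int(max(slot %/% 4L, 1L), 1)
      pos <- start0
      for (e in seq_len(n_exon)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, chrom = chrom, strand = strand,
          feature = c("exon", "CDS"), start = pos, end = pos + exon_len[e],
          stringsAsFactors = FALSE)
        pos <- pos + exon_len[e] + if (e < n_exon) intron_len[e] else 0L
      }
    }
  }
  gene_models(do.call(rbind, rows))
}

#' Generate synthetic gene sets over a gene-model universe
#'
#' Random member draws plus one set seeded with the first genes, giving a
#' mixture of null and potentially enriched sets for over-representation
#' testing.
#' @param genes gene-models list.
#' @param n_sets number of sets; @param set_size members per set.
#' @return named list of gene-id vectors.
#' @export
synthetic_gene_sets <- function(genes, n_sets = 6L, set_size = 8L) {
  ids <- unique(genes$models$gene_id)
  sets <- lapply(seq_len(n_sets), function(i) {
    sort(sample(ids, min(set_size, length(ids))))
  })
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  sets[["dna_repair_like"]] <- utils::head(sort(ids), min(set_size, length(ids)))
  sets
}

# union length of a track (coverage oracle helper used by callers/tests)
track_coverage <- function(track, sizes) {
  if (nrow(track) == 0) return(0)
  gr <- GenomicRanges::reduce(track_to_granges(track))
  sum(as.numeric(GenomicRanges::width(gr))) / sum(as.numeric(sizes))
}
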