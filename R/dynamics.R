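# Hotspot clustering, median-normalized burden profiles, temporal
# presence-pattern classification, and genotype-group comparison.

#' Detect breakpoint hotspot clusters by positional chaining
#'
#' Single-linkage chaining per chromosome: consecutive (sorted) breakends
#' join one cluster iff their gap is at most `max_gap`; chains with fewer
#' than `min_events` members are discarded. Deterministic and
#' permutation-invariant.
#'
#' Defaults are scaled to the desk-scale synthetic genomes this package
#' simulates (megabase chromosomes at whole-genome-sequencing breakpoint
#' density); on a full mammalian genome the equivalent chaining distance is
#' of megabase order and should be set explicitly.
#'
#' @param breakends breakend table ([breakend_table]) or SV table.
#' @param max_gap maximum gap between consecutive cluster members, bp
#'   (default 4000).
#' @param min_events minimum members per reported cluster (default 5).
#' @return data frame: cluster_id, chrom, start, end (0-based half-open
#'   span covering all members), n_events, sv_ids (comma-separated
#'   member ids), sorted by chromosome then start.
#' @export
cluster_breakpoints <- function(breakends, max_gap = 4000L, min_events = 5L) {
  if ("sv_type" %in% names(breakends)) breakends <- breakend_table(breakends)
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_events = integer(), sv_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(breakends) == 0) return(empty)
  out <- list()
  for (chrom in sort(unique(breakends$chrom))) {
    b <- breakends[breakends$chrom == chrom, , drop = FALSE]
    b <- b[order(b$pos, b$sv_id), , drop = FALSE]
    gap_break <- c(TRUE, diff(b$pos) > max_gap)
    grp <- cumsum(gap_break)
    for (g in unique(grp)) {
      members <- b[grp == g, , drop = FALSE]
      if (nrow(members) >= min_events) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = min(members$pos),
          end = max(members$pos) + 1L, n_events = nrow(members),
          sv_ids = paste(unique(members$sv_id), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("cluster%02d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Median-normalized per-timepoint mutation burden profile
#'
#' For each variant type, the raw combined count per timepoint is divided
#' by the replicate count (the "combined and divided by 2" average for a
#' duplicate design) and then normalized by the median of the averaged
#' series across timepoints. An all-zero series has no defined
#' normalization and is reported as missing with a flag.
#'
#' @param counts data frame with columns `timepoint`, `variant_type`,
#'   `raw` (combined record count across replicates).
#' @param replicates replicate count per timepoint.
#' @param timepoints ordered timepoint labels (default: order of
#'   appearance).
#' @return data frame: timepoint, variant_type, raw, averaged, normalized
#'   (NA for an all-zero series), degenerate flag.
#' @export
burden_profile <- function(counts, replicates = 2L,
                           timepoints = unique(counts$timepoint)) {
  stopifnot(all(counts$timepoint %in% timepoints))
  out <- lapply(unique(counts$variant_type), function(vt) {
    d <- counts[counts$variant_type == vt, , drop = FALSE]
    d <- d[match(timepoints, d$timepoint), , drop = FALSE]
    d$timepoint <- timepoints
    d$variant_type <- vt
    d$raw[is.na(d$raw)] <- 0
    d$averaged <- d$raw / replicates
    med <- stats::median(d$averaged)
    if (med == 0) {
      d$normalized <- NA_real_
      d$degenerate <- TRUE
    } else {
      d$normalized <- d$averaged / med
      d$degenerate <- FALSE
    }
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("timepoint", "variant_type", "raw", "averaged", "normalized",
          "degenerate")]
}

#' Classify a temporal presence pattern
#'
#' `persistent`: present at every timepoint; `recurrent`: present, then
#' absent, then present again at least once; `transient`: any other
#' non-empty pattern. The three classes are exhaustive and mutually
#' exclusive over non-empty presence vectors.
#' @param present logical vector ordered by timepoint, at least one `TRUE`.
#' @return one of `"persistent"`, `"recurrent"`, `"transient"`.
#' @export
classify_presence <- function(present) {
  if (!any(present)) stop("presence vector must be non-empty")
  if (all(present)) return("persistent")
  r <- rle(present)
  runs <- r$values[r$values]
  if (length(runs) >= 2) "recurrent" else "transient"
}

#' Per-entity presence matrix across timepoints
#'
#' Builds the gene/cluster-by-timepoint presence matrix underlying
#' timecourse heatmaps: an entity is present at a timepoint iff at least
#' `min_hits` merged records hit it there.
#'
#' @param hits data frame with columns `entity` (gene or cluster id) and
#'   `timepoint`; one row per record hit.
#' @param timepoints ordered timepoint labels.
#' @param min_hits presence threshold (default 1).
#' @return list with `matrix` (logical entity x timepoint) and `patterns`
#'   (data frame: entity, pattern_class).
#' @export
presence_matrix <- function(hits, timepoints, min_hits = 1L) {
  entities <- sort(unique(hits$entity))
  mat <- matrix(FALSE, nrow = length(entities), ncol = length(timepoints),
                dimnames = list(entities, timepoints))
  if (nrow(hits) > 0) {
    tab <- table(factor(hits$entity, entities),
                 factor(hits$timepoint, timepoints))
    mat <- tab >= min_hits
  }
  seen <- entities[rowSums(mat) > 0]
  patterns <- data.frame(
    entity = seen,
    pattern_class = vapply(seen, function(e) classify_presence(mat[e, ]), ""),
    stringsAsFactors = FALSE)
  rownames(patterns) <- NULL
  list(matrix = mat, patterns = patterns)
}

#' Compare genome-instability burden between two groups
#'
#' Unpaired two-sided Student's t test with pooled variance on per-sample
#' burdens. Degenerate inputs are resolved explicitly: zero pooled
#' variance with equal means gives t = 0, p = 1; zero pooled variance with
#' unequal means gives p = 0 with a degenerate flag.
#'
#' @param group_a,group_b numeric vectors of per-sample burdens (>= 2
#'   samples each).
#' @param welch use the Welch unequal-variance form instead (default
#'   `FALSE`).
#' @return list: t, p, df, mean_a, mean_b, degenerate.
#' @export
compare_groups <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples")
  }
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                 sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2)
  if (pooled_var == 0 && stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    equal <- mean(group_a) == mean(group_b)
    return(list(t = if (equal) 0 else Inf * sign(mean(group_a) - mean(group_b)),
                p = if (equal) 1 else 0,
                df = length(group_a) + length(group_b) - 2,
                mean_a = mean(group_a), mean_b = mean(group_b),
                degenerate = TRUE))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = !welch,
                       alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b), degenerate = FALSE)
}
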