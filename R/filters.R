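# Post-caller hard filters for SV and CNV callsets. Boundary semantics
# follow the stated inequalities strictly: MAPQ < 40 is removed (40 kept);
# CNVs must exceed 1 kb; e-value and q0 must fall strictly below their
# cutoffs; loss read depth strictly below 0.4, gain strictly above 1.6.

#' Quality-filter an SV callset
#'
#' Removes records with (1) poor mapping quality (median MAPQ below
#' `min_median_mapq`), (2) discordant read support in the paired normal, or
#' (3) a DNA library artifact flag. Each removed record carries exactly one
#' primary reason, assigned in that order.
#'
#' @param svs SV table.
#' @param min_median_mapq removal threshold; a record is removed iff
#'   `median_mapq < min_median_mapq` (default 40, so 40 itself is kept).
#' @return list with `kept` (SV table) and `removed` (SV table plus a
#'   `reason` column); the two partition the input.
#' @export
quality_filter_svs <- function(svs, min_median_mapq = 40L) {
  svs <- sv_table(svs)
  if (anyNA(svs$median_mapq) || anyNA(svs$normal_discordant) ||
      anyNA(svs$artifact_flag)) {
    bad <- which(is.na(svs$median_mapq) | is.na(svs$normal_discordant) |
                   is.na(svs$artifact_flag))
    stop("missing quality field(s) for record(s): ",
         paste(svs$sv_id[bad], collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(svs))
  reason[svs$artifact_flag] <- "library artifact"
  reason[svs$normal_discordant] <- "discordant reads in paired normal"
  reason[svs$median_mapq < min_median_mapq] <-
    sprintf("median MAPQ < %d", as.integer(min_median_mapq))
  removed <- svs[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = svs[is.na(reason), , drop = FALSE], removed = removed)
}

#' Hard-filter a CNV callset
#'
#' A call is kept iff q0 < `max_q0`, length > `min_length` bp,
#' e-value < `max_e`, and the normalized read depth is consistent with the
#' call: losses strictly below `loss_rd_max`, gains strictly above
#' `gain_rd_min`.
#'
#' @param cnvs CNV table.
#' @param max_q0,min_length,max_e,loss_rd_max,gain_rd_min thresholds
#'   (defaults 0.5, 1000 bp, 0.05, 0.4, 1.6).
#' @return list with `kept` and `removed` (with `reason`, first failing
#'   check in the order q0, length, e-value, read depth).
#' @export
filter_cnvs <- function(cnvs, max_q0 = 0.5, min_length = 1000L,
                        max_e = 0.05, loss_rd_max = 0.4, gain_rd_min = 1.6) {
  cnvs <- cnv_table(cnvs)
  len <- cnvs$end - cnvs$start
  rd_ok <- ifelse(cnvs$cnv_type == "loss",
                  cnvs$normalized_rd < loss_rd_max,
                  cnvs$normalized_rd > gain_rd_min)
  reason <- rep(NA_character_, nrow(cnvs))
  reason[!rd_ok] <- "read depth"
  reason[!(cnvs$e_value < max_e)] <- "e-value"
  reason[!(len > min_length)] <- "length"
  reason[!(cnvs$q0 < max_q0)] <- "q0"
  removed <- cnvs[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = cnvs[is.na(reason), , drop = FALSE], removed = removed)
}

#' Breakpoint match policy
#'
#' Two SV records match when both breakend positions agree within `window`
#' bp on the same chromosomes and, when required, types and orientations
#' agree. The study states no tolerance; 100 bp is conservative relative to
#' typical caller confidence intervals.
#' @param window bp tolerance (default 100).
#' @param require_type_match,require_orientation_match strictness flags
#'   (default both `TRUE`).
#' @return a `match_policy` list.
#' @export
match_policy <- function(window = 100L, require_type_match = TRUE,
                         require_orientation_match = TRUE) {
  if (window < 0) stop("match window must be >= 0")
  structure(list(window = as.integer(window),
                 require_type_match = require_type_match,
                 require_orientation_match = require_orientation_match),
            class = "match_policy")
}

# logical vector: does svs[i] match any record in ref under policy?
sv_matches_any <- function(svs, ref, policy) {
  if (nrow(svs) == 0) return(logical(0))
  if (nrow(ref) == 0) return(rep(FALSE, nrow(svs)))
  w <- policy$window
  vapply(seq_len(nrow(svs)), function(i) {
    cand <- ref$chrom1 == svs$chrom1[i] & ref$chrom2 == svs$chrom2[i] &
      abs(ref$pos1 - svs$pos1[i]) <= w & abs(ref$pos2 - svs$pos2[i]) <= w
    if (policy$require_type_match) {
      cand <- cand & ref$sv_type == svs$sv_type[i]
    }
    if (policy$require_orientation_match) {
      cand <- cand & ref$ori1 == svs$ori1[i] & ref$ori2 == svs$ori2[i]
    }
    any(cand)
  }, NA)
}

#' Subtract a wildtype panel from an SV callset
#'
#' Removes every record matching a wildtype-control (strain-background)
#' record under `policy`, cancelling strain-vs-reference differences.
#' Idempotent.
#' @param svs SV table; @param panel panel SV table.
#' @param policy [match_policy()].
#' @return list with `kept` and `removed`.
#' @export
subtract_panel <- function(svs, panel, policy = match_policy()) {
  svs <- sv_table(svs)
  hit <- sv_matches_any(svs, sv_table(panel), policy)
  list(kept = svs[!hit, , drop = FALSE], removed = svs[hit, , drop = FALSE])
}

#' Separate accumulated from de novo events against a baseline callset
#'
#' Records matching the baseline (e.g. the kidney callset of the matched
#' individual, a tissue taken as inheritance-stable) are classed
#' accumulated/inherited; the rest are de novo. The two outputs partition
#' the input.
#' @param svs SV table; @param baseline baseline SV table.
#' @param policy [match_policy()].
#' @return list with `accumulated` and `de_novo`.
#' @export
split_de_novo <- function(svs, baseline, policy = match_policy()) {
  svs <- sv_table(svs)
  baseline <- sv_table(baseline)
  if (nrow(baseline) == 0) {
    warning("empty baseline callset: every record is classed de novo")
  }
  hit <- sv_matches_any(svs, baseline, policy)
  list(accumulated = svs[hit, , drop = FALSE],
       de_novo = svs[!hit, , drop = FALSE])
}

#' Merge replicate callsets at one timepoint
#'
#' Union semantics: records matching across replicates under `policy`
#' appear once with `replicate_count` equal to the number of replicates
#' carrying them; a record private to one replicate is retained with count
#' 1. The per-variant-type frequency is the combined record total divided
#' by the number of replicates (the "combined and divided by 2" average
#' for duplicate cohorts).
#'
#' @param callsets list of SV tables, one per replicate.
#' @param policy [match_policy()].
#' @param replicates expected replicate count; mismatch with
#'   `length(callsets)` is an error.
#' @return list with `merged` (SV table + `replicate_count`) and
#'   `frequency` (data frame: sv_type, frequency).
#' @export
merge_replicates <- function(callsets, policy = match_policy(),
                             replicates = length(callsets)) {
  if (length(callsets) != replicates) {
    stop("expected ", replicates, " replicates, got ", length(callsets))
  }
  callsets <- lapply(callsets, sv_table)
  merged <- callsets[[1]]
  merged$replicate_count <- rep(1L, nrow(merged))
  for (rep_i in seq_along(callsets)[-1]) {
    nxt <- callsets[[rep_i]]
    hit <- sv_matches_any(nxt, merged, policy)
    if (any(hit)) {
      # count each matched incoming record toward its first merged match
      for (j in which(hit)) {
        cand <- which(sv_matches_any(merged, nxt[j, , drop = FALSE], policy))
        merged$replicate_count[cand[1]] <- merged$replicate_count[cand[1]] + 1L
      }
    }
    if (any(!hit)) {
      add <- nxt[!hit, , drop = FALSE]
      add$replicate_count <- 1L
      merged <- rbind(merged, add)
    }
  }
  total_by_type <- tapply(merged$replicate_count, factor(merged$sv_type, SV_TYPES),
                          sum, default = 0L)
  freq <- data.frame(sv_type = SV_TYPES,
                     frequency = as.numeric(total_by_type) / replicates,
                     stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  list(merged = merged, frequency = freq)
}
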