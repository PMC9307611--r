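#' svdynamics: longitudinal genome-instability profiling
#'
#' All genomic coordinates inside the package are 0-based half-open
#' (`[start, end)`); 1-based external formats (VCF, RepeatMasker .out, GTF,
#' CNVnator tables) are converted exactly once on read and once on write.
#'
#' A breakend is an oriented breakpoint side. Orientation `"right"` means the
#' breakend faces right: the retained sequence lies to the LEFT of (and
#' including) `pos`, and the junction follows `pos`. Orientation `"left"`
#' means the retained sequence starts at `pos` and extends rightwards, the
#' junction preceding it. Under this convention a deletion joining
#' `ref[..p1]` to `ref[p2..]` has breakends `(p1, right)` and `(p2, left)`,
#' a tandem duplication has `(p1, left)` then `(p2, right)`, and an
#' inversion junction has matching orientations on both sides.
#'
#' @keywords internal
"_PACKAGE"

SV_TYPES <- c("DEL", "DUP", "INV", "BND")
ORIENTATIONS <- c("left", "right")

#' Columns of an SV record table
#'
#' SV callsets are plain data frames with one row per structural variant and
#' these columns. `pos1`/`pos2` are 0-based breakend positions; `ori1`/`ori2`
#' are `"left"` or `"right"` (see package help for the convention).
#' @format Character vector of required column names.
#' @export
sv_table_columns <- c(
  "sv_id", "sv_type", "chrom1", "pos1", "ori1", "chrom2", "pos2", "ori2",
  "median_mapq", "normal_discordant", "artifact_flag", "support_reads",
  "sample_id", "timepoint"
)

cnv_table_columns <- c(
  "cnv_id", "chrom", "start", "end", "cnv_type", "normalized_rd",
  "e_value", "q0", "sample_id", "timepoint"
)

indel_table_columns <- c(
  "indel_id", "chrom", "start", "end", "ref", "alt", "kind",
  "sample_id", "timepoint"
)

#' Build and validate an SV record table
#'
#' @param df data frame carrying at least the coordinate and type columns.
#'   Missing quality/label columns are filled with permissive defaults
#'   (`median_mapq = 60`, flags `FALSE`, `support_reads = 0`, labels `NA`).
#' @param contigs optional named integer vector of contig lengths (a sequence
#'   dictionary); when supplied, unknown chromosomes or out-of-range
#'   positions are an error.
#' @return the validated data frame with columns in canonical order.
#' @export
sv_table <- function(df, contigs = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sv_id" %in% names(df)) {
    df$sv_id <- sprintf("sv%05d", seq_len(nrow(df)))
  }
  defaults <- list(median_mapq = 60L, normal_discordant = FALSE,
                   artifact_flag = FALSE, support_reads = 0L,
                   sample_id = NA_character_, timepoint = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }
  missing <- setdiff(sv_table_columns, names(df))
  if (length(missing) > 0) {
    stop("SV table is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[, sv_table_columns, drop = FALSE]
  df$pos1 <- as.integer(df$pos1)
  df$pos2 <- as.integer(df$pos2)
  if (!all(df$sv_type %in% SV_TYPES)) {
    stop("sv_type must be one of ", paste(SV_TYPES, collapse = "/"))
  }
  if (!all(df$ori1 %in% ORIENTATIONS) || !all(df$ori2 %in% ORIENTATIONS)) {
    stop("orientations must be 'left' or 'right'")
  }
  intra <- df$sv_type %in% c("DEL", "DUP", "INV")
  bad <- intra & (df$chrom1 != df$chrom2 | df$pos1 >= df$pos2)
  if (any(bad)) {
    stop("DEL/DUP/INV records must have chrom1 == chrom2 and pos1 < pos2 (",
         paste(df$sv_id[bad], collapse = ", "), ")")
  }
  ok_ori <- rep(TRUE, nrow(df))
  ok_ori[df$sv_type == "DEL"] <-
    df$ori1[df$sv_type == "DEL"] == "right" & df$ori2[df$sv_type == "DEL"] == "left"
  ok_ori[df$sv_type == "DUP"] <-
    df$ori1[df$sv_type == "DUP"] == "left" & df$ori2[df$sv_type == "DUP"] == "right"
  ok_ori[df$sv_type == "INV"] <-
    df$ori1[df$sv_type == "INV"] == df$ori2[df$sv_type == "INV"]
  if (any(!ok_ori)) {
    stop("orientations inconsistent with sv_type for: ",
         paste(df$sv_id[!ok_ori], collapse = ", "))
  }
  if (!is.null(contigs)) {
    check_contigs(df$chrom1, df$pos1, contigs)
    check_contigs(df$chrom2, df$pos2, contigs)
  }
  rownames(df) <- NULL
  df
}

empty_sv_table <- function() {
  sv_table(data.frame(
    sv_id = character(), sv_type = character(),
    chrom1 = character(), pos1 = integer(), ori1 = character(),
    chrom2 = character(), pos2 = integer(), ori2 = character(),
    median_mapq = integer(), normal_discordant = logical(),
    artifact_flag = logical(), support_reads = integer(),
    sample_id = character(), timepoint = character(),
    stringsAsFactors = FALSE
  ))
}

check_contigs <- function(chrom, pos, contigs) {
  unknown <- setdiff(unique(chrom), names(contigs))
  if (length(unknown) > 0) {
    stop("unknown contig(s) not in sequence dictionary: ",
         paste(unknown, collapse = ", "))
  }
  if (length(pos) > 0 && any(pos < 0 | pos >= contigs[chrom])) {
    stop("breakend position outside contig bounds")
  }
  invisible(TRUE)
}

#' Build and validate a CNV record table
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `cnv_type` ("gain"/"loss"), `normalized_rd`, `e_value`,
#'   `q0`, plus optional id/label columns.
#' @return validated data frame in canonical column order.
#' @export
cnv_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"cnv_id" %in% names(df)) df$cnv_id <- sprintf("cnv%05d", seq_len(nrow(df)))
  for (nm in c("sample_id", "timepoint")) {
    if (!nm %in% names(df)) df[[nm]] <- rep(NA_character_, nrow(df))
  }
  missing <- setdiff(cnv_table_columns, names(df))
  if (length(missing) > 0) {
    stop("CNV table is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[, cnv_table_columns, drop = FALSE]
  if (!all(df$cnv_type %in% c("gain", "loss"))) {
    stop("cnv_type must be 'gain' or 'loss'")
  }
  if (nrow(df) > 0 && any(df$q0 < 0 | df$q0 > 1)) stop("q0 must lie in [0, 1]")
  if (nrow(df) > 0 && any(df$normalized_rd < 0)) stop("normalized_rd must be >= 0")
  if (nrow(df) > 0 && any(df$end <= df$start)) stop("CNV intervals must satisfy end > start")
  rownames(df) <- NULL
  df
}

#' Build and validate an indel record table
#'
#' `kind` is derived from the allele length difference when absent; ref/alt
#' use the VCF anchor-base convention.
#' @param df data frame with `chrom`, `start` (0-based), `ref`, `alt`.
#' @return validated data frame in canonical column order.
#' @export
indel_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"indel_id" %in% names(df)) df$indel_id <- sprintf("ind%05d", seq_len(nrow(df)))
  for (nm in c("sample_id", "timepoint")) {
    if (!nm %in% names(df)) df[[nm]] <- rep(NA_character_, nrow(df))
  }
  if (!"end" %in% names(df)) df$end <- df$start + nchar(df$ref)
  inferred <- ifelse(nchar(df$alt) > nchar(df$ref), "insertion", "deletion")
  if (!"kind" %in% names(df)) df$kind <- inferred
  if (nrow(df) > 0 && any(nchar(df$ref) == nchar(df$alt))) {
    stop("indel records must have alleles of different lengths")
  }
  if (any(df$kind != inferred)) {
    stop("indel kind inconsistent with allele length difference")
  }
  df <- df[, indel_table_columns, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build an annotation track
#'
#' An annotation track is a data frame of labelled intervals: columns
#' `chrom`, `start`, `end` (0-based half-open) and `class` (non-empty label:
#' repeat family, fragile-site gene name, gene id, ...).
#' @param chrom,start,end,class vectors of equal length.
#' @return annotation track data frame.
#' @export
annotation_track <- function(chrom = character(), start = integer(),
                             end = integer(), class = character()) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), class = as.character(class),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$start < 0)) stop("track start must be >= 0")
    if (any(df$end <= df$start)) stop("track intervals must satisfy end > start")
    if (any(!nzchar(df$class))) stop("track class labels must be non-empty")
  }
  df
}

# 0-based half-open track -> GRanges (1-based closed)
track_to_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    class = track$class
  )
}
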