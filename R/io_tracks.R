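# Annotation-track and table formats: RepeatMasker .out, BED, CNVnator-style
# CNV tables, FASTA, GTF gene models, GMT gene sets.

#' Read a RepeatMasker .out annotation
#'
#' Whitespace-delimited RepeatMasker output with its 3 header lines; query
#' coordinates are 1-based inclusive and are shifted to the internal
#' 0-based half-open convention. The class label is the repClass/repFamily
#' string (column 11, e.g. `"LINE/L1"`).
#'
#' @param path .out file.
#' @return annotation track (see [annotation_track]).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) body <- lines[-(1:3)] else body <- character()
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(annotation_track())
  fields <- strsplit(trimws(body), "[[:space:]]+")
  n <- vapply(fields, length, 0L)
  if (any(n < 11)) {
    stop("RepeatMasker row ", which(n < 11)[1] + 3L, " has fewer than 11 fields")
  }
  qbegin <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
  qend <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7L)))
  if (anyNA(qbegin) || anyNA(qend)) {
    bad <- which(is.na(qbegin) | is.na(qend))[1]
    stop("non-numeric coordinate in RepeatMasker row ", bad + 3L)
  }
  annotation_track(
    chrom = vapply(fields, `[`, "", 5L),
    start = qbegin - 1L,
    end = qend,
    class = vapply(fields, `[`, "", 11L))
}

#' Write an annotation track in RepeatMasker .out layout
#' @param track annotation track; @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(track, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  rows <- sprintf("  225  10.0  0.0  0.0  %s %10d %10d (0) + %s %s 1 %d (0) %d",
                  track$chrom, track$start + 1L, track$end,
                  sub("/.*", "", track$class), track$class,
                  track$end - track$start, seq_len(nrow(track)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a BED3+1 file as an annotation track
#'
#' Column 4 (name) becomes the class label; BED is already 0-based
#' half-open so coordinates pass through unchanged.
#' @param path BED file.
#' @return annotation track.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) return(annotation_track())
  label <- if (!is.null(gr$name)) gr$name else rep("region", length(gr))
  annotation_track(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    class = label)
}

#' @rdname read_bed
#' @param track annotation track to write (class label -> BED name).
#' @export
write_bed <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start,
                     track$end, track$class), path)
  invisible(path)
}

#' Read a CNVnator-style CNV table
#'
#' Tab-delimited caller output: type (`deletion`/`duplication`), interval
#' `chr:start-end` (1-based inclusive), length, normalized read depth, four
#' e-values, q0. Types map to `loss`/`gain`; `e_value` is the first
#' e-value column.
#' @param path table path.
#' @param sample_id,timepoint labels attached to every record.
#' @return CNV table (see [cnv_table]).
#' @export
read_cnv_table <- function(path, sample_id = NA_character_,
                           timepoint = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0 || ncol(df) < 9) stop("expected >= 9 CNV table columns")
  names(df)[1:9] <- c("type", "coords", "length", "normalized_rd",
                      "e1", "e2", "e3", "e4", "q0")
  m <- regmatches(df$coords, regexec("^([^:]+):([0-9]+)-([0-9]+)$", df$coords))
  bad <- vapply(m, length, 0L) != 4
  if (any(bad)) stop("malformed CNV interval in row ", which(bad)[1])
  type_map <- c(deletion = "loss", duplication = "gain")
  if (!all(df$type %in% names(type_map))) {
    stop("unknown CNV type (expected deletion/duplication) in row ",
         which(!df$type %in% names(type_map))[1])
  }
  cnv_table(data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)) - 1L,
    end = as.integer(vapply(m, `[`, "", 4L)),
    cnv_type = unname(type_map[df$type]),
    normalized_rd = df$normalized_rd,
    e_value = df$e1,
    q0 = df$q0,
    sample_id = sample_id, timepoint = timepoint,
    stringsAsFactors = FALSE))
}

#' @rdname read_cnv_table
#' @param cnvs CNV table to write.
#' @export
write_cnv_table <- function(cnvs, path) {
  type_map <- c(loss = "deletion", gain = "duplication")
  lines <- sprintf("%s\t%s:%d-%d\t%d\t%.6g\t%.6g\t%.6g\t%.6g\t%.6g\t%.6g",
                   type_map[cnvs$cnv_type], cnvs$chrom, cnvs$start + 1L,
                   cnvs$end, cnvs$end - cnvs$start, cnvs$normalized_rd,
                   cnvs$e_value, cnvs$e_value, cnvs$e_value, cnvs$e_value,
                   cnvs$q0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a sequence store
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] (the package's sequence store).
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @param genome DNAStringSet to write.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Read GMT gene sets
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports exon and CDS features (single-transcript gene models) and
#' returns both a gene-body annotation track and the per-gene exon/CDS
#' structure needed for fusion frame analysis.
#'
#' @param path GTF2.2 file.
#' @return list with `track` (gene bodies labelled by gene id) and `models`
#'   (data frame: gene_id, chrom, strand, feature exon/CDS, start, end —
#'   0-based half-open).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  models <- data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  gene_models(models)
}

# assemble track + models list from a models data frame
gene_models <- function(models) {
  if (nrow(models) == 0) {
    return(list(track = annotation_track(), models = models))
  }
  bodies <- do.call(rbind, lapply(split(models, models$gene_id), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               class = g$gene_id[1], stringsAsFactors = FALSE)
  }))
  bodies <- bodies[order(bodies$chrom, bodies$start), ]
  list(track = annotation_track(bodies$chrom, bodies$start, bodies$end,
                                bodies$class),
       models = models[order(models$gene_id, models$start), ])
}

#' Write gene models as GTF
#' @param genes list as returned by [read_gene_models].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  m <- genes$models
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";', m$gene_id, m$gene_id)
  lines <- sprintf("%s\tsvdynamics\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   m$chrom, m$feature, m$start + 1L, m$end, m$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}
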