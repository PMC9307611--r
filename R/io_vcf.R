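# SV/indel VCF reading and writing. External VCFs are 1-based; internal
# breakend positions are 0-based (POS column = pos + 1 exactly once).

ct_code <- c(right = "3", left = "5")
ct_decode <- c(`3` = "right", `5` = "left")

sv_ct <- function(ori1, ori2) paste0(ct_code[ori1], "to", ct_code[ori2])

#' Read a structural-variant VCF into an SV table
#'
#' Accepts the two common SV dialects: symbolic ALTs (`<DEL>`, `<DUP>`,
#' `<INV>` with `END`; `<BND>`-style translocations carried on one line via
#' `CHR2`/`POS2`) and breakend bracket notation (two mated `SVTYPE=BND`
#' lines collapsed to one record via `MATEID`, with a fallback to the
#' ALT-encoded mate coordinate when `MATEID` is absent). Breakend
#' orientations come from the `CT` INFO field (`3to5` etc.) or from the
#' bracket form.
#'
#' @param path VCF file (plain or gzip).
#' @param dialect `"auto"` (default), `"bnd"` or `"symbolic"`; `auto`
#'   detects bracket ALTs per record.
#' @param discordant_key,artifact_key INFO flag keys populating the
#'   `normal_discordant` / `artifact_flag` columns (caller-dependent; the
#'   defaults match the synthetic writer).
#' @param contigs optional named contig-length vector; defaults to the
#'   `##contig` header lines. Unknown chromosomes are an error.
#' @param sample_id,timepoint labels attached to every record.
#' @return SV table (see [sv_table_columns]); mated BND lines collapse to
#'   one row with breakends in (chrom, pos) canonical order.
#' @export
read_sv_vcf <- function(path, dialect = c("auto", "bnd", "symbolic"),
                        discordant_key = "DISCORDANT",
                        artifact_key = "ARTIFACT",
                        contigs = NULL,
                        sample_id = NA_character_,
                        timepoint = NA_character_) {
  dialect <- match.arg(dialect)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(contigs)) contigs <- vcf_header_contigs(vcf@meta)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_sv_table())
  info <- fix$INFO
  svtype <- info_field(info, "SVTYPE")
  if (anyNA(svtype)) {
    stop("VCF record(s) without SVTYPE at line(s): ",
         paste(which(is.na(svtype)), collapse = ", "))
  }
  pos <- as.integer(fix$POS) - 1L
  end0 <- suppressWarnings(as.integer(info_field(info, "END"))) - 1L
  mapq <- suppressWarnings(as.integer(info_field(info, "MAPQ")))
  mapq[is.na(mapq)] <- 60L
  sr <- suppressWarnings(as.integer(info_field(info, "SR")))
  sr[is.na(sr)] <- 0L
  disc <- info_flag(info, discordant_key)
  arti <- info_flag(info, artifact_key)
  ct <- info_field(info, "CT")

  rows <- list()
  bnd_lines <- list()
  for (i in seq_len(nrow(fix))) {
    st <- svtype[i]
    if (st %in% c("DEL", "DUP", "INV")) {
      if (is.na(end0[i])) stop("symbolic ", st, " record without END (record ", i, ")")
      oris <- ct_orientations(ct[i], st)
      rows[[length(rows) + 1L]] <- data.frame(
        sv_id = fix$ID[i], sv_type = st,
        chrom1 = fix$CHROM[i], pos1 = pos[i], ori1 = oris[1],
        chrom2 = fix$CHROM[i], pos2 = end0[i], ori2 = oris[2],
        median_mapq = mapq[i], normal_discordant = disc[i],
        artifact_flag = arti[i], support_reads = sr[i],
        ord = i, stringsAsFactors = FALSE)
    } else if (st == "BND") {
      chr2 <- info_field(info[i], "CHR2")
      use_bracket <- dialect == "bnd" ||
        (dialect == "auto" && grepl("[][]", fix$ALT[i]))
      if (!use_bracket && !is.na(chr2)) {
        pos2 <- as.integer(info_field(info[i], "POS2")) - 1L
        oris <- ct_orientations(ct[i], "BND")
        rows[[length(rows) + 1L]] <- data.frame(
          sv_id = fix$ID[i], sv_type = "BND",
          chrom1 = fix$CHROM[i], pos1 = pos[i], ori1 = oris[1],
          chrom2 = chr2, pos2 = pos2, ori2 = oris[2],
          median_mapq = mapq[i], normal_discordant = disc[i],
          artifact_flag = arti[i], support_reads = sr[i],
          ord = i, stringsAsFactors = FALSE)
      } else {
        bnd_lines[[length(bnd_lines) + 1L]] <- list(
          i = i, id = fix$ID[i], chrom = fix$CHROM[i], pos = pos[i],
          alt = fix$ALT[i], mate = info_field(info[i], "MATEID"),
          mapq = mapq[i], disc = disc[i], arti = arti[i], sr = sr[i])
      }
    } else {
      stop("unsupported SVTYPE '", st, "' (record ", i, ")")
    }
  }
  if (length(bnd_lines) > 0) {
    rows <- c(rows, collapse_bnd_mates(bnd_lines))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else return(empty_sv_table())
  out <- out[order(out$ord), setdiff(names(out), "ord"), drop = FALSE]
  out$sample_id <- sample_id
  out$timepoint <- timepoint
  sv_table(out, contigs = contigs)
}

# bracket ALT "N[chr:pos[", "N]chr:pos]", "]chr:pos]N", "[chr:pos[N"
parse_bracket_alt <- function(alt) {
  m <- regmatches(alt, regexec("([\\]\\[])([^\\]\\[:]+):([0-9]+)([\\]\\[])",
                               alt, perl = TRUE))[[1]]
  if (length(m) == 0) return(NULL)
  ref_first <- !(startsWith(alt, "[") || startsWith(alt, "]"))
  list(
    ori_self = if (ref_first) "right" else "left",
    mate_chrom = m[3],
    mate_pos = as.integer(m[4]) - 1L,
    ori_mate = if (m[2] == "[") "left" else "right"
  )
}

collapse_bnd_mates <- function(lines) {
  ids <- vapply(lines, `[[`, "", "id")
  names(lines) <- ids
  done <- character()
  rows <- list()
  for (ln in lines) {
    if (ln$id %in% done) next
    pb <- parse_bracket_alt(ln$alt)
    if (is.null(pb)) {
      warning("BND record ", ln$id, " has no bracket ALT and no CHR2; skipped")
      done <- c(done, ln$id)
      next
    }
    mate <- NULL
    if (!is.na(ln$mate) && ln$mate %in% ids) {
      mate <- lines[[ln$mate]]
    } else {
      # fallback: locate the mate by its ALT-encoded coordinate
      for (cand in lines) {
        if (cand$id %in% c(done, ln$id)) next
        if (cand$chrom == pb$mate_chrom && cand$pos == pb$mate_pos) {
          mate <- cand
          break
        }
      }
    }
    if (is.null(mate) && is.na(ln$mate)) {
      # single-line bracket BND: mate coordinate taken from ALT alone
      mate <- list(id = ln$id, chrom = pb$mate_chrom, pos = pb$mate_pos)
    }
    if (is.null(mate)) {
      warning("BND record ", ln$id, " has no resolvable mate; skipped")
      done <- c(done, ln$id)
      next
    }
    done <- c(done, ln$id, mate$id)
    b1 <- list(chrom = ln$chrom, pos = ln$pos, ori = pb$ori_self)
    b2 <- list(chrom = pb$mate_chrom, pos = pb$mate_pos, ori = pb$ori_mate)
    if (b2$chrom < b1$chrom || (b2$chrom == b1$chrom && b2$pos < b1$pos)) {
      tmp <- b1; b1 <- b2; b2 <- tmp
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sv_id = sub("_[12]$", "", ln$id), sv_type = "BND",
      chrom1 = b1$chrom, pos1 = b1$pos, ori1 = b1$ori,
      chrom2 = b2$chrom, pos2 = b2$pos, ori2 = b2$ori,
      median_mapq = ln$mapq, normal_discordant = ln$disc,
      artifact_flag = ln$arti, support_reads = ln$sr,
      ord = ln$i, stringsAsFactors = FALSE)
  }
  rows
}

ct_orientations <- function(ct, sv_type) {
  if (!is.na(ct) && grepl("^[35]to[35]$", ct)) {
    parts <- strsplit(ct, "to")[[1]]
    return(unname(ct_decode[parts]))
  }
  switch(sv_type,
    DEL = c("right", "left"),
    DUP = c("left", "right"),
    INV = c("right", "right"),
    BND = c("right", "left"))
}

info_field <- function(info, key) {
  pat <- paste0("(^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(;|$)"), info)
}

vcf_header_contigs <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (length(lines) == 0) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', "\\1", lines)
  lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", lines)))
  if (anyNA(lens)) return(NULL)
  stats::setNames(lens, ids)
}

#' Write an SV table as a VCF
#'
#' Inverse of [read_sv_vcf]: symbolic ALTs for DEL/DUP/INV; BND records
#' either as two mated bracket-notation lines (`dialect = "bnd"`) or one
#' line with `CHR2`/`POS2` (`dialect = "symbolic"`). Orientations are
#' encoded in `CT`.
#'
#' @param svs SV table.
#' @param path output path.
#' @param contigs named contig-length vector for the `##contig` header.
#' @param dialect BND encoding.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, contigs = NULL,
                         dialect = c("bnd", "symbolic")) {
  dialect <- match.arg(dialect)
  svs <- sv_table(svs, contigs = contigs)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svdynamics",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based)">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Mate chromosome">',
    '##INFO=<ID=POS2,Number=1,Type=Integer,Description="Mate position (1-based)">',
    '##INFO=<ID=CT,Number=1,Type=String,Description="Breakend orientation (3=retained left, 5=retained right)">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
    '##INFO=<ID=MAPQ,Number=1,Type=Integer,Description="Median mapping quality of supporting reads">',
    '##INFO=<ID=SR,Number=1,Type=Integer,Description="Supporting read count">',
    '##INFO=<ID=DISCORDANT,Number=0,Type=Flag,Description="Discordant reads in paired normal">',
    '##INFO=<ID=ARTIFACT,Number=0,Type=Flag,Description="DNA library artifact">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character()
  for (i in seq_len(nrow(svs))) {
    r <- svs[i, ]
    flags <- paste0(
      if (r$normal_discordant) ";DISCORDANT" else "",
      if (r$artifact_flag) ";ARTIFACT" else "")
    common <- sprintf("CT=%s;MAPQ=%d;SR=%d%s",
                      sv_ct(r$ori1, r$ori2), r$median_mapq, r$support_reads, flags)
    if (r$sv_type %in% c("DEL", "DUP", "INV")) {
      info <- sprintf("SVTYPE=%s;END=%d;%s", r$sv_type, r$pos2 + 1L, common)
      lines <- c(lines, sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                                r$chrom1, r$pos1 + 1L, r$sv_id, r$sv_type, info))
    } else if (dialect == "symbolic") {
      info <- sprintf("SVTYPE=BND;CHR2=%s;POS2=%d;%s", r$chrom2, r$pos2 + 1L, common)
      lines <- c(lines, sprintf("%s\t%d\t%s\tN\t<BND>\t.\tPASS\t%s",
                                r$chrom1, r$pos1 + 1L, r$sv_id, info))
    } else {
      id1 <- paste0(r$sv_id, "_1"); id2 <- paste0(r$sv_id, "_2")
      alt1 <- bracket_alt(r$ori1, r$chrom2, r$pos2 + 1L, r$ori2)
      alt2 <- bracket_alt(r$ori2, r$chrom1, r$pos1 + 1L, r$ori1)
      base <- sprintf("CT=%s;MAPQ=%d;SR=%d%s",
                      sv_ct(r$ori1, r$ori2), r$median_mapq, r$support_reads, flags)
      lines <- c(lines,
        sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;%s",
                r$chrom1, r$pos1 + 1L, id1, alt1, id2, base),
        sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;%s",
                r$chrom2, r$pos2 + 1L, id2, alt2, id1, base))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# bracket ALT for a breakend with orientation ori_self, mate at chrom:pos1b
bracket_alt <- function(ori_self, mate_chrom, mate_pos1b, ori_mate) {
  br <- if (ori_mate == "left") "[" else "]"
  coord <- paste0(br, mate_chrom, ":", mate_pos1b, br)
  if (ori_self == "right") paste0("N", coord) else paste0(coord, "N")
}

#' Read an indel VCF
#'
#' Plain REF/ALT records with alleles of unequal length (VCF anchor-base
#' convention); `kind` derives from the length difference.
#' @inheritParams read_sv_vcf
#' @return indel table (columns [cnv_table_columns]-style; see
#'   [indel_table]).
#' @export
read_indel_vcf <- function(path, contigs = NULL,
                           sample_id = NA_character_,
                           timepoint = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(contigs)) contigs <- vcf_header_contigs(vcf@meta)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(indel_table(data.frame(chrom = character(), start = integer(),
                                  ref = character(), alt = character(),
                                  stringsAsFactors = FALSE)))
  }
  start <- as.integer(fix$POS) - 1L
  if (!is.null(contigs)) check_contigs(fix$CHROM, start, contigs)
  indel_table(data.frame(
    indel_id = fix$ID, chrom = fix$CHROM, start = start,
    ref = fix$REF, alt = fix$ALT,
    sample_id = sample_id, timepoint = timepoint,
    stringsAsFactors = FALSE))
}

#' Write an indel table as a VCF
#' @param indels indel table; @param path output path;
#' @param contigs named contig-length vector for the header.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(indels, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svdynamics",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                   indels$chrom, indels$start + 1L, indels$indel_id,
                   indels$ref, indels$alt)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read/write SV tables as 10+ column BEDPE
#'
#' Columns 1-10 follow the BEDPE convention (0-based half-open, strand `+`
#' for a right-facing breakend); extra columns carry type and quality
#' fields.
#' @param path file path.
#' @param sample_id,timepoint labels attached to every record.
#' @return SV table.
#' @export
read_bedpe <- function(path, sample_id = NA_character_,
                       timepoint = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 14) stop("expected >= 14 BEDPE columns, got ", ncol(df))
  names(df)[1:14] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                       "sv_id", "score", "strand1", "strand2", "sv_type",
                       "median_mapq", "normal_discordant", "artifact_flag")
  sv_table(data.frame(
    sv_id = df$sv_id, sv_type = df$sv_type,
    chrom1 = df$chrom1, pos1 = df$start1,
    ori1 = ifelse(df$strand1 == "+", "right", "left"),
    chrom2 = df$chrom2, pos2 = df$start2,
    ori2 = ifelse(df$strand2 == "+", "right", "left"),
    median_mapq = df$median_mapq,
    normal_discordant = as.logical(df$normal_discordant),
    artifact_flag = as.logical(df$artifact_flag),
    support_reads = df$score,
    sample_id = sample_id, timepoint = timepoint,
    stringsAsFactors = FALSE))
}

#' @rdname read_bedpe
#' @param svs SV table to write.
#' @export
write_bedpe <- function(svs, path) {
  svs <- sv_table(svs)
  hdr <- paste0("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\t",
                "strand1\tstrand2\tsv_type\tmedian_mapq\tnormal_discordant\t",
                "artifact_flag\tsvdynamics=", utils::packageVersion("svdynamics"))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%d\t%s\t%s",
                   svs$chrom1, svs$pos1, svs$pos1 + 1L,
                   svs$chrom2, svs$pos2, svs$pos2 + 1L,
                   svs$sv_id, svs$support_reads,
                   ifelse(svs$ori1 == "right", "+", "-"),
                   ifelse(svs$ori2 == "right", "+", "-"),
                   svs$sv_type, svs$median_mapq,
                   svs$normal_discordant, svs$artifact_flag)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
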