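# Junction microhomology from reference flanks.
#
# A junction joins two oriented breakends; the derived sequence around it is
# seg1 ++ seg2, each segment read in derived-chromosome orientation
# (reverse-complemented when the retained side lies 3' of the breakend).
# Microhomology is the total breakpoint-placement ambiguity: the number of
# positions the junction can slide while yielding an identical derived
# sequence. It decomposes into the longest common suffix of the two
# sequences immediately upstream of the junction (the retained left flank
# vs the mate's continuation) plus the longest common prefix of the two
# sequences immediately downstream — the HOMLEN convention of SV callers.

#' Default microhomology-to-pathway bounds
#'
#' Repair-pathway classes by junction microhomology length: 1-5 bp
#' non-homologous end joining (NHEJ), 6-25 bp microhomology-mediated end
#' joining (MMEJ), above 25 bp single-strand annealing (SSA); 0 bp is a
#' blunt junction outside all three classes.
#' @param nhej,mmej inclusive `[lo, hi]` length ranges.
#' @return a `pathway_bounds` list.
#' @export
pathway_bounds <- function(nhej = c(1L, 5L), mmej = c(6L, 25L)) {
  if (nhej[1] != 1L || nhej[2] + 1L != mmej[1]) {
    stop("pathway bounds must be contiguous from 1 bp")
  }
  structure(list(nhej = as.integer(nhej), mmej = as.integer(mmej),
                 ssa_min = as.integer(mmej[2] + 1L)),
            class = "pathway_bounds")
}

# reference slice, 0-based half-open, clipped at contig edges
seq_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("unknown contig '", chrom, "' in reference")
  }
  len <- length(genome[[chrom]])
  s <- max(start, 0L)
  e <- min(end, len)
  clipped <- (s != start) || (e != end)
  seq <- if (e > s) {
    as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e))
  } else ""
  list(seq = seq, clipped = clipped)
}

revcomp_chr <- function(x) {
  if (nchar(x) == 0) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# the four junction-orientation sequences around one junction:
#   L: retained flank entering the junction (ends at it)
#   A: reference continuation past the junction on side 1
#   B: reference sequence immediately preceding the junction on side 2
#   R: retained flank leaving the junction (starts at it)
junction_context <- function(genome, chrom1, pos1, ori1,
                             chrom2, pos2, ori2, flank) {
  p1 <- as.integer(pos1); p2 <- as.integer(pos2); f <- as.integer(flank)
  if (ori1 == "right") {
    L <- seq_slice(genome, chrom1, p1 - f + 1L, p1 + 1L)
    A <- seq_slice(genome, chrom1, p1 + 1L, p1 + f + 1L)
  } else {
    L <- seq_slice(genome, chrom1, p1, p1 + f)
    A <- seq_slice(genome, chrom1, p1 - f, p1)
    L$seq <- revcomp_chr(L$seq); A$seq <- revcomp_chr(A$seq)
  }
  if (ori2 == "left") {
    R <- seq_slice(genome, chrom2, p2, p2 + f)
    B <- seq_slice(genome, chrom2, p2 - f, p2)
  } else {
    R <- seq_slice(genome, chrom2, p2 - f + 1L, p2 + 1L)
    B <- seq_slice(genome, chrom2, p2 + 1L, p2 + f + 1L)
    R$seq <- revcomp_chr(R$seq); B$seq <- revcomp_chr(B$seq)
  }
  list(L = L, A = A, B = B, R = R,
       clipped = L$clipped || A$clipped || B$clipped || R$clipped)
}

# longest common prefix / suffix with case folding; N never matches
match_bases <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  ok <- toupper(a[seq_len(n)]) == toupper(b[seq_len(n)]) &
    toupper(a[seq_len(n)]) != "N"
  if (all(ok)) n else which(!ok)[1] - 1L
}

lcp_len <- function(x, y) {
  match_bases(strsplit(x, "")[[1]], strsplit(y, "")[[1]])
}

lcs_len <- function(x, y) {
  match_bases(rev(strsplit(x, "")[[1]]), rev(strsplit(y, "")[[1]]))
}

#' Extract the derived-chromosome flanks of an SV junction
#'
#' Returns the `flank` bases entering the junction (ending at breakend 1)
#' and leaving it (starting at breakend 2), both in derived-chromosome
#' reading order: a segment that joins the junction from the reverse strand
#' is reverse-complemented. Flanks shorter than `flank` are flagged as
#' clipped at a contig edge.
#'
#' @param genome sequence store ([Biostrings::DNAStringSet]).
#' @param svs SV table (one or more rows).
#' @param flank flank length in bp (default 50).
#' @return data frame: sv_id, left_flank, right_flank, clipped.
#' @export
extract_flanks <- function(genome, svs, flank = 50L) {
  svs <- sv_table(svs)
  out <- lapply(seq_len(nrow(svs)), function(i) {
    r <- svs[i, ]
    cx <- junction_context(genome, r$chrom1, r$pos1, r$ori1,
                           r$chrom2, r$pos2, r$ori2, flank)
    data.frame(sv_id = r$sv_id, left_flank = cx$L$seq,
               right_flank = cx$R$seq,
               clipped = cx$L$clipped || cx$R$clipped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compute junction microhomology and repair-pathway class
#'
#' For each SV the microhomology length is the breakpoint-placement
#' ambiguity of the junction computed from `flank`-bp reference windows:
#' the longest common suffix of the sequences immediately upstream of the
#' two breakends (in junction orientation) plus the longest common prefix
#' of the sequences immediately downstream, capped at `flank`
#' (`mode = "total"`); `mode = "upstream"` reports the suffix component
#' only. Comparison is case-insensitive and `N` never matches. A record
#' with a non-empty `junction_insert` column (non-templated inserted
#' sequence) is forced to 0 bp, since templated homology cannot span an
#' insertion.
#'
#' @inheritParams extract_flanks
#' @param bounds [pathway_bounds()] classification bounds.
#' @param mode `"total"` (placement ambiguity, HOMLEN convention) or
#'   `"upstream"`.
#' @return data frame: sv_id, chrom1, pos1, chrom2, pos2, mh_length,
#'   mh_sequence, pathway, left_flank, right_flank, clipped.
#' @export
junction_homology <- function(genome, svs, flank = 50L,
                              bounds = pathway_bounds(),
                              mode = c("total", "upstream")) {
  mode <- match.arg(mode)
  inserts <- if ("junction_insert" %in% names(svs)) as.character(svs$junction_insert)
             else rep("", nrow(svs))
  inserts[is.na(inserts)] <- ""
  svs <- sv_table(svs)
  degen <- svs$chrom1 == svs$chrom2 & svs$pos1 == svs$pos2
  if (any(degen)) {
    stop("degenerate junction with identical breakends: ",
         paste(svs$sv_id[degen], collapse = ", "))
  }
  out <- lapply(seq_len(nrow(svs)), function(i) {
    r <- svs[i, ]
    cx <- junction_context(genome, r$chrom1, r$pos1, r$ori1,
                           r$chrom2, r$pos2, r$ori2, flank)
    if (nzchar(inserts[i])) {
      m <- 0L; k <- 0L
    } else {
      m <- lcs_len(cx$L$seq, cx$B$seq)
      k <- if (mode == "total") lcp_len(cx$A$seq, cx$R$seq) else 0L
    }
    mh <- min(m + k, as.integer(flank))
    if (m + k > flank) {           # cap: trim the downstream component
      k <- as.integer(flank) - m
    }
    tract <- paste0(
      if (m > 0) substr(cx$L$seq, nchar(cx$L$seq) - m + 1L, nchar(cx$L$seq)) else "",
      if (k > 0) substr(cx$R$seq, 1L, k) else "")
    data.frame(sv_id = r$sv_id, chrom1 = r$chrom1, pos1 = r$pos1,
               ori1 = r$ori1, chrom2 = r$chrom2, pos2 = r$pos2,
               ori2 = r$ori2, mh_length = mh, mh_sequence = tract,
               pathway = classify_pathway(mh, bounds),
               left_flank = cx$L$seq, right_flank = cx$R$seq,
               clipped = cx$clipped, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify repair pathway from microhomology length
#'
#' Maps a junction microhomology length to the repair-pathway class it
#' signals: 0 bp blunt, 1-5 bp NHEJ, 6-25 bp MMEJ, >25 bp SSA (defaults;
#' see [pathway_bounds()]).
#' @param mh_length integer vector of lengths (bp, >= 0).
#' @param bounds [pathway_bounds()].
#' @return character vector in {blunt, NHEJ, MMEJ, SSA}.
#' @export
classify_pathway <- function(mh_length, bounds = pathway_bounds()) {
  mh_length <- as.integer(mh_length)
  if (any(is.na(mh_length)) || any(mh_length < 0)) {
    stop("microhomology length must be a nonnegative integer")
  }
  ifelse(mh_length == 0L, "blunt",
    ifelse(mh_length <= bounds$nhej[2], "NHEJ",
      ifelse(mh_length <= bounds$mmej[2], "MMEJ", "SSA")))
}

#' Summarize repair-pathway counts over a cohort
#'
#' Counts junctions per pathway class after removing duplicate junctions
#' (identical breakend pairs, as when the same event recurs across
#' timepoints). Blunt junctions are tallied but excluded from the
#' non-blunt repair-event total, since the microhomology classes start at
#' 1 bp.
#' @param homologies output of [junction_homology] (possibly concatenated
#'   across samples).
#' @return list with `counts` (named: blunt, NHEJ, MMEJ, SSA), `total`
#'   (deduplicated junction count) and `non_blunt` (NHEJ+MMEJ+SSA).
#' @export
summarize_pathways <- function(homologies) {
  key <- paste(homologies$chrom1, homologies$pos1, homologies$ori1,
               homologies$chrom2, homologies$pos2, homologies$ori2)
  uniq <- homologies[!duplicated(key), , drop = FALSE]
  classes <- c("blunt", "NHEJ", "MMEJ", "SSA")
  counts <- vapply(classes, function(cl) sum(uniq$pathway == cl), 0L)
  list(counts = counts, total = nrow(uniq),
       non_blunt = sum(counts[c("NHEJ", "MMEJ", "SSA")]))
}
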