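# Breakpoint annotation: repeat classes, fragile sites, gene disruption,
# fusion candidates and reading frame, and gene-set over-representation.

#' Expand an SV table to a breakend table
#'
#' One row per breakend (two per SV), keeping the junction orientation.
#' @param svs SV table.
#' @return data frame: sv_id, side (1/2), chrom, pos, ori.
#' @export
breakend_table <- function(svs) {
  svs <- sv_table(svs)
  rbind(
    data.frame(sv_id = svs$sv_id, side = 1L, chrom = svs$chrom1,
               pos = svs$pos1, ori = svs$ori1, stringsAsFactors = FALSE),
    data.frame(sv_id = svs$sv_id, side = 2L, chrom = svs$chrom2,
               pos = svs$pos2, ori = svs$ori2, stringsAsFactors = FALSE))
}

# give two GRanges a shared seqlevel set so overlaps never warn
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

breakend_windows <- function(breakends, flank) {
  GenomicRanges::GRanges(
    seqnames = breakends$chrom,
    ranges = IRanges::IRanges(start = pmax(breakends$pos - flank, 0L) + 1L,
                              end = breakends$pos + flank + 1L))
}

#' Annotate breakends with repeat classes
#'
#' A breakend is "in repeat" iff its `flank`-bp window on either side
#' (i.e. `[pos - flank, pos + flank]`) intersects a repeat interval; its
#' class is that of the interval with the largest overlap, ties broken by
#' the lexicographically smallest class label.
#'
#' @param breakends breakend table ([breakend_table]) or SV table (expanded
#'   automatically).
#' @param repeats repeat annotation track.
#' @param flank window half-width in bp (default 50, the junction flank
#'   convention).
#' @return list with `breakends` (input + `repeat_class`, `NA` when
#'   outside repeats) and `fraction` (in-repeat breakends / all breakends).
#' @export
annotate_repeats <- function(breakends, repeats, flank = 50L) {
  if ("sv_type" %in% names(breakends)) breakends <- breakend_table(breakends)
  cls <- rep(NA_character_, nrow(breakends))
  if (nrow(breakends) > 0 && nrow(repeats) > 0) {
    al <- align_seqlevels(breakend_windows(breakends, flank),
                          track_to_granges(repeats))
    win <- al$a; rep_gr <- al$b
    hits <- GenomicRanges::findOverlaps(win, rep_gr)
    if (length(hits) > 0) {
      ov <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                      rep_gr[S4Vectors::subjectHits(hits)])
      cand <- data.frame(i = S4Vectors::queryHits(hits),
                         class = rep_gr$class[S4Vectors::subjectHits(hits)],
                         width = GenomicRanges::width(ov),
                         stringsAsFactors = FALSE)
      # largest overlap wins; ties -> lexicographically smallest class
      cand <- cand[order(cand$i, -cand$width, cand$class), ]
      cand <- cand[!duplicated(cand$i), ]
      cls[cand$i] <- cand$class
    }
  }
  breakends$repeat_class <- cls
  frac <- if (nrow(breakends) == 0) NA_real_ else mean(!is.na(cls))
  list(breakends = breakends, fraction = frac)
}

#' Exact binomial test for repeat enrichment at breakpoints
#'
#' Upper-tail exact binomial probability of observing at least `k` in-repeat
#' breakpoints out of `n` when the genome-wide repeat fraction is
#' `background_fraction`: P(X >= k | n, background). The underlying
#' comparison (observed repeat overlap vs genomic repeat content) is
#' reported descriptively in the source study; the formal test is this
#' package's extension.
#' @param k_in_repeat,n_total counts, 0 <= k <= n, n > 0.
#' @param background_fraction genomic repeat fraction in (0, 1).
#' @return one-sided p-value.
#' @export
repeat_enrichment_test <- function(k_in_repeat, n_total, background_fraction) {
  if (n_total <= 0) stop("n_total must be positive")
  if (k_in_repeat < 0 || k_in_repeat > n_total) stop("k must lie in [0, n]")
  if (background_fraction <= 0 || background_fraction >= 1) {
    stop("background_fraction must lie in (0, 1)")
  }
  stats::pbinom(k_in_repeat - 1, n_total, background_fraction,
                lower.tail = FALSE)
}

#' Intersect SV breakpoints with fragile-site intervals
#'
#' Reports every (SV, fragile-site gene) pair whose `flank`-bp breakend
#' window intersects a fragile-site interval, deduplicated per pair.
#' @param svs SV table.
#' @param fragile_track annotation track labelled with fragile-site gene
#'   names.
#' @param flank window half-width (default 50).
#' @return data frame: sv_id, fragile_gene.
#' @export
intersect_fragile_sites <- function(svs, fragile_track, flank = 50L) {
  be <- breakend_table(svs)
  empty <- data.frame(sv_id = character(), fragile_gene = character(),
                      stringsAsFactors = FALSE)
  if (nrow(be) == 0 || nrow(fragile_track) == 0) return(empty)
  al <- align_seqlevels(breakend_windows(be, flank),
                        track_to_granges(fragile_track))
  win <- al$a; fr <- al$b
  hits <- GenomicRanges::findOverlaps(win, fr)
  if (length(hits) == 0) return(empty)
  out <- data.frame(sv_id = be$sv_id[S4Vectors::queryHits(hits)],
                    fragile_gene = fr$class[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$sv_id, out$fragile_gene)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate gene disruption and fusion candidates
#'
#' A gene is disrupted when an SV breakend falls in its body or, for
#' DEL/DUP/INV, when the rearranged span intersects it. A junction whose
#' two breakends fall in two distinct genes yields a fusion candidate when
#' a consistent donor/acceptor assignment exists: the 5' partner is the
#' gene whose coding strand reads into the junction (a "+"-strand gene at a
#' right-facing breakend, a "-"-strand gene at a left-facing one), and the
#' 3' partner the gene whose strand reads away from it.
#'
#' @param svs SV table.
#' @param genes gene models ([read_gene_models] list).
#' @return list with `disrupted` (sv_id, gene_id) and `fusions` (sv_id,
#'   five_prime, three_prime, frame).
#' @export
annotate_genes <- function(svs, genes) {
  svs <- sv_table(svs)
  track <- genes$track
  empty_dis <- data.frame(sv_id = character(), gene_id = character(),
                          stringsAsFactors = FALSE)
  empty_fus <- data.frame(sv_id = character(), five_prime = character(),
                          three_prime = character(), frame = character(),
                          stringsAsFactors = FALSE)
  if (nrow(svs) == 0 || nrow(track) == 0) {
    return(list(disrupted = empty_dis, fusions = empty_fus))
  }
  # disruption: breakend points plus intra-chromosomal spans
  be <- breakend_table(svs)
  al <- align_seqlevels(
    GenomicRanges::GRanges(be$chrom,
                           IRanges::IRanges(be$pos + 1L, be$pos + 1L)),
    track_to_granges(track))
  pt <- al$a; gene_gr <- al$b
  hits <- GenomicRanges::findOverlaps(pt, gene_gr)
  dis <- data.frame(sv_id = be$sv_id[S4Vectors::queryHits(hits)],
                    gene_id = gene_gr$class[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  intra <- svs[svs$sv_type %in% c("DEL", "DUP", "INV"), , drop = FALSE]
  if (nrow(intra) > 0) {
    span <- GenomicRanges::GRanges(intra$chrom1,
                                   IRanges::IRanges(intra$pos1 + 1L, intra$pos2 + 1L))
    GenomeInfoDb::seqlevels(span) <- union(GenomeInfoDb::seqlevels(span),
                                           GenomeInfoDb::seqlevels(gene_gr))
    GenomeInfoDb::seqlevels(gene_gr) <- GenomeInfoDb::seqlevels(span)
    sh <- GenomicRanges::findOverlaps(span, gene_gr)
    dis <- rbind(dis, data.frame(
      sv_id = intra$sv_id[S4Vectors::queryHits(sh)],
      gene_id = gene_gr$class[S4Vectors::subjectHits(sh)],
      stringsAsFactors = FALSE))
  }
  dis <- dis[!duplicated(paste(dis$sv_id, dis$gene_id)), , drop = FALSE]
  dis <- dis[order(dis$sv_id, dis$gene_id), , drop = FALSE]
  rownames(dis) <- NULL

  # fusion candidates
  strand_of <- gene_strands(genes$models)
  fus <- empty_fus
  bhits <- GenomicRanges::findOverlaps(pt, gene_gr)
  hit_gene <- rep(NA_character_, nrow(be))
  hit_gene[S4Vectors::queryHits(bhits)] <- gene_gr$class[S4Vectors::subjectHits(bhits)]
  n <- nrow(svs)
  g1 <- hit_gene[seq_len(n)]
  g2 <- hit_gene[n + seq_len(n)]
  for (i in which(!is.na(g1) & !is.na(g2) & g1 != g2)) {
    b1 <- list(chrom = svs$chrom1[i], pos = svs$pos1[i], ori = svs$ori1[i])
    b2 <- list(chrom = svs$chrom2[i], pos = svs$pos2[i], ori = svs$ori2[i])
    asgn <- NULL
    if (reads_into_junction(b1$ori, strand_of[[g1[i]]]) &&
        reads_away_from_junction(b2$ori, strand_of[[g2[i]]])) {
      asgn <- list(fp = g1[i], fb = b1, tp = g2[i], tb = b2)
    } else if (reads_into_junction(b2$ori, strand_of[[g2[i]]]) &&
               reads_away_from_junction(b1$ori, strand_of[[g1[i]]])) {
      asgn <- list(fp = g2[i], fb = b2, tp = g1[i], tb = b1)
    }
    if (!is.null(asgn)) {
      frame <- fusion_frame(genes, asgn$fp, asgn$fb, asgn$tp, asgn$tb)
      fus <- rbind(fus, data.frame(
        sv_id = svs$sv_id[i], five_prime = asgn$fp, three_prime = asgn$tp,
        frame = frame, stringsAsFactors = FALSE))
    }
  }
  rownames(fus) <- NULL
  list(disrupted = dis, fusions = fus)
}

gene_strands <- function(models) {
  s <- models$strand[!duplicated(models$gene_id)]
  names(s) <- models$gene_id[!duplicated(models$gene_id)]
  as.list(s)
}

# does a gene's coding strand enter the junction 5'->3' at this breakend?
reads_into_junction <- function(ori, strand) {
  (ori == "right" && strand == "+") || (ori == "left" && strand == "-")
}

reads_away_from_junction <- function(ori, strand) {
  (ori == "left" && strand == "+") || (ori == "right" && strand == "-")
}

# coding bases 5' of the junction cut in transcript orientation.
# retained_left: is the retained sequence at this breakend the reference
# left flank (ori "right")? the cut then falls after pos, else before it.
cds_bases_upstream <- function(models, gene_id, pos, ori) {
  cds <- models[models$gene_id == gene_id & models$feature == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(NULL)
  strand <- cds$strand[1]
  cut <- if (ori == "right") pos + 1L else pos  # 0-based cut offset
  if (cut < min(cds$start) || cut > max(cds$end)) return(NULL)  # outside CDS span
  if (strand == "+") {
    sum(pmax(0L, pmin(cds$end, cut) - cds$start))
  } else {
    sum(pmax(0L, cds$end - pmax(cds$start, cut)))
  }
}

#' Reading frame of a candidate gene fusion
#'
#' Classifies a donor/acceptor junction as `in-frame`, `out-of-frame`, or
#' `noncoding`. Noncoding when either gene lacks a CDS or a breakend cut
#' falls outside the CDS span. Otherwise the CDS phase at each breakend is
#' the number of coding bases 5' of the junction cut (in transcript
#' orientation) mod 3; the fusion is in frame iff the donor and acceptor
#' phases agree, i.e. donor phase plus the acceptor's remaining phase is
#' 0 mod 3.
#'
#' @param genes gene models list.
#' @param donor_gene,acceptor_gene gene ids (5' and 3' partner).
#' @param donor_bnd,acceptor_bnd breakends as `list(chrom, pos, ori)`.
#' @return one of `"in-frame"`, `"out-of-frame"`, `"noncoding"`.
#' @export
fusion_frame <- function(genes, donor_gene, donor_bnd,
                         acceptor_gene, acceptor_bnd) {
  m <- genes$models
  d <- cds_bases_upstream(m, donor_gene, donor_bnd$pos, donor_bnd$ori)
  a <- cds_bases_upstream(m, acceptor_gene, acceptor_bnd$pos, acceptor_bnd$ori)
  if (is.null(d) || is.null(a)) return("noncoding")
  if ((d - a) %% 3 == 0) "in-frame" else "out-of-frame"
}

#' Hypergeometric over-representation test of gene sets
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the realized overlap between the hit genes and the set, drawn
#' from the gene universe. Raw p-values by default to mirror a plain
#' p < alpha call; Benjamini-Hochberg adjustment optional.
#'
#' @param hit_genes character vector, must be a subset of `universe`.
#' @param gene_sets named list of character vectors (intersected with the
#'   universe).
#' @param universe character vector of all testable genes.
#' @param alpha significance cutoff (default 0.05).
#' @param adjust apply Benjamini-Hochberg across sets (default `FALSE`).
#' @return data frame: set, set_size, hits, overlap, p, significant.
#' @export
ora_test <- function(hit_genes, gene_sets, universe, alpha = 0.05,
                     adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe)) {
    stop("hit genes outside the universe: ",
         paste(utils::head(setdiff(hit_genes, universe)), collapse = ", "))
  }
  N <- length(universe)
  K <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    k <- length(intersect(hit_genes, set))
    p <- stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, hits = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- (if (adjust) out$p_adj else out$p) < alpha
  out
}
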