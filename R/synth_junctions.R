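# Breakpoint placement and microhomology implantation.
#
# Placement honors four constraints: designed hotspot clusters get
# deterministic, evenly spaced breakends inside the central 70% of their
# spans; background breakends avoid cluster spans plus a chaining margin;
# an exact quota of breakends lands inside repeat intervals (the remainder
# at least one flank-window away from any repeat); and every breakend
# reserves a (flank + 2)-bp edit window on each side so that sequence
# edits of different junctions never interact.
#
# Microhomology is implanted by editing the reference: the designed tract
# is copied so the two junction sides share exactly m bases upstream and k
# bases downstream of the breakpoint (m + k = designed length), and the
# flanking base on each side is forced to mismatch, making the designed
# length exact by construction rather than in expectation.

# margin around a breakend whose sequence belongs to one junction only
edit_margin <- function(flank) flank + 2L

place_in_interval <- function(start, end) {
  if (end <= start) return(NA_integer_)
  start + sample.int(end - start, 1) - 1L
}

# candidate pools per chromosome: inside repeats / clear of repeats
build_pools <- function(sizes, repeats, flank) {
  m <- edit_margin(flank)
  clearance <- flank + 5L  # window [pos-flank, pos+flank] must miss repeats
  pools <- list()
  for (chrom in names(sizes)) {
    len <- sizes[[chrom]]
    rep_iv <- repeats[repeats$chrom == chrom, , drop = FALSE]
    rep_iv <- rep_iv[order(rep_iv$start), , drop = FALSE]
    # inside repeats, away from their edges enough to keep pos in-repeat
    inside <- rep_iv[rep_iv$end - rep_iv$start > 2, , drop = FALSE]
    gaps_start <- c(0L, inside$end)[seq_len(nrow(inside) + 1L)]
    if (nrow(rep_iv) > 0) {
      gs <- c(0L, rep_iv$end)
      ge <- c(rep_iv$start, len)
    } else {
      gs <- 0L
      ge <- len
    }
    clear <- data.frame(start = gs + clearance, end = ge - clearance)
    clear <- clear[clear$end > clear$start, , drop = FALSE]
    clear$start <- pmax(clear$start, m)
    clear$end <- pmin(clear$end, len - m)
    clear <- clear[clear$end > clear$start, , drop = FALSE]
    rep_in <- data.frame(start = pmax(rep_iv$start + 1L, m),
                         end = pmin(rep_iv$end - 1L, len - m))
    rep_in <- rep_in[rep_in$end > rep_in$start, , drop = FALSE]
    pools[[chrom]] <- list(repeat_iv = rep_in, clear_iv = clear, len = len)
  }
  pools
}

sample_pool_position <- function(pool, in_repeat) {
  iv <- if (in_repeat) pool$repeat_iv else pool$clear_iv
  if (nrow(iv) == 0) return(NA_integer_)
  w <- iv$end - iv$start
  i <- sample.int(nrow(iv), 1, prob = w)
  place_in_interval(iv$start[i], iv$end[i])
}

new_occupancy <- function(chroms) {
  stats::setNames(lapply(chroms, function(x) {
    data.frame(start = integer(), end = integer())
  }), chroms)
}

occupied <- function(occ, chrom, start, end) {
  iv <- occ[[chrom]]
  nrow(iv) > 0 && any(iv$start < end & start < iv$end)
}

reserve <- function(occ, chrom, start, end) {
  occ[[chrom]] <- rbind(occ[[chrom]], data.frame(start = start, end = end))
  occ
}

# is pos within `clearance` of a repeat interval on this chromosome?
near_repeat <- function(repeats, chrom, pos, clearance) {
  r <- repeats[repeats$chrom == chrom, , drop = FALSE]
  nrow(r) > 0 && any(r$start - clearance <= pos & pos < r$end + clearance)
}

#' Place SV breakpoints for a synthetic cohort
#'
#' Realizes the cluster design, the repeat-bias quota and the edit-window
#' spacing (see the module header) and assigns each event a type, designed
#' microhomology length (drawn from `config$mh_distribution` and split at
#' random between the upstream and downstream junction side) and cluster
#' membership. Clustered breakends are placed first and their realized
#' repeat overlap counted; the exact remaining quota
#' `round(repeat_bias * n_breakends)` is then imposed on the unconstrained
#' breakends.
#'
#' @param tracks output of [generate_genome] (sequence not consulted).
#' @param config [sim_config()].
#' @return truth data frame: event_id, sv_type, chrom1, pos1, ori1,
#'   chrom2, pos2, ori2, mh_len, mh_up (upstream split), cluster_id,
#'   in_repeat1, in_repeat2.
#' @export
place_breakpoints <- function(tracks, config) {
  sizes <- config$genome_sizes
  flank <- config$flank
  m <- edit_margin(flank)
  repeats <- tracks$repeats
  pools <- build_pools(sizes, repeats, flank)
  occ <- new_occupancy(names(sizes))
  clearance <- flank + 5L

  n_clustered <- sum(vapply(config$cluster_spec, `[[`, 0, "n_events"))
  n_bg <- config$n_sv - n_clustered
  rows <- list()
  ei <- 0L

  # --- clustered events: deterministic slots in the central 70% of spans
  for (ci in seq_along(config$cluster_spec)) {
    cs <- config$cluster_spec[[ci]]
    span <- cs$end - cs$start
    n_ev <- cs$n_events
    usable_start <- cs$start + 0.15 * span
    step <- 0.7 * span / (2 * n_ev)
    slots <- round(usable_start + (seq_len(2 * n_ev) - 1L) * step)
    for (j in seq_len(n_ev)) {
      ei <- ei + 1L
      p1 <- as.integer(slots[2 * j - 1L])
      p2 <- as.integer(slots[2 * j])
      type <- sample(c("DEL", "DUP", "INV"), 1)
      oris <- sv_orientations(type)
      rows[[ei]] <- data.frame(
        event_id = sprintf("sv%04d", ei), sv_type = type,
        chrom1 = cs$chrom, pos1 = p1, ori1 = oris[1],
        chrom2 = cs$chrom, pos2 = p2, ori2 = oris[2],
        cluster_id = sprintf("design%02d", ci),
        in_repeat1 = near_repeat(repeats, cs$chrom, p1, clearance - 5L),
        in_repeat2 = near_repeat(repeats, cs$chrom, p2, clearance - 5L),
        stringsAsFactors = FALSE)
      occ <- reserve(occ, cs$chrom, p1 - m, p1 + m + 1L)
      occ <- reserve(occ, cs$chrom, p2 - m, p2 + m + 1L)
    }
  }

  # block cluster spans (plus chaining margin) for background placement
  bg_occ <- occ
  for (cs in config$cluster_spec) {
    bg_occ <- reserve(bg_occ, cs$chrom, cs$start - 6000L, cs$end + 6000L)
  }

  # --- repeat quota for background breakends
  n_breakends <- 2L * config$n_sv
  quota_total <- round(config$repeat_bias * n_breakends)
  realized_cluster <- if (ei > 0) {
    sum(vapply(rows, function(r) r$in_repeat1 + r$in_repeat2, 0))
  } else 0
  quota_bg <- quota_total - realized_cluster
  n_bg_breakends <- 2L * n_bg
  if (quota_bg < 0 || quota_bg > n_bg_breakends) {
    stop("repeat-bias quota infeasible with this cluster design")
  }
  flags <- rep(FALSE, n_bg_breakends)
  flags[sample.int(n_bg_breakends, quota_bg)] <- TRUE

  bg_types <- sample(c("DEL", "DUP", "INV", "BND"), n_bg, replace = TRUE,
                     prob = c(0.35, 0.2, 0.15, 0.3))
  chrom_w <- as.numeric(sizes) / sum(as.numeric(sizes))
  for (j in seq_len(n_bg)) {
    ei <- ei + 1L
    type <- bg_types[j]
    f1 <- flags[2 * j - 1L]
    f2 <- flags[2 * j]
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (type == "BND") {
        cpair <- sample(names(sizes), 2, replace = length(sizes) == 1,
                        prob = chrom_w)
        pa <- sample_pool_position(pools[[cpair[1]]], f1)
        pb <- sample_pool_position(pools[[cpair[2]]], f2)
        if (is.na(pa) || is.na(pb)) next
        b <- data.frame(chrom = cpair, pos = c(pa, pb),
                        in_repeat = c(f1, f2), stringsAsFactors = FALSE)
        # canonical breakend order (chrom, pos)
        b <- b[order(b$chrom, b$pos), ]
        if (b$chrom[1] == b$chrom[2] && abs(b$pos[1] - b$pos[2]) < 3L * m) next
        ori <- sample(ORIENTATIONS, 2, replace = TRUE)
      } else {
        chrom <- sample(names(sizes), 1, prob = chrom_w)
        pa <- sample_pool_position(pools[[chrom]], f1)
        pb <- sample_pool_position(pools[[chrom]], f2)
        if (is.na(pa) || is.na(pb) || abs(pa - pb) < 3L * m) next
        b <- data.frame(chrom = chrom, pos = sort(c(pa, pb)),
                        in_repeat = if (pa < pb) c(f1, f2) else c(f2, f1),
                        stringsAsFactors = FALSE)
        ori <- sv_orientations(type)
        if (type == "INV") ori <- rep(sample(ORIENTATIONS, 1), 2)
      }
      if (occupied(bg_occ, b$chrom[1], b$pos[1] - m, b$pos[1] + m + 1L)) next
      if (occupied(bg_occ, b$chrom[2], b$pos[2] - m, b$pos[2] + m + 1L)) next
      rows[[ei]] <- data.frame(
        event_id = sprintf("sv%04d", ei), sv_type = type,
        chrom1 = b$chrom[1], pos1 = b$pos[1], ori1 = ori[1],
        chrom2 = b$chrom[2], pos2 = b$pos[2], ori2 = ori[2],
        cluster_id = NA_character_,
        in_repeat1 = b$in_repeat[1], in_repeat2 = b$in_repeat[2],
        stringsAsFactors = FALSE)
      occ <- reserve(occ, b$chrom[1], b$pos[1] - m, b$pos[1] + m + 1L)
      occ <- reserve(occ, b$chrom[2], b$pos[2] - m, b$pos[2] + m + 1L)
      bg_occ <- reserve(bg_occ, b$chrom[1], b$pos[1] - m, b$pos[1] + m + 1L)
      bg_occ <- reserve(bg_occ, b$chrom[2], b$pos[2] - m, b$pos[2] + m + 1L)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("breakpoint placement failure after bounded retries (event ", ei, ")")
    }
  }
  truth <- do.call(rbind, rows)

  # designed microhomology lengths and upstream/downstream split
  mh <- sample(config$mh_distribution$length, nrow(truth), replace = TRUE,
               prob = config$mh_distribution$prob)
  truth$mh_len <- as.integer(mh)
  truth$mh_up <- vapply(truth$mh_len, function(L) {
    if (L == 0) 0L else sample.int(L + 1L, 1) - 1L
  }, 0L)
  truth
}

sv_orientations <- function(type) {
  switch(type,
    DEL = c("right", "left"),
    DUP = c("left", "right"),
    INV = c("right", "right"),
    BND = c("right", "left"))
}

# region descriptors matching junction_context(); jo = junction orientation
junction_regions <- function(chrom1, pos1, ori1, chrom2, pos2, ori2, flank) {
  f <- flank
  r <- function(chrom, start, end, rc) list(chrom = chrom, start = start,
                                            end = end, rc = rc)
  list(
    L = if (ori1 == "right") r(chrom1, pos1 - f + 1L, pos1 + 1L, FALSE)
        else r(chrom1, pos1, pos1 + f, TRUE),
    A = if (ori1 == "right") r(chrom1, pos1 + 1L, pos1 + f + 1L, FALSE)
        else r(chrom1, pos1 - f, pos1, TRUE),
    R = if (ori2 == "left") r(chrom2, pos2, pos2 + f, FALSE)
        else r(chrom2, pos2 - f + 1L, pos2 + 1L, TRUE),
    B = if (ori2 == "left") r(chrom2, pos2 - f, pos2, FALSE)
        else r(chrom2, pos2 + 1L, pos2 + f + 1L, TRUE))
}

read_region <- function(seqs, rg) {
  s <- substr(seqs[[rg$chrom]], rg$start + 1L, rg$end)
  v <- strsplit(s, "")[[1]]
  if (rg$rc) rev(comp_base(v)) else v
}

write_region <- function(seqs, rg, chars) {
  if (rg$rc) chars <- comp_base(rev(chars))
  substr(seqs[[rg$chrom]], rg$start + 1L, rg$end) <- paste(chars, collapse = "")
  seqs
}

comp_base <- function(v) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[v]
}

mismatch_base <- function(b) {
  cyc <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  unname(cyc[b])
}

#' Implant designed junction microhomology into a reference
#'
#' Edits the genome so that, for each event with designed length
#' `mh_len = m + k`, the `m` bases upstream and `k` bases downstream of the
#' junction are identical between the two joined sides and the next base
#' on each side mismatches: [junction_homology] on the edited sequence
#' returns the designed length exactly. Edits touch only the
#' reserved windows around each breakend.
#'
#' @param genome DNAStringSet to edit.
#' @param truth placement table from [place_breakpoints].
#' @param flank junction flank (must be >= every designed length).
#' @return the edited DNAStringSet.
#' @export
implant_junctions <- function(genome, truth, flank = 50L) {
  if (any(truth$mh_len > flank)) {
    stop("designed microhomology exceeds the flank window")
  }
  seqs <- stats::setNames(as.list(as.character(genome)), names(genome))
  f <- as.integer(flank)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rg <- junction_regions(tr$chrom1, tr$pos1, tr$ori1,
                           tr$chrom2, tr$pos2, tr$ori2, f)
    m <- tr$mh_up
    k <- tr$mh_len - m
    L <- read_region(seqs, rg$L)
    R <- read_region(seqs, rg$R)
    B <- read_region(seqs, rg$B)
    A <- read_region(seqs, rg$A)
    if (m > 0) B[(f - m + 1L):f] <- L[(f - m + 1L):f]
    if (m < f) B[f - m] <- mismatch_base(L[f - m])
    if (k > 0) A[1:k] <- R[1:k]
    if (k < f) A[k + 1L] <- mismatch_base(R[k + 1L])
    seqs <- write_region(seqs, rg$B, B)
    seqs <- write_region(seqs, rg$A, A)
  }
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(genome)
  out
}
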