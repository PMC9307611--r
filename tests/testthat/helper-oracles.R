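# Independent oracles used across the suite. These deliberately avoid the
# package's own sequence/interval helpers: string reconstruction and
# nested-loop comparisons only.

revcomp_str <- function(x) {
  # library primitive, not part of the code path under test
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# full derived-chromosome sequence for one junction (character genome)
derived_full <- function(seqs, chrom1, pos1, ori1, chrom2, pos2, ori2) {
  s1 <- seqs[[chrom1]]
  s2 <- seqs[[chrom2]]
  seg1 <- if (ori1 == "right") substr(s1, 1, pos1 + 1) else
    revcomp_str(substr(s1, pos1 + 1, nchar(s1)))
  seg2 <- if (ori2 == "left") substr(s2, pos2 + 1, nchar(s2)) else
    revcomp_str(substr(s2, 1, pos2 + 1))
  paste0(seg1, seg2)
}

# junction-slide brute force: number of breakpoint shifts in [-flank, flank]
# that reproduce the identical derived chromosome, minus one
oracle_slide_mh <- function(seqs, sv, flank = 50L) {
  shift1 <- function(p, ori, s) if (ori == "right") p + s else p - s
  shift2 <- function(p, ori, s) if (ori == "left") p + s else p - s
  ref <- derived_full(seqs, sv$chrom1, sv$pos1, sv$ori1,
                      sv$chrom2, sv$pos2, sv$ori2)
  hits <- 0L
  for (s in seq(-flank, flank)) {
    d <- derived_full(seqs,
                      sv$chrom1, shift1(sv$pos1, sv$ori1, s), sv$ori1,
                      sv$chrom2, shift2(sv$pos2, sv$ori2, s), sv$ori2)
    if (identical(d, ref)) hits <- hits + 1L
  }
  hits - 1L
}

genome_as_strings <- function(genome) {
  stats::setNames(as.list(as.character(genome)), names(genome))
}

# O(n * m) all-pairs SV matching under a policy
brute_matches_any <- function(svs, ref, policy) {
  out <- logical(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    for (j in seq_len(nrow(ref))) {
      if (svs$chrom1[i] != ref$chrom1[j] || svs$chrom2[i] != ref$chrom2[j]) next
      if (abs(svs$pos1[i] - ref$pos1[j]) > policy$window) next
      if (abs(svs$pos2[i] - ref$pos2[j]) > policy$window) next
      if (policy$require_type_match && svs$sv_type[i] != ref$sv_type[j]) next
      if (policy$require_orientation_match &&
          (svs$ori1[i] != ref$ori1[j] || svs$ori2[i] != ref$ori2[j])) next
      out[i] <- TRUE
      break
    }
  }
  out
}

# nested-loop window/interval intersection
brute_window_hits <- function(chrom, pos, track, flank) {
  hits <- character(0)
  for (j in seq_len(nrow(track))) {
    if (track$chrom[j] != chrom) next
    ws <- pos - flank
    we <- pos + flank + 1     # window [pos - flank, pos + flank], half-open
    if (ws < track$end[j] && track$start[j] < we) {
      hits <- c(hits, track$class[j])
    }
  }
  hits
}

# interval union length computed by sweeping sorted endpoints
brute_union_length <- function(track) {
  total <- 0
  for (chrom in unique(track$chrom)) {
    iv <- track[track$chrom == chrom, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    cur_s <- iv$start[1]; cur_e <- iv$end[1]
    for (j in seq_len(nrow(iv))[-1]) {
      if (iv$start[j] <= cur_e) {
        cur_e <- max(cur_e, iv$end[j])
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- iv$start[j]; cur_e <- iv$end[j]
      }
    }
    total <- total + (cur_e - cur_s)
  }
  total
}

random_sv_set <- function(n, chroms = c("chrA", "chrB"), span = 100000L,
                          types = c("DEL", "DUP", "INV", "BND")) {
  rows <- lapply(seq_len(n), function(i) {
    type <- sample(types, 1)
    if (type == "BND") {
      c1 <- sample(chroms, 1); c2 <- sample(chroms, 1)
      p <- sort(sample.int(span, 2) + 100L)
      if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp }
      ori <- sample(c("left", "right"), 2, replace = TRUE)
      data.frame(sv_id = sprintf("r%04d", i), sv_type = type,
                 chrom1 = c1, pos1 = p[1], ori1 = ori[1],
                 chrom2 = c2, pos2 = p[2], ori2 = ori[2],
                 stringsAsFactors = FALSE)
    } else {
      c1 <- sample(chroms, 1)
      p <- sort(sample.int(span, 2) + 100L)
      while (p[2] - p[1] < 10L) p <- sort(sample.int(span, 2) + 100L)
      ori <- switch(type, DEL = c("right", "left"), DUP = c("left", "right"),
                    INV = rep(sample(c("left", "right"), 1), 2))
      data.frame(sv_id = sprintf("r%04d", i), sv_type = type,
                 chrom1 = c1, pos1 = p[1], ori1 = ori[1],
                 chrom2 = c1, pos2 = p[2], ori2 = ori[2],
                 stringsAsFactors = FALSE)
    }
  })
  sv_table(do.call(rbind, rows))
}

# toy single-chromosome genome from an explicit string
toy_genome <- function(seq, name = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

del_record <- function(p1, p2, chrom = "chrT") {
  sv_table(data.frame(sv_id = "d1", sv_type = "DEL",
                      chrom1 = chrom, pos1 = p1, ori1 = "right",
                      chrom2 = chrom, pos2 = p2, ori2 = "left"))
}
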