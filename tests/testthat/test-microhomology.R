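# Junction flanks, microhomology length, pathway classification.

test_that("flank extraction returns the reference windows for a deletion", {
  set.seed(1)
  s <- rand_seq(400)
  g <- toy_genome(s)
  a <- 150L; b <- 300L                    # derived = ref[..149] ++ ref[300..]
  fl <- extract_flanks(g, del_record(a - 1L, b))
  expect_equal(fl$left_flank, substr(s, a - 50 + 1, a))
  expect_equal(fl$right_flank, substr(s, b + 1, b + 50))
  expect_false(fl$clipped)
  z <- extract_flanks(g, del_record(a - 1L, b), flank = 0L)
  expect_equal(nchar(z$left_flank), 0L)
  expect_equal(nchar(z$right_flank), 0L)
})

test_that("flanks near a contig edge are clipped and flagged", {
  g <- toy_genome(rand_seq(200, seed = 2))
  fl <- extract_flanks(g, del_record(20L, 180L))
  expect_true(fl$clipped)
  expect_equal(nchar(fl$left_flank), 21L)
})

test_that("a designed upstream+downstream tract gives the summed length", {
  # 3 matching bases upstream of both breakends ("CAT", 4th differs) and 2
  # matching downstream ("GG", 3rd differs) -> total ambiguity 5, NHEJ
  set.seed(3)
  v <- strsplit(rand_seq(400), "")[[1]]
  a <- 150L; b <- 300L                    # deleting 0-based [150, 300)
  v[(a - 3):a] <- c("T", "C", "A", "T")   # upstream of junction side 1
  v[(b - 3):b] <- c("G", "C", "A", "T")   # upstream of junction side 2
  v[(a + 1):(a + 3)] <- c("G", "G", "A")  # downstream side 1 (deleted side)
  v[(b + 1):(b + 3)] <- c("G", "G", "C")  # downstream side 2 (retained)
  g <- toy_genome(paste(v, collapse = ""))
  sv <- del_record(a - 1L, b)
  h <- junction_homology(g, sv)
  expect_equal(h$mh_length, 5L)
  expect_equal(h$pathway, "NHEJ")
  expect_equal(h$mh_sequence, "CATGG")
  expect_equal(oracle_slide_mh(genome_as_strings(g), sv), 5L)
  # upstream-only mode reports the suffix component alone
  expect_equal(junction_homology(g, sv, mode = "upstream")$mh_length, 3L)
})

test_that("homology between identical tracts caps at the flank length", {
  set.seed(4)
  tract <- rand_seq(60)
  s <- paste0(rand_seq(150), tract, rand_seq(100), tract, rand_seq(150))
  g <- toy_genome(s)
  # join the start of the two tract copies: breakpoints slide freely
  p1 <- 150L + 0L   # first tract base, side 1 retained up to p1
  p2 <- 150L + 60L + 100L + 1L
  sv <- del_record(p1, p2)
  h <- junction_homology(g, sv)
  expect_equal(h$mh_length, 50L)
  expect_equal(h$pathway, "SSA")
})

test_that("forced first-base mismatches give a blunt junction", {
  co <- tiny_cohort()
  cfg <- tiny_sim_config(seed = 41L,
                         mh_distribution = data.frame(length = 0L, prob = 1))
  co0 <- simulate_cohort(cfg)
  h <- junction_homology(co0$genome, truth_sv(co0))
  expect_true(all(h$mh_length == 0L))
})

test_that("a non-templated junction insertion forces zero homology", {
  co <- tiny_cohort()
  sv <- truth_sv(co)[1:3, ]
  sv$junction_insert <- c("ACGT", "", "")
  h <- junction_homology(co$genome, sv)
  expect_equal(h$mh_length[1], 0L)
  expect_equal(h$mh_length[2:3], co$truth$mh_len[2:3])
})

test_that("degenerate junctions with identical breakends are rejected", {
  g <- toy_genome(rand_seq(300, seed = 5))
  sv <- sv_table(data.frame(sv_id = "x", sv_type = "BND",
                            chrom1 = "chrT", pos1 = 100L, ori1 = "right",
                            chrom2 = "chrT", pos2 = 100L, ori2 = "left"))
  expect_error(junction_homology(g, sv), "degenerate")
})

test_that("detector equals the junction-slide oracle on every cohort junction", {
  co <- tiny_cohort()
  seqs <- genome_as_strings(co$genome)
  sv <- truth_sv(co)
  h <- junction_homology(co$genome, sv)
  for (i in seq_len(nrow(sv))) {
    expect_equal(h$mh_length[i], min(oracle_slide_mh(seqs, sv[i, ]), 50L),
                 label = sv$sv_id[i])
  }
})

test_that("microhomology is invariant under reverse-complementing the genome", {
  co <- tiny_cohort()
  sv <- truth_sv(co)
  h <- junction_homology(co$genome, sv)
  rc <- Biostrings::reverseComplement(co$genome)
  lens <- stats::setNames(Biostrings::width(co$genome), names(co$genome))
  flip <- sv
  flip$pos1 <- lens[sv$chrom1] - 1L - sv$pos1
  flip$pos2 <- lens[sv$chrom2] - 1L - sv$pos2
  flip$ori1 <- ifelse(sv$ori1 == "right", "left", "right")
  flip$ori2 <- ifelse(sv$ori2 == "right", "left", "right")
  # swap roles so bnd1 still enters the junction, and keep DEL/DUP validity
  flip2 <- flip
  flip2$pos1 <- flip$pos2; flip2$chrom1 <- flip$chrom2; flip2$ori1 <- flip$ori2
  flip2$pos2 <- flip$pos1; flip2$chrom2 <- flip$chrom1; flip2$ori2 <- flip$ori1
  h2 <- junction_homology(rc, flip2)
  expect_equal(h2$mh_length, h$mh_length)
})

test_that("homology grows by one per matching base until the flank cap", {
  set.seed(6)
  base <- strsplit(rand_seq(500), "")[[1]]
  a <- 200L; b <- 400L
  g0 <- toy_genome(paste(base, collapse = ""))
  sv <- del_record(a - 1L, b)
  for (L in c(0L, 1L, 2L, 7L, 25L, 49L, 50L)) {
    v <- base
    # junction-adjacent retained base is 1-based `a` on side 1, `b` on side 2
    if (L > 0) v[(b - L + 1L):b] <- v[(a - L + 1L):a]
    # force the next upstream base to mismatch
    if (L < 50L) v[b - L] <- setdiff(c("A", "C", "G", "T"), v[a - L])[1]
    # force downstream first bases to mismatch (kill the prefix component)
    v[a + 1L] <- setdiff(c("A", "C", "G", "T"), v[b + 1L])[1]
    h <- junction_homology(toy_genome(paste(v, collapse = "")), sv)
    expect_equal(h$mh_length, L, label = paste("designed", L))
  }
})

test_that("pathway classification follows the printed bounds exactly", {
  expect_equal(classify_pathway(c(0L, 1L, 5L, 6L, 25L, 26L, 50L)),
               c("blunt", "NHEJ", "NHEJ", "MMEJ", "MMEJ", "SSA", "SSA"))
  expect_error(classify_pathway(-1L), "nonnegative")
  # exhaustive consistency with the bounds object over 0..60
  b <- pathway_bounds()
  for (L in 0:60) {
    want <- if (L == 0) "blunt" else if (L <= 5) "NHEJ" else if (L <= 25)
      "MMEJ" else "SSA"
    expect_equal(classify_pathway(L, b), want)
  }
})

test_that("pathway summaries deduplicate repeated junctions", {
  h <- data.frame(
    sv_id = c("a", "b", "c", "d", "e"),
    chrom1 = "c1", pos1 = c(1, 2, 3, 4, 5), ori1 = "right",
    chrom2 = "c1", pos2 = c(11, 12, 13, 14, 15), ori2 = "left",
    mh_length = c(0L, 3L, 3L, 10L, 30L),
    pathway = c("blunt", "NHEJ", "NHEJ", "MMEJ", "SSA"),
    stringsAsFactors = FALSE)
  s <- summarize_pathways(h)
  expect_equal(unname(s$counts), c(1L, 2L, 1L, 1L))
  expect_equal(s$non_blunt, 4L)
  expect_equal(s$total, 5L)
  # the same junction listed twice counts once
  s2 <- summarize_pathways(rbind(h, h[2, ]))
  expect_equal(s2$counts, s$counts)
})

test_that("cohort pathway counts equal the designed class quotas", {
  co <- tiny_cohort()
  h <- junction_homology(co$genome, truth_sv(co))
  s <- summarize_pathways(h)
  designed <- table(factor(classify_pathway(co$truth$mh_len),
                           c("blunt", "NHEJ", "MMEJ", "SSA")))
  expect_equal(unname(s$counts), as.vector(designed))
})
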