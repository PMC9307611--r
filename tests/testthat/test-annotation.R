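# Repeat/fragile-site annotation, enrichment tests, gene disruption,
# fusion frame, over-representation.

test_that("breakends take the class of the largest-overlap repeat", {
  track <- annotation_track(
    chrom = c("c1", "c1", "c1"),
    start = c(100L, 470L, 540L),
    end = c(200L, 540L, 700L),
    class = c("LINE/L1", "LTR/ERVK", "Simple_repeat"))
  be <- data.frame(sv_id = c("a", "b"), side = 1L, chrom = "c1",
                   pos = c(110L, 520L), ori = "right")
  res <- annotate_repeats(be, track)
  expect_equal(res$breakends$repeat_class[1], "LINE/L1")
  # window [470, 571): overlap 70 bp with LTR/ERVK vs 31 bp with Simple_repeat
  expect_equal(res$breakends$repeat_class[2], "LTR/ERVK")
  expect_equal(res$fraction, 1)
})

test_that("exact overlap ties break to the lexicographically smaller class", {
  track <- annotation_track(
    chrom = c("c1", "c1"), start = c(0L, 149L), end = c(100L, 250L),
    class = c("zeta", "alpha"))
  be <- data.frame(sv_id = "t", side = 1L, chrom = "c1", pos = 124L,
                   ori = "right")
  # window [74, 175): 26 bp overlap with each interval
  res <- annotate_repeats(be, track)
  expect_equal(res$breakends$repeat_class, "alpha")
})

test_that("repeat annotation agrees with a nested-loop window oracle", {
  set.seed(9)
  start <- sample.int(50000, 60)
  track <- annotation_track(chrom = sample(c("c1", "c2"), 60, replace = TRUE),
                            start = start, end = start + sample.int(800, 60),
                            class = sample(letters[1:4], 60, replace = TRUE))
  be <- data.frame(sv_id = sprintf("b%02d", 1:80), side = 1L,
                   chrom = sample(c("c1", "c2"), 80, replace = TRUE),
                   pos = sample.int(52000, 80), ori = "right")
  res <- annotate_repeats(be, track)
  for (i in seq_len(nrow(be))) {
    hits <- brute_window_hits(be$chrom[i], be$pos[i], track, 50L)
    expect_equal(!is.na(res$breakends$repeat_class[i]), length(hits) > 0,
                 label = be$sv_id[i])
  }
  expect_equal(res$fraction, mean(!is.na(res$breakends$repeat_class)))
  # permutation invariance of the overall fraction
  res2 <- annotate_repeats(be[sample(nrow(be)), ],
                           track[sample(nrow(track)), ])
  expect_equal(res2$fraction, res$fraction)
})

test_that("repeat enrichment p-values match direct binomial-tail summation", {
  expect_equal(repeat_enrichment_test(0, 10, 0.45), 1.0)
  expect_equal(repeat_enrichment_test(10, 10, 0.45), 0.45^10)
  direct <- sum(vapply(54:100, function(i) {
    choose(100, i) * 0.45^i * 0.55^(100 - i)
  }, 0))
  expect_equal(repeat_enrichment_test(54, 100, 0.45), direct,
               tolerance = 1e-12)
  expect_error(repeat_enrichment_test(1, 0, 0.45), "positive")
})

test_that("fragile-site intersection matches the all-pairs oracle", {
  co <- tiny_cohort()
  sv <- truth_sv(co)
  hits <- intersect_fragile_sites(sv, co$fragile)
  be <- breakend_table(sv)
  want <- character(0)
  for (i in seq_len(nrow(be))) {
    for (g in brute_window_hits(be$chrom[i], be$pos[i], co$fragile, 50L)) {
      want <- c(want, paste(be$sv_id[i], g))
    }
  }
  expect_setequal(paste(hits$sv_id, hits$fragile_gene), unique(want))
  # a breakend placed inside a labelled interval reports that gene
  fr <- co$fragile[1, ]
  probe <- sv_table(data.frame(
    sv_id = "probe", sv_type = "DEL",
    chrom1 = fr$chrom, pos1 = fr$start + 500L, ori1 = "right",
    chrom2 = fr$chrom, pos2 = fr$start + 2500L, ori2 = "left"))
  expect_true(fr$class %in%
                intersect_fragile_sites(probe, co$fragile)$fragile_gene)
  # and one far outside every interval reports nothing
  far <- annotation_track("cZ", 10L, 20L, "nowhere")
  expect_equal(nrow(intersect_fragile_sites(probe, far)), 0L)
})

# two intron-less genes on separate chromosomes for fusion tests
toy_fusion_genes <- function(s1_len = 3000L, s2_len = 3000L,
                             cds1 = c(600L, 1800L), cds2 = c(900L, 2100L),
                             strand1 = "+", strand2 = "+") {
  models <- data.frame(
    gene_id = rep(c("geneA", "geneB"), each = 2),
    chrom = rep(c("g1", "g2"), each = 2),
    strand = rep(c(strand1, strand2), each = 2),
    feature = rep(c("exon", "CDS"), 2),
    start = c(cds1[1], cds1[1], cds2[1], cds2[1]),
    end = c(cds1[2], cds1[2], cds2[2], cds2[2]),
    stringsAsFactors = FALSE)
  svdynamics:::gene_models(models)
}

test_that("gene disruption covers breakends and rearranged spans", {
  genes <- toy_fusion_genes()
  # deletion spanning all of geneA
  sv <- sv_table(data.frame(sv_id = "s", sv_type = "DEL",
                            chrom1 = "g1", pos1 = 100L, ori1 = "right",
                            chrom2 = "g1", pos2 = 2500L, ori2 = "left"))
  ann <- annotate_genes(sv, genes)
  expect_true("geneA" %in% ann$disrupted$gene_id)
  # distant junction with no breakend in a gene disrupts nothing
  sv2 <- sv_table(data.frame(sv_id = "s2", sv_type = "BND",
                             chrom1 = "g1", pos1 = 100L, ori1 = "right",
                             chrom2 = "g2", pos2 = 100L, ori2 = "left"))
  expect_equal(nrow(annotate_genes(sv2, genes)$disrupted), 0L)
})

test_that("fusion partners follow the junction orientation rule", {
  genes <- toy_fusion_genes()
  # geneA (+ strand) at a right-facing breakend reads into the junction:
  # 5' partner geneA, 3' partner geneB
  sv <- sv_table(data.frame(sv_id = "f1", sv_type = "BND",
                            chrom1 = "g1", pos1 = 1200L, ori1 = "right",
                            chrom2 = "g2", pos2 = 1500L, ori2 = "left"))
  fus <- annotate_genes(sv, genes)$fusions
  expect_equal(fus$five_prime, "geneA")
  expect_equal(fus$three_prime, "geneB")
  # both breakends right-facing on + strand genes: no consistent assignment
  sv2 <- sv_table(data.frame(sv_id = "f2", sv_type = "BND",
                             chrom1 = "g1", pos1 = 1200L, ori1 = "right",
                             chrom2 = "g2", pos2 = 1500L, ori2 = "right"))
  expect_equal(nrow(annotate_genes(sv2, genes)$fusions), 0L)
  # a minus-strand acceptor accepts at a right-facing breakend
  genes_m <- toy_fusion_genes(strand2 = "-")
  fus3 <- annotate_genes(sv2, genes_m)$fusions
  expect_equal(fus3$five_prime, "geneA")
  expect_equal(fus3$three_prime, "geneB")
})

test_that("fusion frame arithmetic matches explicit phase cases", {
  genes <- toy_fusion_genes()
  bndA <- function(p) list(chrom = "g1", pos = p, ori = "right")
  bndB <- function(p) list(chrom = "g2", pos = p, ori = "left")
  # donor keeps (pos - 600 + 1) coding bases; acceptor skips (pos - 900)
  # phase 0 + phase 0 -> in frame
  expect_equal(fusion_frame(genes, "geneA", bndA(600L + 299L),
                            "geneB", bndB(900L + 300L)), "in-frame")
  # donor phase 1, acceptor phase 0 -> out of frame
  expect_equal(fusion_frame(genes, "geneA", bndA(600L + 300L),
                            "geneB", bndB(900L + 300L)), "out-of-frame")
  # breakend outside the CDS span -> noncoding
  expect_equal(fusion_frame(genes, "geneA", bndA(100L),
                            "geneB", bndB(900L + 300L)), "noncoding")
})

test_that("fusion frame agrees with a conceptual-translation oracle", {
  set.seed(12)
  for (case in 1:20) {
    cds1 <- c(600L, 600L + 3L * sample(150:300, 1))
    cds2 <- c(900L, 900L + 3L * sample(150:300, 1))
    genes <- toy_fusion_genes(cds1 = cds1, cds2 = cds2)
    s1 <- rand_seq(3000); s2 <- rand_seq(3000)
    p1 <- sample(seq(cds1[1] + 30L, cds1[2] - 30L), 1)
    p2 <- sample(seq(cds2[1] + 90L, cds2[2] - 90L), 1)
    got <- fusion_frame(genes, "geneA", list(chrom = "g1", pos = p1, ori = "right"),
                        "geneB", list(chrom = "g2", pos = p2, ori = "left"))
    donor_cds <- substr(s1, cds1[1] + 1L, p1 + 1L)
    acceptor_tail <- substr(s2, p2 + 1L, cds2[2])
    fused <- paste0(donor_cds, acceptor_tail)
    fused <- substr(fused, 1, 3 * (nchar(fused) %/% 3))
    aa_fused <- as.character(Biostrings::translate(
      Biostrings::DNAString(fused), if.fuzzy.codon = "solve"))
    # acceptor peptide from its first complete native codon after the junction
    acc_off <- (p2 - cds2[1]) %% 3
    native_tail <- substr(s2, p2 + 1L + (3 - acc_off) %% 3, cds2[2])
    native_tail <- substr(native_tail, 1, 3 * (nchar(native_tail) %/% 3))
    aa_native <- as.character(Biostrings::translate(
      Biostrings::DNAString(native_tail), if.fuzzy.codon = "solve"))
    aa_native <- substr(aa_native, 2, nchar(aa_native) - 1)
    preserved <- grepl(aa_native, aa_fused, fixed = TRUE)
    expect_equal(got == "in-frame", preserved,
                 label = sprintf("case %d (p1=%d p2=%d)", case, p1, p2))
  }
})

test_that("over-representation p-values match hypergeometric enumeration", {
  universe <- sprintf("g%03d", 1:100)
  hits <- universe[1:20]
  set_ <- universe[c(1:6, 51:54)]          # overlap 6, size 10
  res <- ora_test(hits, list(s = set_), universe)
  direct <- sum(vapply(6:10, function(k) {
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)
  }, 0))
  expect_equal(res$p, direct, tolerance = 1e-12)
  # disjoint set: observing >= 0 is certain
  expect_equal(ora_test(hits, list(s = universe[90:99]), universe)$p, 1)
  # hits = set = universe: degenerate certainty
  expect_equal(ora_test(universe, list(s = universe), universe)$p, 1)
  expect_error(ora_test(character(), list(s = "x"), character()), "empty")
  expect_error(ora_test("zz", list(s = "x"), universe), "outside")
})

test_that("small sets in a large universe approach the binomial limit", {
  universe <- sprintf("u%04d", 1:5000)
  hits <- universe[1:500]
  set_ <- universe[c(1, 2, 1001, 2001, 3001)]   # size 5, overlap 2
  p_hyper <- ora_test(hits, list(s = set_), universe)$p
  p_binom <- stats::pbinom(1, 5, 0.1, lower.tail = FALSE)
  expect_lt(abs(p_hyper - p_binom), 1e-3)
})

test_that("ORA supports Benjamini-Hochberg adjustment across sets", {
  universe <- sprintf("g%03d", 1:60)
  sets <- list(a = universe[1:10], b = universe[11:20], c = universe[21:30])
  res <- ora_test(universe[1:12], sets, universe, adjust = TRUE)
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"))
})
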