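# Hotspot chaining, burden normalization, presence patterns, group t test.

brute_chain_clusters <- function(pos, max_gap, min_events) {
  pos <- sort(pos)
  groups <- list()
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= max_gap) cur <- c(cur, p)
    else { groups[[length(groups) + 1]] <- cur; cur <- p }
  }
  groups[[length(groups) + 1]] <- cur
  Filter(function(g) length(g) >= min_events, groups)
}

test_that("dense breakends chain into one cluster; sparse ones into none", {
  be <- data.frame(sv_id = sprintf("s%02d", 1:10), side = 1L, chrom = "c1",
                   pos = 50000L + seq(0L, 900L, by = 100L), ori = "right")
  cl <- cluster_breakpoints(be, max_gap = 10000L, min_events = 5L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_events, 10L)
  set.seed(31)
  sparse <- data.frame(sv_id = sprintf("u%02d", 1:20), side = 1L, chrom = "c1",
                       pos = sort(sample.int(5000000L, 20)), ori = "right")
  # expected spacing 250 kb: far beyond a 10-kb chaining gap
  expect_equal(nrow(cluster_breakpoints(sparse, 10000L, 5L)), 0L)
})

test_that("chaining equals the brute-force oracle and ignores input order", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 300
    be <- data.frame(sv_id = sprintf("x%03d", seq_len(n)), side = 1L,
                     chrom = sample(c("c1", "c2"), n, replace = TRUE),
                     pos = sample.int(2000000L, n), ori = "right")
    cl <- cluster_breakpoints(be, max_gap = 20000L, min_events = 4L)
    want <- 0L
    for (chrom in unique(be$chrom)) {
      want <- want + length(brute_chain_clusters(be$pos[be$chrom == chrom],
                                                 20000L, 4L))
    }
    expect_equal(nrow(cl), want)
    perm <- cluster_breakpoints(be[sample(n), ], 20000L, 4L)
    expect_identical(perm, cl)
  }
})

test_that("designed hotspot clusters are recovered with exact membership", {
  cfg <- sim_config(
    genome_sizes = c(chr1 = 2e6, chr2 = 2e6),
    n_sv = 60L,
    cluster_spec = list(
      list(chrom = "chr1", start = 5e5, end = 6e5, n_events = 10L),
      list(chrom = "chr2", start = 1e6, end = 1.1e6, n_events = 10L)),
    n_cnv = 0L, n_indel = 0L, n_genes = 4L, n_panel = 0L, seed = 43L)
  gen <- generate_genome(cfg)
  truth <- place_breakpoints(gen, cfg)
  be <- data.frame(sv_id = rep(truth$event_id, 2),
                   side = rep(1:2, each = nrow(truth)),
                   chrom = c(truth$chrom1, truth$chrom2),
                   pos = c(truth$pos1, truth$pos2),
                   ori = c(truth$ori1, truth$ori2))
  cl <- cluster_breakpoints(be)
  for (ci in 1:2) {
    want <- sort(truth$event_id[!is.na(truth$cluster_id) &
                                  truth$cluster_id == sprintf("design%02d", ci)])
    match_i <- which(vapply(seq_len(nrow(cl)), function(i) {
      setequal(strsplit(cl$sv_ids[i], ",")[[1]], want)
    }, NA))
    expect_length(match_i, 1)
  }
})

test_that("burden profiles reproduce the hand-computed normalization", {
  counts <- data.frame(timepoint = c("10.5E", "16.5E", "1M", "4M", "8M", "12M"),
                       variant_type = "SV",
                       raw = c(10, 20, 30, 40, 60, 80))
  prof <- burden_profile(counts, replicates = 2)
  expect_equal(prof$averaged, c(5, 10, 15, 20, 30, 40))
  expect_equal(prof$normalized,
               c(5, 10, 15, 20, 30, 40) / 17.5, tolerance = 1e-9)
  # constant counts normalize to exactly 1
  const <- burden_profile(data.frame(timepoint = letters[1:5],
                                     variant_type = "CNV", raw = 8),
                          replicates = 2)
  expect_true(all(const$normalized == 1))
  # a single timepoint is its own median
  single <- burden_profile(data.frame(timepoint = "t1", variant_type = "SV",
                                      raw = 12), replicates = 2)
  expect_equal(single$normalized, 1)
})

test_that("normalization is scale invariant and flags all-zero series", {
  counts <- data.frame(timepoint = rep(letters[1:6], 2),
                       variant_type = rep(c("SV", "indel"), each = 6),
                       raw = c(3, 9, 4, 12, 6, 18, rep(0, 6)))
  prof <- burden_profile(counts, replicates = 2)
  scaled <- counts
  scaled$raw[scaled$variant_type == "SV"] <-
    scaled$raw[scaled$variant_type == "SV"] * 7
  prof2 <- burden_profile(scaled, replicates = 2)
  sv_rows <- prof$variant_type == "SV"
  expect_equal(prof2$normalized[sv_rows], prof$normalized[sv_rows])
  zero_rows <- prof$variant_type == "indel"
  expect_true(all(is.na(prof$normalized[zero_rows])))
  expect_true(all(prof$degenerate[zero_rows]))
})

test_that("presence patterns are exhaustive and mutually exclusive", {
  # spot checks mirroring the observed timecourse categories
  expect_equal(classify_presence(rep(TRUE, 6)), "persistent")
  expect_equal(classify_presence(c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
               "transient")
  expect_equal(classify_presence(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)),
               "recurrent")
  # all 63 non-empty 6-timepoint vectors fall in exactly one class
  counts <- c(persistent = 0L, transient = 0L, recurrent = 0L)
  for (code in 1:63) {
    v <- as.logical(bitwAnd(code, 2^(0:5)))
    cls <- classify_presence(v)
    expect_true(cls %in% names(counts))
    counts[cls] <- counts[cls] + 1L
  }
  expect_equal(sum(counts), 63L)
  expect_equal(counts[["persistent"]], 1L)
  expect_error(classify_presence(rep(FALSE, 3)), "non-empty")
})

test_that("presence matrices threshold hits per timepoint", {
  hits <- data.frame(entity = c("Brca1", "Brca1", "Brca1", "g2", "g2"),
                     timepoint = c("t1", "t2", "t3", "t1", "t3"))
  pm <- presence_matrix(hits, c("t1", "t2", "t3"))
  expect_equal(pm$patterns$pattern_class[pm$patterns$entity == "Brca1"],
               "persistent")
  expect_equal(pm$patterns$pattern_class[pm$patterns$entity == "g2"],
               "recurrent")
  pm2 <- presence_matrix(hits, c("t1", "t2", "t3"), min_hits = 2L)
  expect_true(all(!pm2$matrix))
})

test_that("group comparison matches the pooled-variance closed form", {
  a <- c(10, 12, 14, 16)
  b <- c(11, 13, 15, 17)
  res <- compare_groups(a, b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 6
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_manual <- 2 * stats::pt(abs(t_manual), df = 6, lower.tail = FALSE)
  expect_equal(res$t, t_manual, tolerance = 1e-9)
  expect_equal(res$p, p_manual, tolerance = 1e-9)
  expect_equal(res$df, 6)
})

test_that("group comparison resolves degenerate and extreme inputs", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  sep <- compare_groups(c(1, 2, 3), c(1, 2, 3) + 1e6)
  expect_lt(sep$p, 1e-10)
  flat <- compare_groups(c(5, 5, 5), c(9, 9, 9))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 0)
  const <- compare_groups(c(4, 4), c(4, 4))
  expect_true(const$degenerate)
  expect_equal(const$p, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  welch <- compare_groups(c(1, 2, 3, 9), c(2, 2.1, 2.2), welch = TRUE)
  expect_true(is.finite(welch$p))
})
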