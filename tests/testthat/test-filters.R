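# Hard filters, panel subtraction, de novo separation, replicate merging.

rand_quality_svs <- function(n, seed) {
  set.seed(seed)
  sv <- random_sv_set(n)
  sv$median_mapq <- sample(c(0L, 20L, 39L, 40L, 41L, 60L), n, replace = TRUE)
  sv$normal_discordant <- sample(c(TRUE, FALSE), n, replace = TRUE,
                                 prob = c(0.2, 0.8))
  sv$artifact_flag <- sample(c(TRUE, FALSE), n, replace = TRUE,
                             prob = c(0.2, 0.8))
  sv
}

test_that("SV quality filter removes below-40 MAPQ and keeps 40 itself", {
  sv <- random_sv_set(3)
  sv$median_mapq <- c(39L, 40L, 41L)
  res <- quality_filter_svs(sv)
  expect_equal(res$removed$sv_id, sv$sv_id[1])
  expect_equal(res$removed$reason, "median MAPQ < 40")
  expect_equal(res$kept$sv_id, sv$sv_id[2:3])
})

test_that("SV quality filter equals brute-force predicate evaluation", {
  sv <- rand_quality_svs(50, seed = 101)
  res <- quality_filter_svs(sv)
  keep <- !(sv$median_mapq < 40 | sv$normal_discordant | sv$artifact_flag)
  expect_equal(res$kept$sv_id, sv$sv_id[keep])
  expect_equal(res$removed$sv_id, sv$sv_id[!keep])
  # partition: kept and removed reassemble the input exactly
  expect_setequal(c(res$kept$sv_id, res$removed$sv_id), sv$sv_id)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(sv))
  # one primary reason each, in the stated order
  art_only <- !sv$normal_discordant & sv$artifact_flag & sv$median_mapq >= 40
  expect_true(all(res$removed$reason[match(sv$sv_id[art_only],
                                           res$removed$sv_id)] ==
                    "library artifact"))
})

test_that("CNV filter applies the four hard thresholds with strict bounds", {
  mk <- function(type, len, rd, e, q0) {
    data.frame(chrom = "c1", start = 1000L, end = 1000L + len,
               cnv_type = type, normalized_rd = rd, e_value = e, q0 = q0)
  }
  keep <- filter_cnvs(mk("loss", 5000L, 0.35, 1e-6, 0.1))
  expect_equal(nrow(keep$kept), 1L)
  rd_fail <- filter_cnvs(mk("loss", 5000L, 0.45, 1e-6, 0.1))
  expect_equal(rd_fail$removed$reason, "read depth")
  # boundary: length must exceed 1 kb, so exactly 1000 is removed
  len_fail <- filter_cnvs(mk("gain", 1000L, 2.0, 1e-6, 0.1))
  expect_equal(len_fail$removed$reason, "length")
  expect_equal(nrow(filter_cnvs(mk("gain", 1001L, 2.0, 1e-6, 0.1))$kept), 1L)
  # boundary: q0 and e-value are strict upper bounds
  expect_equal(filter_cnvs(mk("loss", 5000L, 0.3, 1e-6, 0.5))$removed$reason, "q0")
  expect_equal(filter_cnvs(mk("loss", 5000L, 0.3, 0.05, 0.1))$removed$reason,
               "e-value")
  # boundary: read depth strictly below 0.4 / strictly above 1.6
  expect_equal(filter_cnvs(mk("loss", 5000L, 0.4, 1e-6, 0.1))$removed$reason,
               "read depth")
  expect_equal(filter_cnvs(mk("gain", 5000L, 1.6, 1e-6, 0.1))$removed$reason,
               "read depth")
})

test_that("CNV filter equals brute-force predicate evaluation", {
  set.seed(77)
  n <- 120
  cnv <- data.frame(
    chrom = "c1",
    start = 1000L + 200L * seq_len(n),
    cnv_type = sample(c("gain", "loss"), n, replace = TRUE),
    normalized_rd = sample(c(0.1, 0.39, 0.4, 0.41, 1.59, 1.6, 1.61, 2.5), n,
                           replace = TRUE),
    e_value = sample(c(1e-8, 0.049, 0.05, 0.2), n, replace = TRUE),
    q0 = sample(c(0, 0.49, 0.5, 0.9), n, replace = TRUE))
  cnv$end <- cnv$start + sample(c(500L, 1000L, 1001L, 8000L), n, replace = TRUE)
  res <- filter_cnvs(cnv)
  len <- cnv$end - cnv$start
  keep <- cnv$q0 < 0.5 & len > 1000 & cnv$e_value < 0.05 &
    ifelse(cnv$cnv_type == "loss", cnv$normalized_rd < 0.4,
           cnv$normalized_rd > 1.6)
  expect_equal(sort(res$kept$cnv_id), sort(cnv_table(cnv)$cnv_id[keep]))
  expect_equal(nrow(res$kept) + nrow(res$removed), n)
})

test_that("panel subtraction matches records within the window and is idempotent", {
  sv <- random_sv_set(1, types = "DEL")
  # identical record, zero window: removed
  expect_equal(nrow(subtract_panel(sv, sv, match_policy(window = 0L))$kept), 0L)
  # breakends offset by 120 bp with window 100: kept
  shifted <- sv
  shifted$pos1 <- shifted$pos1 + 120L
  shifted$pos2 <- shifted$pos2 + 120L
  expect_equal(nrow(subtract_panel(sv, shifted, match_policy(window = 100L))$kept),
               1L)
  set.seed(303)
  a <- random_sv_set(30)
  b <- random_sv_set(30)
  pol <- match_policy(window = 50L)
  res <- subtract_panel(a, b, pol)
  expect_equal(res$kept$sv_id, a$sv_id[!brute_matches_any(a, b, pol)])
  again <- subtract_panel(res$kept, b, pol)
  expect_identical(again$kept$sv_id, res$kept$sv_id)
})

test_that("subtraction and de novo separation are order-invariant partitions", {
  set.seed(404)
  a <- random_sv_set(40)
  base <- rbind(a[sample(40, 15), ], random_sv_set(10))
  pol <- match_policy()
  sp <- split_de_novo(a, base, pol)
  expect_equal(nrow(sp$accumulated) + nrow(sp$de_novo), nrow(a))
  perm <- a[sample(nrow(a)), ]
  sp2 <- split_de_novo(perm, base[sample(nrow(base)), ], pol)
  expect_setequal(sp2$accumulated$sv_id, sp$accumulated$sv_id)
  expect_setequal(sp2$de_novo$sv_id, sp$de_novo$sv_id)
})

test_that("de novo separation handles the degenerate baselines", {
  a <- random_sv_set(10)
  sp <- split_de_novo(a, a, match_policy())
  expect_equal(nrow(sp$de_novo), 0L)
  disjoint <- random_sv_set(10)
  disjoint$chrom1 <- "chrZ"
  disjoint$chrom2 <- "chrZ"
  sp2 <- split_de_novo(a, disjoint, match_policy())
  expect_equal(nrow(sp2$accumulated), 0L)
  expect_warning(sp3 <- split_de_novo(a, a[0, ], match_policy()),
                 "empty baseline")
  expect_equal(nrow(sp3$de_novo), nrow(a))
})

test_that("window-0 matching on exact duplicates reduces to set intersection", {
  set.seed(55)
  a <- random_sv_set(40)
  b <- rbind(a[sample(40, 20), ], random_sv_set(15))
  key <- function(x) paste(x$sv_type, x$chrom1, x$pos1, x$ori1,
                           x$chrom2, x$pos2, x$ori2)
  res <- subtract_panel(a, b, match_policy(window = 0L))
  expect_setequal(key(res$removed), intersect(key(a), key(b)))
})

test_that("replicate merge uses union semantics with per-record counts", {
  a <- random_sv_set(10)
  # identical replicates: every record count 2, frequency = per-replicate count
  m1 <- merge_replicates(list(a, a), match_policy(window = 0L))
  expect_true(all(m1$merged$replicate_count == 2L))
  expect_equal(sum(m1$frequency$frequency), 10)
  # disjoint replicates of sizes 10 and 14: union of 24, total frequency 12
  b <- random_sv_set(14)
  b$chrom1 <- paste0(b$chrom1, "_r2")
  b$chrom2 <- paste0(b$chrom2, "_r2")
  b$sv_id <- paste0("b_", b$sv_id)
  m2 <- merge_replicates(list(a, b), match_policy(window = 0L))
  expect_equal(nrow(m2$merged), 24L)
  expect_true(all(m2$merged$replicate_count == 1L))
  expect_equal(sum(m2$frequency$frequency), 12)
  expect_error(merge_replicates(list(a, b), replicates = 3L), "3 replicates")
})

test_that("replicate merge equals a brute-force union with matching", {
  set.seed(66)
  a <- random_sv_set(25)
  b <- rbind(a[sample(25, 10), ], random_sv_set(12))
  b$sv_id <- paste0("r2_", seq_len(nrow(b)))
  pol <- match_policy(window = 0L)
  m <- merge_replicates(list(a, b), pol)
  matched_b <- brute_matches_any(b, a, pol)
  expect_equal(nrow(m$merged), nrow(a) + sum(!matched_b))
  expect_equal(sum(m$merged$replicate_count), nrow(a) + nrow(b))
})
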