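test_that("window GC on hand-checkable sequences", {
  expect_equal(window_gc(seq_tbl(s = "GCGCGCGC"), 4)$gc, c(1, 1))
  expect_equal(window_gc(seq_tbl(s = "ATGCATGC"), 4)$gc, c(0.5, 0.5))
  # trailing partial window dropped
  expect_equal(nrow(window_gc(seq_tbl(s = "ATGCATGCAT"), 4)), 2)
  # N-rich window invalidated; N excluded from the denominator elsewhere
  expect_warning(tr <- window_gc(seq_tbl(s = "GCNNNNNNGC"), 5,
                                 max_n_fraction = 0.5),
                 "No valid windows")
  expect_equal(tr$valid, c(FALSE, FALSE))
  tr2 <- window_gc(seq_tbl(s = "GCANNGCGCA"), 5, max_n_fraction = 0.5)
  expect_equal(tr2$gc[1], 2 / 3)  # GCANN: 2 GC of 3 ACGT
  expect_warning(window_gc(seq_tbl(s = "ACGT"), 100), "No valid windows")
})

test_that("window GC mean and SD match the binomial closed form", {
  withr::local_seed(41)
  p <- 0.42; W <- 5000
  s <- random_seq(1e6, prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2))
  tr <- window_gc(seq_tbl(g = s), W)
  sm <- gc_summary(tr)
  se <- sqrt(p * (1 - p) / (W * sm$n_windows))
  expect_lt(abs(sm$mean - p), 3 * se)
  expect_lt(abs(sm$sd - sqrt(p * (1 - p) / W)) / sqrt(p * (1 - p) / W), 0.10)
})

test_that("gc_summary matches a two-pass variance oracle and filters classes", {
  withr::local_seed(42)
  seqs <- seq_tbl(stats::setNames(replicate(6, random_seq(4000)),
                                  paste0("s", 1:6)))
  tr <- window_gc(seqs, 500)
  sm <- gc_summary(tr)
  gc <- tr$gc[tr$valid]
  m <- sum(gc) / length(gc)
  v <- sum((gc - m)^2) / (length(gc) - 1)  # two-pass
  expect_equal(sm$mean, m, tolerance = 1e-12)
  expect_equal(sm$sd, sqrt(v), tolerance = 1e-12)

  part <- tibble::tibble(seq_id = c("s1", "s2", "s3"),
                         class = c("macro", "macro", "Z"))
  sm_mac <- gc_summary(tr, part, "macro")
  expect_equal(sm_mac$n_windows, 16)  # 8 windows per 4 kbp sequence
  expect_error(gc_summary(tr, part, "micro"), "Fewer than 2")

  # all-equal windows have SD 0
  smc <- gc_summary(window_gc(seq_tbl(c = strrep("GCAT", 500)), 100))
  expect_equal(smc$sd, 0)
})

test_that("SD follows 1/sqrt(W) on homogeneous sequence and plateaus on isochores", {
  withr::local_seed(43)
  iid <- make_genome(2e6, gc_uniform(0.418), seed = 5)
  curve <- sd_vs_scale(seq_tbl(g = iid$seq), c(5000, 20000))
  expect_lt(abs(curve$sd[2] / curve$sd[1] - 0.5), 0.15 * 0.5)

  # block-isochore genome: between-block variance dominates at all scales
  blocks <- make_genome(2e6, gc_blocks(block_length = 2e5), seed = 6)
  bcurve <- sd_vs_scale(seq_tbl(g = blocks$seq), c(5000, 10000, 20000, 40000))
  expect_gt(isochore_contrast(bcurve), 0.8)
  icurve <- sd_vs_scale(seq_tbl(g = iid$seq), c(5000, 10000, 20000, 40000))
  expect_lt(isochore_contrast(icurve), 0.4)  # ~ sqrt(5/40) = 0.35 expected

  # constant-GC sequence: SD exactly 0 at every scale
  const <- sd_vs_scale(seq_tbl(c = strrep("GCAT", 2e4)), c(1000, 4000))
  expect_equal(const$sd, c(0, 0))

  expect_error(sd_vs_scale(seq_tbl(s = "ACGT"), c(10, 5)), "ascending")
})

test_that("component GC on hand-checkable input and union semantics", {
  seqs <- seq_tbl(s = "GGGGGAAAAA")
  cds <- tibble::tibble(seq_id = "s", start = 0L, end = 5L, category = "CDS")
  got <- component_gc(seqs, cds)
  expect_equal(got$gc, 1)
  expect_equal(got$bases, 5)
  comp <- complement_intervals(cds, seqs)
  expect_equal(component_gc(seqs, comp)$gc, 0)
  # duplicated intervals: identical to one copy
  dup <- rbind(cds, cds)
  expect_equal(component_gc(seqs, dup), got)
  # interval beyond the sequence end is named in the error
  bad <- tibble::tibble(seq_id = "s", start = 5L, end = 20L, category = "CDS")
  expect_error(component_gc(seqs, bad), "beyond sequence end")
})

test_that("component GC equals the per-base mask oracle on random data", {
  withr::local_seed(44)
  seqs_chr <- stats::setNames(replicate(4, random_seq(2000)), paste0("s", 1:4))
  seqs <- seq_tbl(seqs_chr)
  iv <- tibble::tibble(
    seq_id = sample(names(seqs_chr), 60, replace = TRUE),
    start = sample(0:1800, 60, replace = TRUE)
  )
  iv$end <- pmin(iv$start + sample(20:400, 60, replace = TRUE), 2000L)
  iv$category <- "repeat"
  got <- component_gc(seqs, iv)
  expect_equal(got$gc, oracle_masked_gc(seqs_chr, iv), tolerance = 1e-12)
  expect_equal(got$bases,
               oracle_union_bases(iv, lapply(seqs_chr, nchar)))
})

test_that("component GC over a partition of all bases reconstructs the whole", {
  withr::local_seed(45)
  seqs_chr <- stats::setNames(replicate(3, random_seq(3000)), paste0("s", 1:3))
  seqs <- seq_tbl(seqs_chr)
  iv <- tibble::tibble(seq_id = rep(names(seqs_chr), each = 2),
                       start = rep(c(0L, 1200L), 3),
                       end = rep(c(1200L, 3000L), 3),
                       category = rep(c("cat", "rest"), 3))
  got <- component_gc(seqs, iv)
  whole <- sum(got$gc * got$bases) / sum(got$bases)
  all_gc <- oracle_masked_gc(seqs_chr,
                             tibble::tibble(seq_id = names(seqs_chr),
                                            start = 0L, end = 3000L))
  expect_equal(whole, all_gc, tolerance = 1e-9)
})

test_that("component GC groups by chromosome class", {
  seqs <- seq_tbl(m1 = strrep("G", 100), z1 = strrep("A", 100))
  part <- tibble::tibble(seq_id = c("m1", "z1"), class = c("macro", "Z"))
  iv <- tibble::tibble(seq_id = c("m1", "z1"), start = 0L, end = 100L,
                       category = "CDS")
  got <- component_gc(seqs, iv, part)
  expect_equal(got$gc[got$class == "macro"], 1)
  expect_equal(got$gc[got$class == "Z"], 0)
})
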