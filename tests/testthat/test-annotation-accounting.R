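test_that("interval merging unions overlaps and book-ends", {
  iv <- tibble::tibble(seq_id = "s", start = c(0L, 5L), end = c(10L, 15L),
                       category = "LINE")
  m <- merge_intervals(iv)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  expect_equal(attr(m, "total_bases"), 15)

  disj <- tibble::tibble(seq_id = "s", start = c(0L, 10L), end = c(5L, 15L),
                         category = "LINE")
  expect_equal(attr(merge_intervals(disj), "total_bases"), 10)
  # book-ended intervals join
  be <- tibble::tibble(seq_id = "s", start = c(0L, 5L), end = c(5L, 9L),
                       category = "LINE")
  expect_equal(nrow(merge_intervals(be)), 1)
})

test_that("merging is idempotent, order-invariant, and matches the mask oracle", {
  withr::local_seed(51)
  iv <- tibble::tibble(
    seq_id = sample(paste0("s", 1:5), 10000, replace = TRUE),
    start = sample(0:49000, 10000, replace = TRUE)
  )
  iv$end <- iv$start + sample(1:500, 10000, replace = TRUE)
  iv$category <- sample(c("LINE", "SINE"), 10000, replace = TRUE)
  m1 <- merge_intervals(iv)
  m2 <- merge_intervals(iv[sample(nrow(iv)), ])
  expect_equal(m1, m2, ignore_attr = TRUE)
  expect_equal(merge_intervals(m1), m1, ignore_attr = TRUE)
  lens <- stats::setNames(rep(50000, 5), paste0("s", 1:5))
  expect_equal(interval_total_bases(iv),
               oracle_union_bases(iv, as.list(lens)))
  # per-category unions can only exceed the pooled union
  expect_gte(interval_total_bases(iv, by_category = TRUE),
             interval_total_bases(iv))
})

test_that("repeat ledger reproduces planted genome fractions", {
  withr::local_seed(52)
  asm <- make_assembly(n_scaffolds = 10, contig_length = c(2000, 8000),
                       gap_run = "none", seed = 9)
  total <- sum(asm$seqs$length)
  planted <- plant_repeats(asm$seqs, c(LINE = 0.122, SINE = 0.033), seed = 10)
  led <- repeat_fractions(planted$intervals, genome_bases = total)
  pc <- led$per_category
  expect_equal(pc$bases[pc$category == "LINE"],
               unname(planted$truth["LINE"]))
  expect_equal(round(pc$percent[pc$category == "LINE"], 1), 12.2)
  expect_equal(round(pc$percent[pc$category == "SINE"], 1), 3.3)
  # union cannot exceed the per-method sum
  expect_lte(led$grand_total$bases, sum(led$per_method$bases))
})

test_that("combined TE total excludes the tandem category", {
  iv <- tibble::tibble(seq_id = "s",
                       start = c(0L, 100L, 200L),
                       end = c(50L, 150L, 260L),
                       category = c("LINE", "tandem", "LINE"),
                       method = c("rm", "trf", "denovo"))
  led <- repeat_fractions(iv, genome_bases = 1000)
  expect_equal(led$combined_te$bases, 110)
  expect_equal(led$grand_total$bases, 160)
  expect_equal(led$combined_te$percent, 11)
  expect_equal(nrow(led$per_method), 3)
})

test_that("gene-model statistics agree with hand computation and reject overlap", {
  one <- tibble::tibble(gene_id = "g1", start = c(0L, 150L), end = c(100L, 250L))
  st <- gene_model_stats(one)
  expect_equal(st$mean_gene_length, 250)
  expect_equal(st$mean_mrna_length, 200)
  expect_equal(st$mean_exons_per_gene, 2)
  expect_equal(st$mean_exon_length, 100)
  expect_equal(st$mean_intron_length, 50)

  single <- tibble::tibble(gene_id = c("a", "b"), start = c(0L, 0L),
                           end = c(100L, 300L))
  st2 <- gene_model_stats(single)
  expect_equal(st2$single_exon_genes, 2)
  expect_true(is.na(st2$mean_intron_length))

  bad <- tibble::tibble(gene_id = "g", start = c(0L, 50L), end = c(100L, 150L))
  expect_error(gene_model_stats(bad), "Overlapping exons.*g")
})

test_that("gene-model means equal a flat-loop oracle on generated models", {
  gm <- make_gene_models(n_genes = 500, seed = 53)
  got <- gene_model_stats(gm$exons)
  # oracle: loop over the generator's own drawn lengths
  spans <- mrnas <- nexons <- numeric(0)
  exon_all <- intron_all <- numeric(0)
  for (tr in gm$truth) {
    el <- tr$exon_lengths; il <- tr$intron_lengths
    spans <- c(spans, sum(el) + sum(il))
    mrnas <- c(mrnas, sum(el))
    nexons <- c(nexons, length(el))
    exon_all <- c(exon_all, el)
    intron_all <- c(intron_all, il)
  }
  expect_equal(got$n_genes, 500)
  expect_equal(got$single_exon_genes, sum(nexons == 1))
  expect_equal(got$mean_gene_length, mean(spans))
  expect_equal(got$mean_mrna_length, mean(mrnas))
  expect_equal(got$mean_exons_per_gene, mean(nexons))
  expect_equal(got$mean_exon_length, mean(exon_all))
  expect_equal(got$mean_intron_length, mean(intron_all))
})

test_that("gene models round-trip from GFF3", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tsim\tgene\t1\t250\t.\t+\t.\tID=g1",
    "s1\tsim\tmRNA\t1\t250\t.\t+\t.\tID=t1;Parent=g1",
    "s1\tsim\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1",
    "s1\tsim\texon\t151\t250\t.\t+\t.\tID=e2;Parent=t1"
  ), gff)
  ex <- read_gene_models(gff)
  expect_equal(ex$gene_id, c("g1", "g1"))
  expect_equal(ex$start, c(0L, 150L))
  expect_equal(ex$end, c(100L, 250L))
  st <- gene_model_stats(ex)
  expect_equal(st$mean_intron_length, 50)
})

test_that("RPKM follows its unit definition and the closed form", {
  expect_equal(rpkm(1, 1000, 1e6), 1)
  expect_equal(rpkm(0, 500, 1e7), 0)
  expect_error(rpkm(1, 0, 1e6), "gene_length")
  expect_error(rpkm(1, 1000, 0), "mapped_total")
  ex <- make_expression(n_genes = 100, n_samples = 3, seed = 54)
  long <- rpkm_table(ex$counts, ex$mapped_totals)
  merged <- merge(as.data.frame(long), as.data.frame(ex$truth),
                  by = c("gene_id", "sample"))
  expect_equal(merged$rpkm.x, merged$rpkm.y, tolerance = 1e-12)
  # RPKM = 0 iff count = 0
  expect_equal(merged$rpkm.x == 0, merged$count.x == 0)
})

test_that("support ratios count strict exceedance and a combined any-sample row", {
  counts <- tibble::tibble(
    gene_id = paste0("g", 1:4), gene_length = 1000,
    s1 = c(0, 1, 10, 0), s2 = c(0, 0, 0, 2))
  long <- rpkm_table(counts, c(s1 = 1e6, s2 = 1e6))
  sup <- support_ratios(long, thresholds = c(0, 1, 5))
  get <- function(sm, th) sup$n_genes[sup$sample == sm & sup$threshold == th]
  expect_equal(get("s1", 0), 2)
  expect_equal(get("s2", 0), 1)
  expect_equal(get("Combined", 0), 3)
  expect_equal(get("Combined", 1), 2)  # strict: rpkm 1 does not exceed 1
  expect_equal(get("Combined", 5), 1)
  expect_equal(sup$percent[sup$sample == "Combined" & sup$threshold == 0], 75)
  # all-zero table
  z <- rpkm_table(tibble::tibble(gene_id = "g", gene_length = 100, s1 = 0),
                  c(s1 = 1e6))
  expect_true(all(support_ratios(z)$n_genes == 0))
})

test_that("combined counts dominate per-sample counts and decay with threshold", {
  ex <- make_expression(n_genes = 300, n_samples = 5, seed = 55)
  sup <- support_ratios(rpkm_table(ex$counts, ex$mapped_totals))
  for (th in unique(sup$threshold)) {
    comb <- sup$n_genes[sup$sample == "Combined" & sup$threshold == th]
    expect_true(all(sup$n_genes[sup$threshold == th] <= comb))
  }
  comb <- sup[sup$sample == "Combined", ]
  comb <- comb[order(comb$threshold), ]
  expect_true(all(diff(comb$n_genes) <= 0))
})
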