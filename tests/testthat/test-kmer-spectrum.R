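test_that("hand-countable spectra match", {
  s <- count_kmers("AAAA", 2)
  expect_equal(s$histogram,
               tibble::tibble(copy_number = 3L, n_kmers = 1))
  expect_equal(s$total_instances, 3)

  # windows containing or spanning N are skipped
  expect_equal(nrow(count_kmers("ACNGT", 3)$histogram), 0)
  expect_equal(count_kmers("ACNGT", 3)$total_instances, 0)

  # empty source is an empty spectrum, not an error
  expect_equal(count_kmers(character(0), 5)$total_instances, 0)
  expect_error(count_kmers("ACGT", 0), "k must")
  expect_error(count_kmers("ACGT", 32), "k must")
})

test_that("counting matches the brute-force enumeration oracle", {
  withr::local_seed(101)
  for (k in c(3, 5, 17)) {
    seqs <- replicate(5, random_seq(1000))
    # sprinkle Ns into one sequence to exercise window skipping
    seqs[1] <- paste0(substr(seqs[1], 1, 400), "NN", substr(seqs[1], 403, 1000))
    got <- count_kmers(seqs, k)
    want <- oracle_kmer_histogram(seqs, k)
    expect_equal(as.data.frame(got$histogram), want$histogram,
                 ignore_attr = TRUE)
    expect_equal(got$total_instances, want$total)
  }
})

test_that("spectrum is invariant under reverse-complementing the reads", {
  withr::local_seed(102)
  seqs <- replicate(20, random_seq(300))
  rc <- vapply(seqs, oracle_revcomp, character(1), USE.NAMES = FALSE)
  a <- count_kmers(seqs, 7)
  b <- count_kmers(rc, 7)
  expect_equal(a$histogram, b$histogram)
})

test_that("histogram mass equals the number of valid windows", {
  withr::local_seed(103)
  seqs <- replicate(10, random_seq(500, alphabet = c("A", "C", "G", "T", "N"),
                                   prob = c(rep(0.24, 4), 0.04)))
  s <- count_kmers(seqs, 9)
  expect_equal(sum(s$histogram$copy_number * s$histogram$n_kmers),
               s$total_instances)
})

test_that("mode finding resolves constructed two-peak spectra", {
  h <- tibble::tibble(
    copy_number = c(1:8, 20:30, 45:55),
    n_kmers = c(1e6, 5e5, 1e5, 1e4, 2e3, 500, 300, 250,
                seq(2000, 10000, length.out = 6),
                seq(9000, 2500, length.out = 5),
                seq(5000, 20000, length.out = 6),
                seq(19000, 4000, length.out = 5)))
  sp <- structure(list(k = 17, histogram = h,
                       total_instances = sum(h$copy_number * h$n_kmers),
                       n_distinct = sum(h$n_kmers)),
                  class = "kmer_spectrum")
  m <- find_modes(sp)
  expect_lt(abs(m$hom_mode - 50), 1)
  expect_lt(abs(m$het_mode - 25), 1)
  expect_true(m$error_valley < m$het_mode)
  expect_gt(m$het_hom_ratio, 0.4)
  expect_lt(m$het_hom_ratio, 0.6)
})

test_that("single-peak spectra yield a mode and no het peak", {
  sp <- structure(list(k = 17,
                       histogram = tibble::tibble(copy_number = c(1L, 10L),
                                                  n_kmers = c(5, 100)),
                       total_instances = 1005, n_distinct = 105),
                  class = "kmer_spectrum")
  m <- find_modes(sp)
  expect_equal(m$hom_mode, 10)
  expect_true(is.na(m$het_mode))

  # monotone histogram: mode over the whole range, with a warning
  mono <- structure(list(k = 17,
                         histogram = tibble::tibble(copy_number = 1:3,
                                                    n_kmers = c(9, 5, 2)),
                         total_instances = 25, n_distinct = 16),
                    class = "kmer_spectrum")
  expect_warning(mm <- find_modes(mono), "No local minimum")
  expect_true(mm$monotone)
})

test_that("depth and genome-size formulas follow their definitions", {
  # k = 1 collapses the correction factor; L = k collapses the denominator
  expect_equal(average_read_depth(7, 100, 1), 7)
  expect_equal(average_read_depth(10, 5, 5), 50)
  expect_error(average_read_depth(10, 17, 17 + 1), "read_length")
  expect_equal(estimate_genome_size(100, 10), 10)
  expect_error(estimate_genome_size(100, 0), "depth")
})

test_that("spectrum TSV round-trips", {
  withr::local_seed(104)
  sp <- count_kmers(replicate(10, random_seq(200)), 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f, 5)
  expect_equal(back$histogram$copy_number, sp$histogram$copy_number)
  expect_equal(back$histogram$n_kmers, sp$histogram$n_kmers)
  expect_equal(back$total_instances, sp$total_instances)
})

test_that("FASTQ sources feed the counter", {
  withr::local_seed(105)
  reads <- tibble::tibble(id = paste0("r", 1:10),
                          seq = replicate(10, random_seq(60)))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  a <- count_kmers(f, 11)
  b <- count_kmers(reads$seq, 11)
  expect_equal(a$histogram, b$histogram)
})
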