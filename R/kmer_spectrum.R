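#' Count canonical k-mers and build a spectrum
#'
#' Every window of length `k` containing only A/C/G/T is counted once under
#' its canonical form — the lexicographic minimum of the window and its
#' reverse complement — so both strands of a molecule contribute to a single
#' entity. Windows containing N or any other IUPAC ambiguity code are
#' skipped. The spectrum is the histogram of distinct canonical k-mers per
#' copy number (multiplicity): in a diploid read set, heterozygous
#' single-copy sequence forms a peak at half the copy number of homozygous
#' single-copy sequence.
#'
#' @param x Sequences: a character vector of DNA strings, a sequence table
#'   (from [read_fasta()] / [seq_tbl()]), or a path to a FASTA/FASTQ file.
#' @param k K-mer length, 1--31 (bounded so a 2-bit encoding fits one
#'   64-bit word).
#' @param max_copy Copy numbers above this are pooled into a single
#'   overflow row at `max_copy` (default 10000); deep-repeat tails are
#'   irrelevant to the single-copy modes and this bounds memory.
#' @return A `kmer_spectrum` object: list with `k`, `histogram` (tibble of
#'   `copy_number`, `n_kmers`), `total_instances` (number of valid k-mer
#'   windows consumed) and `n_distinct`.
#' @examples
#' count_kmers("AAAA", k = 2)  # canonical "AA" seen 3 times
#' @export
count_kmers <- function(x, k, max_copy = 10000) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 31) {
    abort("k must be a single integer in [1, 31]")
  }
  seqs <- sequences_of(x)
  res <- kmer_spectrum_cpp(toupper(seqs), as.integer(k))
  hist <- tibble(copy_number = res$copy_number, n_kmers = res$n_kmers)
  if (any(hist$copy_number > max_copy)) {
    over <- hist$copy_number > max_copy
    pooled <- sum(hist$n_kmers[over])
    hist <- hist[!over, ]
    i <- match(max_copy, hist$copy_number)
    if (is.na(i)) {
      hist <- bind_rows(hist, tibble(copy_number = as.integer(max_copy),
                                     n_kmers = pooled))
    } else {
      hist$n_kmers[i] <- hist$n_kmers[i] + pooled
    }
    hist <- arrange(hist, .data$copy_number)
  }
  structure(
    list(k = as.integer(k), histogram = hist,
         total_instances = res$total_instances,
         n_distinct = res$n_distinct),
    class = "kmer_spectrum"
  )
}

# accept character vector, sequence tibble, or FASTA/FASTQ path
sequences_of <- function(x) {
  if (is.data.frame(x)) return(x$seq)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(x, format = fmt)))
  }
  if (is.character(x)) return(x)
  abort("Unsupported sequence source")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("Canonical k-mer spectrum (k = ", x$k, ")\n", sep = "")
  cat("  distinct k-mers: ", format(x$n_distinct, big.mark = ","), "\n", sep = "")
  cat("  k-mer instances: ", format(x$total_instances, big.mark = ","), "\n", sep = "")
  cat("  copy numbers:    ", min(x$histogram$copy_number), "..",
      max(x$histogram$copy_number), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.kmer_spectrum <- function(x, ...) x$histogram

#' @export
glance.kmer_spectrum <- function(x, ...) {
  tibble(k = x$k, n_distinct = x$n_distinct,
         total_instances = x$total_instances,
         max_copy_number = max(x$histogram$copy_number))
}

#' Write / read a k-mer spectrum as two-column TSV
#'
#' The on-disk dialect is the plain `copy_number<TAB>distinct_kmers`
#' histogram table that standard k-mer counters export.
#'
#' @param spectrum A `kmer_spectrum` object.
#' @param path File path.
#' @return `write_spectrum`: `path` invisibly; `read_spectrum`: a
#'   `kmer_spectrum` object (with `total_instances` reconstructed as
#'   the sum of copy number times count).
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(spectrum$histogram, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @param k K-mer length the histogram was computed at.
#' @export
read_spectrum <- function(path, k) {
  h <- readr::read_tsv(path, col_names = c("copy_number", "n_kmers"),
                       col_types = "id", progress = FALSE)
  structure(
    list(k = as.integer(k), histogram = as_tibble(h),
         total_instances = sum(h$copy_number * h$n_kmers),
         n_distinct = sum(h$n_kmers)),
    class = "kmer_spectrum"
  )
}

#' Locate the modes of a k-mer spectrum
#'
#' Detects the structure a diploid short-read spectrum shows: a
#' sequencing-error spike at low copy number, a valley, then a heterozygous
#' peak at roughly half the copy number of the homozygous peak. The
#' histogram is smoothed with a centred moving average of window 3 before
#' peak finding; argmax ties break toward the lower copy number. Each
#' detected peak is then refined by fitting a parabola through the three
#' points around it and reporting the vertex, which allows fractional modes.
#'
#' @param spectrum A `kmer_spectrum` object.
#' @param min_copy_floor Lower bound for the error valley (default 2;
#'   copy number 1 is dominated by sequencing error in real data).
#' @return A `spectrum_modes` object with fields `error_valley` (integer
#'   copy number of the first local minimum), `het_mode` and `hom_mode`
#'   (possibly fractional copy numbers; `het_mode` is `NA` when no
#'   heterozygous peak exists), and `monotone` (TRUE when no valley was
#'   found and the mode was taken over the whole range).
#' @export
find_modes <- function(spectrum, min_copy_floor = 2) {
  h <- spectrum$histogram
  if (nrow(h) == 0) abort("Cannot find modes of an empty spectrum")
  max_cn <- max(h$copy_number)
  y <- numeric(max_cn)
  y[h$copy_number] <- h$n_kmers
  ys <- smooth_ma3(y)

  n <- length(ys)
  valley <- NA_integer_
  if (n >= 3) {
    for (i in max(2L, as.integer(min_copy_floor)):(n - 1L)) {
      # plateau-tolerant local minimum: no higher than either neighbour,
      # strictly lower than at least one
      if (ys[i] <= ys[i - 1] && ys[i] <= ys[i + 1] &&
          (ys[i] < ys[i - 1] || ys[i] < ys[i + 1])) { valley <- i; break }
    }
  }
  monotone <- is.na(valley)
  if (monotone) {
    warn("No local minimum found in spectrum; taking mode over whole range")
    search <- seq_len(n)
    valley_count <- 0
  } else {
    search <- seq.int(valley + 1L, n)
    valley_count <- ys[valley]
  }
  hom_i <- search[which.max(ys[search])]
  hom_mode <- parabolic_vertex(ys, hom_i)

  # heterozygous peak: the local maximum below the homozygous peak nearest
  # hom/2, taller than the valley count (on error-free read sets the first
  # local minimum is the het-hom dip itself, so the het peak may sit below
  # the detected valley)
  het_mode <- NA_real_
  if (!monotone && hom_i >= 3) {
    cand <- integer()
    for (i in 2L:(hom_i - 1L)) {
      if (ys[i] >= ys[i - 1] && ys[i] >= ys[i + 1] && ys[i] > valley_count) {
        cand <- c(cand, i)
      }
    }
    if (length(cand) > 0) {
      best <- cand[which.min(abs(cand - hom_mode / 2))]
      het_mode <- parabolic_vertex(ys, best)
    }
  }

  ratio <- if (is.na(het_mode)) NA_real_ else het_mode / hom_mode
  if (!is.na(ratio) && (ratio < 0.4 || ratio > 0.6)) {
    warn(sprintf(
      "het/hom mode ratio %.3f outside [0.4, 0.6]; spectrum may not be a simple diploid",
      ratio))
  }
  structure(
    list(error_valley = valley, het_mode = het_mode, hom_mode = hom_mode,
         het_hom_ratio = ratio, monotone = monotone),
    class = "spectrum_modes"
  )
}

# centred moving average, window 3; ends average the available neighbours
smooth_ma3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  out <- (c(y[-1], 0) + y + c(0, y[-n]))
  den <- rep(3, n); den[1] <- 2; den[n] <- 2
  out / den
}

# vertex of the parabola through (i-1, y[i-1]), (i, y[i]), (i+1, y[i+1])
parabolic_vertex <- function(y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) return(as.numeric(i))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(as.numeric(i))
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

#' @export
print.spectrum_modes <- function(x, ...) {
  cat("Spectrum modes\n")
  cat("  error valley: ", x$error_valley, "\n", sep = "")
  cat("  het mode:     ", format(x$het_mode), "\n", sep = "")
  cat("  hom mode:     ", format(x$hom_mode), "\n", sep = "")
  if (!is.na(x$het_hom_ratio)) {
    cat("  het/hom:      ", sprintf("%.3f", x$het_hom_ratio), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.spectrum_modes <- function(x, ...) {
  tibble(error_valley = x$error_valley, het_mode = x$het_mode,
         hom_mode = x$hom_mode, het_hom_ratio = x$het_hom_ratio,
         monotone = x$monotone)
}

#' Average read depth from a spectrum mode
#'
#' A k-mer of copy number `mode` in the read set was seen once per read
#' covering it; a read of length L contributes L - k + 1 k-mer windows, so
#' the per-base read depth is `mode * L / (L - k + 1)`.
#'
#' @param mode Copy number of the homozygous single-copy peak.
#' @param read_length Read length L in bp.
#' @param k K-mer length used for the spectrum.
#' @return Depth in fold coverage, unrounded.
#' @examples
#' average_read_depth(48.5, 125, 17)  # 55.62 to 2 decimals
#' @export
average_read_depth <- function(mode, read_length, k) {
  if (any(mode <= 0)) abort("mode must be > 0")
  if (any(read_length < k) || any(k < 1)) {
    abort("read_length must be at least k and k must be >= 1")
  }
  mode * read_length / (read_length - k + 1)
}

#' Genome size from total sequenced bases and depth
#'
#' @param total_bases Total read bases in bp.
#' @param depth Average read depth in fold (e.g. from
#'   [average_read_depth()]).
#' @return Genome size in bp, unrounded.
#' @examples
#' estimate_genome_size(98.35e9, average_read_depth(48.5, 125, 17)) / 1e9
#' @export
estimate_genome_size <- function(total_bases, depth) {
  if (any(depth <= 0)) abort("depth must be > 0")
  total_bases / depth
}

#' One-call genome-size estimate from a spectrum
#'
#' Composes [find_modes()], [average_read_depth()] and
#' [estimate_genome_size()].
#'
#' @param spectrum A `kmer_spectrum` object.
#' @param read_length Read length in bp.
#' @param total_bases Total read bases in bp.
#' @param min_copy_floor Passed to [find_modes()].
#' @return One-row tibble: `k`, `hom_mode`, `het_mode`, `depth`,
#'   `genome_size`.
#' @export
genome_size_from_spectrum <- function(spectrum, read_length, total_bases,
                                      min_copy_floor = 2) {
  modes <- find_modes(spectrum, min_copy_floor = min_copy_floor)
  depth <- average_read_depth(modes$hom_mode, read_length, spectrum$k)
  tibble(k = spectrum$k, hom_mode = modes$hom_mode, het_mode = modes$het_mode,
         depth = depth,
         genome_size = estimate_genome_size(total_bases, depth))
}

#' Plot a k-mer spectrum
#'
#' @param object A `kmer_spectrum` object.
#' @param modes Optional `spectrum_modes` to mark as vertical lines.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.kmer_spectrum <- function(object, modes = NULL, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$copy_number, y = .data$n_kmers)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "k-mer copy number", y = "distinct k-mers",
                  title = sprintf("Canonical %d-mer spectrum", object$k)) +
    ggplot2::theme_minimal()
  if (!is.null(modes)) {
    v <- c(modes$het_mode, modes$hom_mode)
    p <- p + ggplot2::geom_vline(xintercept = v[!is.na(v)], linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
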