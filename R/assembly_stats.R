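#' Split scaffolds into contigs at N-run gaps
#'
#' Each scaffold is split at every maximal run of at least `min_gap_run`
#' consecutive N characters; zero-length fragments are discarded. With the
#' default `min_gap_run = 1` every N is a gap, so contig bases plus N bases
#' equal scaffold bases exactly. Some assemblers' "scaftig" conventions use
#' longer thresholds (e.g. 10).
#'
#' @param seqs Sequence table ([read_fasta()] / [seq_tbl()]) or character
#'   vector.
#' @param min_gap_run Minimum N-run length treated as a gap (default 1).
#' @return A sequence tibble of contigs, ids formed as
#'   `<scaffold_id>_<ordinal>`.
#' @examples
#' scaffolds_to_contigs(seq_tbl(s = "ACGTNNNACGT"))
#' @export
scaffolds_to_contigs <- function(seqs, min_gap_run = 1) {
  if (min_gap_run < 1) abort("min_gap_run must be >= 1")
  seqs <- as_seq_tbl(seqs)
  pieces <- purrr::map(seqs$seq, split_on_n_runs_cpp,
                       min_run = as.integer(min_gap_run))
  n_each <- lengths(pieces)
  ids <- unlist(purrr::map2(seqs$id, n_each, function(id, n) {
    if (n == 0) character() else paste0(id, "_", seq_len(n))
  }), use.names = FALSE)
  out <- unlist(pieces, use.names = FALSE)
  if (length(out) == 0) {
    return(tibble(id = character(), seq = character(), length = integer(),
                  mask = list()))
  }
  seq_tbl(stats::setNames(out, ids))
}

#' Nx ladder of a length set
#'
#' Sort lengths descending; the Nx size is the length at which the
#' cumulative sum first reaches x per cent of the total, and the Nx count
#' is the number of sequences up to and including that one. N50 is the
#' familiar special case: sequences at least N50 long hold at least half
#' of the total bases.
#'
#' @param lengths Positive sequence lengths in bp.
#' @param x_values Percentages in (0, 100); default 50, 60, 70, 80, 90.
#' @return Tibble with columns `x`, `size` (bp), `count`.
#' @examples
#' nx_ladder(c(8, 5, 4, 3), 50)  # size 5, count 2
#' @export
nx_ladder <- function(lengths, x_values = c(50, 60, 70, 80, 90)) {
  if (length(lengths) == 0) abort("lengths must be non-empty")
  if (any(lengths <= 0)) abort("lengths must all be > 0")
  if (any(x_values <= 0 | x_values >= 100)) abort("x_values must lie in (0, 100)")
  sorted <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(as.numeric(sorted))
  total <- csum[length(csum)]
  idx <- vapply(x_values, function(x) {
    which(csum >= x / 100 * total)[1]
  }, integer(1))
  tibble(x = x_values, size = sorted[idx], count = idx)
}

#' Gap statistics of a sequence set
#'
#' @param seqs Sequence table or character vector.
#' @return One-row tibble: `gap_bases` (total N characters), `total_bases`,
#'   `gap_ratio` (fraction of bases that are N; 0 with a warning for an
#'   empty set).
#' @export
gap_stats <- function(seqs) {
  seqs <- as_seq_tbl(seqs)
  total <- sum(as.numeric(seqs$length))
  if (total == 0) {
    warn("Empty sequence set; gap ratio undefined, reporting 0")
    return(tibble(gap_bases = 0, total_bases = 0, gap_ratio = 0))
  }
  gaps <- sum(stringr::str_count(seqs$seq, stringr::fixed("N")))
  tibble(gap_bases = gaps, total_bases = total, gap_ratio = gaps / total)
}

#' Summarise an assembly: Nx ladder, totals, threshold counts, gaps
#'
#' Produces the standard assembly report at both scaffold and contig level:
#' the Nx size/count ladder, longest sequence, total size, counts of
#' sequences at or above length thresholds, and the gap ratio (fraction of
#' scaffold bases that are N). Contigs are derived by splitting scaffolds
#' at N runs via [scaffolds_to_contigs()].
#'
#' @param seqs Scaffold sequence table or character vector.
#' @param thresholds Length thresholds for the count rows (default 100 and
#'   2000 bp).
#' @param x_values Nx percentages (default 50--90 by 10).
#' @param min_gap_run Gap definition passed to [scaffolds_to_contigs()].
#' @return An `assembly_summary` object; `tidy()` renders the Table-style
#'   layout, `glance()` the headline numbers.
#' @export
summarize_assembly <- function(seqs, thresholds = c(100, 2000),
                               x_values = c(50, 60, 70, 80, 90),
                               min_gap_run = 1) {
  seqs <- as_seq_tbl(seqs)
  contigs <- scaffolds_to_contigs(seqs, min_gap_run = min_gap_run)
  structure(
    list(
      scaffold = level_summary(seqs, thresholds, x_values),
      contig = level_summary(contigs, thresholds, x_values),
      gaps = gap_stats(seqs),
      thresholds = thresholds,
      min_gap_run = min_gap_run
    ),
    class = "assembly_summary"
  )
}

level_summary <- function(seqs, thresholds, x_values) {
  lens <- seqs$length
  if (length(lens) == 0) {
    return(list(nx = tibble(x = x_values, size = NA_real_, count = NA_integer_),
                longest = 0, total = 0, n = 0,
                threshold_counts = tibble(threshold = thresholds, count = 0L)))
  }
  list(
    nx = nx_ladder(lens, x_values),
    longest = max(lens),
    total = sum(as.numeric(lens)),
    n = length(lens),
    threshold_counts = tibble(
      threshold = thresholds,
      count = vapply(thresholds, function(t) sum(lens >= t), integer(1))
    )
  )
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly summary (gap = run of >=", x$min_gap_run, "N)\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.assembly_summary <- function(x, ...) {
  row <- function(stat, cs, ss, cn = NA_integer_, sn = NA_integer_) {
    tibble(statistic = stat, contig_size = cs, scaffold_size = ss,
           contig_count = cn, scaffold_count = sn)
  }
  nx <- purrr::map2_dfr(
    rev(seq_len(nrow(x$scaffold$nx))), rev(x$scaffold$nx$x),
    function(i, xv) {
      row(paste0("N", xv), x$contig$nx$size[i], x$scaffold$nx$size[i],
          x$contig$nx$count[i], x$scaffold$nx$count[i])
    })
  thr <- purrr::map_dfr(seq_along(x$thresholds), function(i) {
    row(paste0(">=", x$thresholds[i], " bp"), NA_real_, NA_real_,
        x$contig$threshold_counts$count[i], x$scaffold$threshold_counts$count[i])
  })
  bind_rows(
    nx,
    row("Longest", x$contig$longest, x$scaffold$longest),
    row("Total size", x$contig$total, x$scaffold$total),
    thr,
    row("Gap ratio (%)", 0, 100 * x$gaps$gap_ratio)
  )
}

#' @export
glance.assembly_summary <- function(x, ...) {
  n50s <- x$scaffold$nx[x$scaffold$nx$x == 50, ]
  n50c <- x$contig$nx[x$contig$nx$x == 50, ]
  tibble(
    n_scaffolds = x$scaffold$n, n_contigs = x$contig$n,
    scaffold_total = x$scaffold$total, contig_total = x$contig$total,
    scaffold_n50 = if (nrow(n50s)) n50s$size else NA_real_,
    contig_n50 = if (nrow(n50c)) n50c$size else NA_real_,
    longest_scaffold = x$scaffold$longest,
    gap_bases = x$gaps$gap_bases, gap_ratio = x$gaps$gap_ratio
  )
}

#' Plot the cumulative-length curve of an assembly
#'
#' Cumulative assembly fraction against sequence rank (longest first), the
#' curve from which every Nx statistic reads off.
#'
#' @param object An `assembly_summary` or a numeric vector of lengths.
#' @param level `"scaffold"` or `"contig"` (for `assembly_summary` input).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
plot_nx_curve <- function(object, level = c("scaffold", "contig"), ...) {
  level <- match.arg(level)
  if (inherits(object, "assembly_summary")) {
    nx <- object[[level]]$nx
    dat <- tibble(x = nx$x, size = nx$size)
  } else {
    sorted <- sort(object, decreasing = TRUE)
    dat <- tibble(x = 100 * cumsum(as.numeric(sorted)) / sum(as.numeric(sorted)),
                  size = sorted)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$size)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cumulative assembly fraction (%)",
                  y = "sequence length (bp)") +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}
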