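#' GC content in non-overlapping windows
#'
#' Windows tile each sequence from its origin; the trailing partial window
#' is dropped (not rescaled) so every window has equal length and SDs are
#' comparable across scales. Per window,
#' `gc = (#G + #C) / (#A + #C + #G + #T)`: non-ACGT characters are
#' excluded from the denominator rather than counted as AT, so assembly
#' gaps do not deflate GC. A window whose non-ACGT fraction exceeds
#' `max_n_fraction` is marked invalid and carries no GC value.
#'
#' @param seqs Sequence table or character vector.
#' @param window_size Window size in bp.
#' @param max_n_fraction Maximum tolerated non-ACGT fraction per window
#'   (default 0.5).
#' @return A tibble (`seq_id`, `start`, `end`, `gc`, `valid`) with a
#'   `window_size` attribute; windows never span sequences.
#' @examples
#' window_gc(seq_tbl(s = "GCGCGCGC"), 4)
#' @export
window_gc <- function(seqs, window_size, max_n_fraction = 0.5) {
  if (window_size < 1) abort("window_size must be >= 1")
  if (max_n_fraction < 0 || max_n_fraction > 1) {
    abort("max_n_fraction must lie in [0, 1]")
  }
  seqs <- as_seq_tbl(seqs)
  rows <- purrr::map2(seqs$id, seqs$seq, function(id, s) {
    cnt <- window_base_counts_cpp(s, window_size)
    n_win <- length(cnt$gc)
    if (n_win == 0) return(NULL)
    start <- (seq_len(n_win) - 1L) * window_size
    valid <- (window_size - cnt$acgt) / window_size <= max_n_fraction &
      cnt$acgt > 0
    tibble(seq_id = id, start = start, end = start + window_size,
           gc = ifelse(valid, cnt$gc / cnt$acgt, NA_real_), valid = valid)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0 || !any(out$valid)) {
    warn("No valid windows (window_size may exceed every sequence length)")
    if (nrow(out) == 0) {
      out <- tibble(seq_id = character(), start = integer(), end = integer(),
                    gc = numeric(), valid = logical())
    }
  }
  attr(out, "window_size") <- window_size
  out
}

#' Mean and SD of window GC, optionally within a chromosome class
#'
#' @param track Window table from [window_gc()].
#' @param partition Optional partition tibble ([read_partition()]).
#' @param class_filter Optional chromosome class (or classes) to restrict
#'   to, e.g. `"macro"`.
#' @return One-row tibble: `mean`, `sd` (n-1 denominator), `n_windows`,
#'   `window_size`.
#' @export
gc_summary <- function(track, partition = NULL, class_filter = NULL) {
  w <- attr(track, "window_size")
  if (!is.null(class_filter)) {
    cls <- partition_lookup(partition, track$seq_id)
    track <- track[cls %in% class_filter, ]
  }
  gc <- track$gc[track$valid]
  if (length(gc) < 2) {
    abort("Fewer than 2 valid windows; SD undefined")
  }
  tibble(mean = mean(gc), sd = stats::sd(gc), n_windows = length(gc),
         window_size = if (is.null(w)) NA_real_ else w)
}

#' Window-GC standard deviation across spatial scales
#'
#' Computes the SD of window GC at a ladder of window sizes. On a
#' compositionally homogeneous (i.i.d.) sequence the SD decays as
#' 1/sqrt(W) with window size W; a genome organised into isochores —
#' long blocks of distinct GC — holds its between-block variance, so the
#' curve plateaus. The plateau-versus-decay contrast is the isochore
#' signature.
#'
#' @param seqs Sequence table or character vector.
#' @param window_sizes Ascending window sizes in bp; defaults to the
#'   5--320 kbp doubling ladder.
#' @param partition,class_filter Optional class restriction as in
#'   [gc_summary()].
#' @param max_n_fraction Window validity threshold as in [window_gc()].
#' @return Tibble (`window_size`, `mean`, `sd`, `n_windows`).
#' @export
sd_vs_scale <- function(seqs,
                        window_sizes = c(5, 10, 20, 40, 80, 160, 320) * 1000,
                        partition = NULL, class_filter = NULL,
                        max_n_fraction = 0.5) {
  if (length(window_sizes) == 0 || is.unsorted(window_sizes, strictly = TRUE)) {
    abort("window_sizes must be non-empty and strictly ascending")
  }
  seqs <- as_seq_tbl(seqs)
  purrr::map_dfr(window_sizes, function(w) {
    tr <- window_gc(seqs, w, max_n_fraction = max_n_fraction)
    s <- gc_summary(tr, partition = partition, class_filter = class_filter)
    tibble(window_size = w, mean = s$mean, sd = s$sd, n_windows = s$n_windows)
  })
}

#' Isochore contrast of a scale curve
#'
#' Ratio of the SD at the largest window size to the SD at the smallest.
#' Values near 1 indicate a plateau (isochore-like structure at or beyond
#' the largest scale); values near the homogeneous-sequence expectation
#' `sqrt(w_min / w_max)` indicate no long-range structure.
#'
#' @param curve Tibble from [sd_vs_scale()].
#' @return A single ratio.
#' @export
isochore_contrast <- function(curve) {
  curve <- arrange(curve, .data$window_size)
  curve$sd[nrow(curve)] / curve$sd[1]
}

#' GC content of genome components by chromosome class
#'
#' For each chromosome class and annotation category, GC is computed over
#' the union of the category's bases on that class: overlapping intervals
#' of one category are deduplicated by union before counting, so a base
#' annotated twice contributes once.
#'
#' @param seqs Sequence table.
#' @param intervals Interval tibble (`seq_id`, `start`, `end`,
#'   `category`), 0-based half-open.
#' @param partition Optional partition tibble; without one every sequence
#'   is `unassigned`.
#' @return Tibble (`class`, `category`, `bases` in the union, `gc`).
#' @export
component_gc <- function(seqs, intervals, partition = NULL) {
  seqs <- as_seq_tbl(seqs)
  validate_intervals(intervals, seqs)
  intervals <- mutate(intervals,
                      class = partition_lookup(partition, .data$seq_id))
  seq_str <- stats::setNames(seqs$seq, seqs$id)
  grp <- dplyr::group_split(group_by(intervals, .data$class, .data$category))
  purrr::map_dfr(grp, function(g) {
    tot <- c(gc = 0, acgt = 0)
    for (sid in unique(g$seq_id)) {
      gi <- g[g$seq_id == sid, ]
      r <- IRanges::reduce(IRanges::IRanges(start = gi$start + 1L, end = gi$end))
      pieces <- substring(seq_str[[sid]], IRanges::start(r), IRanges::end(r))
      for (p in pieces) {
        cnt <- base_counts_cpp(p)
        tot <- tot + cnt[c("gc", "acgt")]
      }
    }
    tibble(class = g$class[1], category = g$category[1],
           bases = sum(g$end - g$start) -
             overlap_excess(g),
           gc = if (tot[["acgt"]] > 0) tot[["gc"]] / tot[["acgt"]] else NA_real_)
  })
}

# bases counted more than once by raw interval sums (union correction)
overlap_excess <- function(g) {
  raw <- sum(as.numeric(g$end - g$start))
  merged <- sum(purrr::map_dbl(unique(g$seq_id), function(sid) {
    gi <- g[g$seq_id == sid, ]
    r <- IRanges::reduce(IRanges::IRanges(start = gi$start + 1L, end = gi$end))
    sum(as.numeric(IRanges::width(r)))
  }))
  raw - merged
}

#' Complement of an interval set over a sequence table
#'
#' Returns the unannotated remainder of each sequence, useful as the
#' baseline category in [component_gc()] breakdowns.
#'
#' @param intervals Interval tibble.
#' @param seqs Sequence table defining the universe.
#' @param category Label for the emitted intervals (default
#'   `"complement"`).
#' @return Interval tibble covering every base not in `intervals`.
#' @export
complement_intervals <- function(intervals, seqs, category = "complement") {
  seqs <- as_seq_tbl(seqs)
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    sid <- seqs$id[i]
    gi <- intervals[intervals$seq_id == sid, ]
    if (nrow(gi) == 0) {
      return(tibble(seq_id = sid, start = 0L, end = seqs$length[i],
                    category = category))
    }
    r <- IRanges::reduce(IRanges::IRanges(start = gi$start + 1L, end = gi$end))
    gaps <- IRanges::gaps(r, start = 1L, end = seqs$length[i])
    if (length(gaps) == 0) {
      return(tibble(seq_id = character(), start = integer(), end = integer(),
                    category = character()))
    }
    tibble(seq_id = sid, start = IRanges::start(gaps) - 1L,
           end = IRanges::end(gaps), category = category)
  })
}

#' Plot SD-versus-scale curves
#'
#' @param curves A tibble from [sd_vs_scale()], or several row-bound
#'   together with a `label` column distinguishing them.
#' @param ... Ignored.
#' @return A ggplot with log2 window-size axis.
#' @export
plot_sd_scale <- function(curves, ...) {
  aes <- if ("label" %in% names(curves)) {
    ggplot2::aes(x = .data$window_size, y = .data$sd, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$window_size, y = .data$sd)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(curves$window_size),
                                labels = function(b) paste0(b / 1000, "k")) +
    ggplot2::labs(x = "window size (bp)", y = "SD of window GC") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of window GC
#'
#' @param track Window table from [window_gc()].
#' @param binwidth Histogram bin width on the GC fraction axis.
#' @return A ggplot.
#' @export
plot_gc_distribution <- function(track, binwidth = 0.01) {
  ggplot2::ggplot(track[track$valid, ], ggplot2::aes(x = .data$gc)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "window GC fraction", y = "windows") +
    ggplot2::theme_minimal()
}
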