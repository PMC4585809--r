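# Independent oracles used across the suite. These deliberately use naive
# string/vector implementations so they share no code path with the package.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# brute-force canonical k-mer tally: enumerate every window, skip windows
# with non-ACGT characters, canonicalise by string comparison, count in a
# plain table
oracle_kmer_histogram <- function(seqs, k) {
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1)
    w <- substring(s, starts, starts + k - 1)
    w <- w[!grepl("[^ACGT]", w)]
    rc <- vapply(w, oracle_revcomp, character(1), USE.NAMES = FALSE)
    ifelse(w <= rc, w, rc)
  })
  kmers <- unlist(per_seq, use.names = FALSE)
  if (length(kmers) == 0) {
    return(list(histogram = data.frame(copy_number = integer(),
                                       n_kmers = numeric()),
                total = 0))
  }
  copy <- table(kmers)
  hist <- as.data.frame(table(as.integer(copy)), stringsAsFactors = FALSE)
  names(hist) <- c("copy_number", "n_kmers")
  hist$copy_number <- as.integer(hist$copy_number)
  hist$n_kmers <- as.numeric(hist$n_kmers)
  list(histogram = hist[order(hist$copy_number), ], total = length(kmers))
}

# Nx by explicit cumulative scan
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(as.numeric(s))
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= x / 100 * total) return(list(size = s[i], count = i))
  }
}

# per-base boolean mask: total covered bases of an interval set
oracle_union_bases <- function(intervals, seq_lengths) {
  total <- 0
  for (sid in names(seq_lengths)) {
    mask <- logical(seq_lengths[[sid]])
    g <- intervals[intervals$seq_id == sid, ]
    for (i in seq_len(nrow(g))) {
      mask[(g$start[i] + 1):g$end[i]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# GC of the union of intervals, by painting a per-base mask
oracle_masked_gc <- function(seqs_chr, intervals) {
  gc <- 0; acgt <- 0
  for (sid in names(seqs_chr)) {
    s <- strsplit(seqs_chr[[sid]], "")[[1]]
    mask <- logical(length(s))
    g <- intervals[intervals$seq_id == sid, ]
    for (i in seq_len(nrow(g))) mask[(g$start[i] + 1):g$end[i]] <- TRUE
    sel <- s[mask]
    gc <- gc + sum(sel %in% c("G", "C"))
    acgt <- acgt + sum(sel %in% c("A", "C", "G", "T"))
  }
  gc / acgt
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
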