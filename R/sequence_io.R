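#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased on input. Soft-masked (lowercase) stretches are
#' preserved as per-record run tables in the `mask` list-column, so
#' repeat-masked fractions remain recoverable after case folding. All
#' coordinates in this package are 0-based half-open.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A tibble with one row per record and columns `id` (first
#'   whitespace-delimited token of the header), `seq` (uppercase residues),
#'   `length` (bp), and `mask` (list-column of tibbles with `start`/`end`
#'   columns giving soft-masked runs, 0-based half-open).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTacgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA in '", path, "': ", conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    abort(paste0("Empty FASTA file (no records): ", path))
  }
  raw <- unname(as.character(set))
  ids <- stringr::str_extract(names(set), "^\\S+")
  if (any(is.na(ids)) || any(ids == "")) {
    bad <- which(is.na(ids) | ids == "")[1]
    abort(paste0("Malformed FASTA header at record ", bad, " in '", path, "'"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sequence id in '", path, "': ",
                 ids[duplicated(ids)][1]))
  }
  mask <- purrr::map(raw, soft_mask_runs)
  tibble(id = ids, seq = toupper(raw),
         length = nchar(raw), mask = mask)
}

# 0-based half-open runs of lowercase characters in one raw sequence
soft_mask_runs <- function(s) {
  m <- gregexpr("[a-z]+", s, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  tibble(start = start, end = start + attr(m, "match.length"))
}

#' Write a sequence table to FASTA
#'
#' Soft-mask runs recorded in the `mask` column are re-applied as lowercase,
#' so `write_fasta(read_fasta(f))` round-trips masked input. Lines are
#' wrapped at a fixed width.
#'
#' @param seqs Sequence table as returned by [read_fasta()] or [seq_tbl()].
#' @param path Output path.
#' @param width Line-wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(width >= 1)
  seqs <- as_seq_tbl(seqs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$seq[i]
    msk <- seqs$mask[[i]]
    if (!is.null(msk) && nrow(msk) > 0) {
      for (j in seq_len(nrow(msk))) {
        piece <- substr(s, msk$start[j] + 1L, msk$end[j])
        substr(s, msk$start[j] + 1L, msk$end[j]) <- tolower(piece)
      }
    }
    writeLines(paste0(">", seqs$id[i]), con)
    n <- nchar(s)
    if (n == 0) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Build a sequence table from named character strings
#'
#' Convenience constructor for the tabular sequence representation used
#' throughout the package (columns `id`, `seq`, `length`, `mask`).
#'
#' @param ... Named DNA strings, or a single named character vector.
#' @return A sequence tibble.
#' @examples
#' seq_tbl(s1 = "ACGT", s2 = "GGCC")
#' @export
seq_tbl <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("All sequences must be named")
  }
  tibble(id = names(x), seq = toupper(unname(x)),
         length = nchar(unname(x)),
         mask = purrr::map(unname(x), soft_mask_runs))
}

as_seq_tbl <- function(x) {
  if (is.character(x)) return(seq_tbl(x))
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (!"length" %in% names(x)) x$length <- nchar(x$seq)
  if (!"mask" %in% names(x)) {
    x$mask <- purrr::map(seq_len(nrow(x)),
                         function(i) tibble(start = integer(), end = integer()))
  }
  as_tibble(x)
}

#' Read genomic intervals from BED, GFF3 or RepeatMasker output
#'
#' All dialects are normalised to 0-based half-open coordinates (BED is
#' native; GFF3 and RepeatMasker `.out` are 1-based inclusive and are
#' shifted). The category label is taken from the dialect's class/feature
#' column: BED column 4, GFF3 column 3 (the feature type), RepeatMasker
#' column 11 (the repeat class/family).
#'
#' @param path Input file.
#' @param dialect One of `"bed"`, `"gff3"`, `"repeatmasker"`.
#' @return A tibble with columns `seq_id`, `start`, `end`, `category`.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3", "repeatmasker")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path)
  out <- switch(dialect,
    bed = parse_bed(lines, path),
    gff3 = parse_gff3(lines, path),
    repeatmasker = parse_rm_out(lines, path)
  )
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    abort(paste0("Interval with end <= start at ", path, " line ",
                 out$line[bad[1]]))
  }
  select(out, "seq_id", "start", "end", "category")
}

parse_bed <- function(lines, path) {
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  f <- stringr::str_split(lines[keep], "\t")
  nf <- lengths(f)
  if (any(nf < 3)) {
    abort(paste0("BED line with fewer than 3 fields at ", path,
                 " line ", keep[which(nf < 3)[1]]))
  }
  tibble(
    seq_id = purrr::map_chr(f, 1),
    start = as.integer(purrr::map_chr(f, 2)),
    end = as.integer(purrr::map_chr(f, 3)),
    category = purrr::map_chr(f, function(x) if (length(x) >= 4) x[4] else "."),
    line = keep
  )
}

parse_gff3 <- function(lines, path) {
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  f <- stringr::str_split(lines[keep], "\t")
  nf <- lengths(f)
  if (any(nf < 8)) {
    abort(paste0("GFF3 line with fewer than 8 fields at ", path,
                 " line ", keep[which(nf < 8)[1]]))
  }
  tibble(
    seq_id = purrr::map_chr(f, 1),
    start = as.integer(purrr::map_chr(f, 4)) - 1L,  # to 0-based half-open
    end = as.integer(purrr::map_chr(f, 5)),
    category = purrr::map_chr(f, 3),
    attributes = purrr::map_chr(f, function(x) if (length(x) >= 9) x[9] else ""),
    line = keep
  )
}

parse_rm_out <- function(lines, path) {
  # RepeatMasker .out: 3 header lines, then whitespace-delimited columns;
  # query = col 5, begin/end = cols 6-7 (1-based inclusive), class = col 11
  if (length(lines) < 3) {
    abort(paste0("RepeatMasker .out too short (needs 3 header lines): ", path))
  }
  body <- lines[-(1:3)]
  keep <- which(nzchar(trimws(body)))
  f <- stringr::str_split(trimws(body[keep]), "\\s+")
  nf <- lengths(f)
  if (any(nf < 11)) {
    abort(paste0("RepeatMasker line with fewer than 11 fields at ", path,
                 " line ", keep[which(nf < 11)[1]] + 3L))
  }
  tibble(
    seq_id = purrr::map_chr(f, 5),
    start = as.integer(purrr::map_chr(f, 6)) - 1L,
    end = as.integer(purrr::map_chr(f, 7)),
    category = purrr::map_chr(f, 11),
    line = keep + 3L
  )
}

#' Write intervals as BED4
#'
#' @param intervals Tibble with `seq_id`, `start`, `end`, `category`
#'   (0-based half-open, the package-internal convention and BED's native
#'   one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  readr::write_tsv(
    select(intervals, "seq_id", "start", "end", "category"),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Validate intervals against a sequence table
#'
#' Checks `0 <= start < end <= length(seq_id)` for every interval.
#'
#' @param intervals Interval tibble.
#' @param seqs Sequence table; if `NULL` only internal consistency is
#'   checked.
#' @return `intervals`, invisibly.
#' @export
validate_intervals <- function(intervals, seqs = NULL) {
  if (any(intervals$start < 0) || any(intervals$end <= intervals$start)) {
    i <- which(intervals$start < 0 | intervals$end <= intervals$start)[1]
    abort(paste0("Invalid interval ", intervals$seq_id[i], ":",
                 intervals$start[i], "-", intervals$end[i]))
  }
  if (!is.null(seqs)) {
    len <- stats::setNames(seqs$length, seqs$id)
    unknown <- setdiff(intervals$seq_id, seqs$id)
    if (length(unknown) > 0) {
      abort(paste0("Interval references unknown sequence: ", unknown[1]))
    }
    over <- which(intervals$end > len[intervals$seq_id])
    if (length(over) > 0) {
      i <- over[1]
      abort(paste0("Interval beyond sequence end: ", intervals$seq_id[i], ":",
                   intervals$start[i], "-", intervals$end[i]))
    }
  }
  invisible(intervals)
}

partition_classes <- function() c("macro", "micro", "Z", "unassigned")

#' Read a scaffold-to-chromosome-class partition
#'
#' Two-column tab-delimited file mapping sequence ids to a chromosome
#' class. Allowed classes are `macro`, `micro`, `Z` and `unassigned`
#' (macrochromosome, microchromosome, Z sex chromosome, unplaced).
#' Sequences absent from the file are treated as `unassigned` by
#' [partition_lookup()].
#'
#' @param path Two-column TSV (seq_id, class). May be empty.
#' @return A tibble with columns `seq_id` and `class`.
#' @export
read_partition <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(seq_id = character(), class = character()))
  }
  f <- stringr::str_split(lines, "\t")
  if (any(lengths(f) < 2)) {
    abort(paste0("Partition line with fewer than 2 fields at ", path,
                 " line ", which(lengths(f) < 2)[1]))
  }
  out <- tibble(seq_id = purrr::map_chr(f, 1), class = purrr::map_chr(f, 2))
  if (anyDuplicated(out$seq_id)) {
    abort(paste0("Duplicate seq_id in partition: ",
                 out$seq_id[duplicated(out$seq_id)][1]))
  }
  bad <- setdiff(unique(out$class), partition_classes())
  if (length(bad) > 0) {
    abort(paste0("Unknown partition class '", bad[1], "'; allowed: ",
                 paste(partition_classes(), collapse = ", ")))
  }
  out
}

#' Look up chromosome classes for sequence ids
#'
#' @param partition Partition tibble from [read_partition()], or `NULL`.
#' @param seq_ids Character vector of sequence ids.
#' @return Character vector of classes, `"unassigned"` where unlisted.
#' @export
partition_lookup <- function(partition, seq_ids) {
  if (is.null(partition) || nrow(partition) == 0) {
    return(rep("unassigned", length(seq_ids)))
  }
  cls <- stats::setNames(partition$class, partition$seq_id)[seq_ids]
  cls[is.na(cls)] <- "unassigned"
  unname(cls)
}
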