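#' Convert a C-value in picograms to base pairs
#'
#' Uses the flow-cytometry convention 1 pg = 0.978e9 bp, so a C-value
#' measured as DNA mass converts directly to an expected haploid genome
#' length.
#'
#' @param mass_pg DNA mass in picograms (C-value).
#' @return Genome size in bp.
#' @examples
#' pg_to_bp(1.81) / 1e9  # 1.77 Gbp to 2 decimals
#' @export
pg_to_bp <- function(mass_pg) {
  if (any(mass_pg < 0)) abort("mass_pg must be >= 0")
  mass_pg * 0.978e9
}

#' Average read depth of a sequencing data set
#'
#' @param total_bases Total sequenced bases in bp.
#' @param genome_size Genome size in bp.
#' @return Fold read depth, `total_bases / genome_size`.
#' @examples
#' read_depth(146.38e9, 1.77e9)  # ~82.7
#' @export
read_depth <- function(total_bases, genome_size) {
  if (any(genome_size <= 0)) abort("genome_size must be > 0")
  total_bases / genome_size
}

#' Physical coverage of a paired-end library
#'
#' The mean number of read-pair inserts spanning a base: each pair spans
#' `insert_size` bp, so coverage is `n_pairs * insert_size / genome_size`.
#' Large-insert mate-pair libraries give high physical coverage at low read
#' depth, which is what makes them informative for scaffolding.
#'
#' @param n_pairs Number of read pairs.
#' @param insert_size Library insert size in bp.
#' @param genome_size Genome size in bp.
#' @return Fold physical coverage.
#' @export
physical_coverage <- function(n_pairs, insert_size, genome_size) {
  if (any(n_pairs <= 0) || any(insert_size <= 0) || any(genome_size <= 0)) {
    abort("n_pairs, insert_size and genome_size must all be > 0")
  }
  n_pairs * insert_size / genome_size
}

#' Percentage of a whole, rounded half-up
#'
#' `100 * part / whole` rounded half away from zero at the requested number
#' of decimals, the convention used when reporting table percentages.
#'
#' @param part Numerator (>= 0).
#' @param whole Denominator (> 0).
#' @param decimals Decimals to round to (default 2).
#' @return Percentage.
#' @examples
#' percent_of(246, 248, 0)  # 99
#' @export
percent_of <- function(part, whole, decimals = 2) {
  if (any(whole <= 0)) abort("whole must be > 0")
  if (any(part < 0)) abort("part must be >= 0")
  round_half_up(100 * part / whole, decimals)
}

#' Per-library sequencing-effort accounting
#'
#' Computes read depth and physical coverage for a table of paired-end
#' libraries against a fixed genome size. When reads are fixed-length the
#' pair count is derived as `total_bases / (2 * read_length)`; for
#' variable-length read sets supply `n_pairs` directly.
#'
#' @param libraries Tibble with columns `insert_size`, `read_length`,
#'   `total_bases`, and optionally `n_pairs`.
#' @param genome_size Genome size in bp used as the denominator.
#' @return The input with `n_pairs`, `read_depth` and `physical_coverage`
#'   columns added.
#' @export
library_effort <- function(libraries, genome_size) {
  stopifnot(all(c("insert_size", "total_bases") %in% names(libraries)))
  libraries <- as_tibble(libraries)
  if (!"n_pairs" %in% names(libraries)) {
    if (!"read_length" %in% names(libraries)) {
      abort("Supply n_pairs or read_length to derive pair counts")
    }
    libraries$n_pairs <- libraries$total_bases / (2 * libraries$read_length)
  }
  mutate(
    libraries,
    read_depth = read_depth(.data$total_bases, genome_size),
    physical_coverage = physical_coverage(.data$n_pairs, .data$insert_size,
                                          genome_size)
  )
}
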