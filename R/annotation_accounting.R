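#' Union overlapping or book-ended intervals
#'
#' Collapses an interval set to its non-redundant union per sequence (and
#' per category unless `by_category = FALSE`), so total annotated bases
#' can be counted without double-counting overlaps. Book-ended intervals
#' (end of one equals start of the next) are joined.
#'
#' @param intervals Interval tibble (`seq_id`, `start`, `end`,
#'   `category`), 0-based half-open.
#' @param by_category Merge within each category separately (default);
#'   with `FALSE` categories are pooled and the result carries category
#'   `"all"`.
#' @return Merged interval tibble with a `total_bases` attribute.
#' @examples
#' merge_intervals(tibble::tibble(seq_id = "s", start = c(0, 5),
#'                                end = c(10, 15), category = "LINE"))
#' @export
merge_intervals <- function(intervals, by_category = TRUE) {
  validate_intervals(intervals)
  if (!by_category) intervals$category <- "all"
  grp <- dplyr::group_split(group_by(intervals, .data$seq_id, .data$category))
  out <- purrr::map_dfr(grp, function(g) {
    r <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    tibble(seq_id = g$seq_id[1], start = IRanges::start(r) - 1L,
           end = IRanges::end(r), category = g$category[1])
  })
  out <- arrange(out, .data$seq_id, .data$category, .data$start)
  attr(out, "total_bases") <- sum(as.numeric(out$end - out$start))
  out
}

#' Total bases covered by an interval set, after union
#'
#' @param intervals Interval tibble.
#' @param by_category Count each category's union separately and sum
#'   (`FALSE`, the default, counts each base once regardless of category).
#' @return Total covered bases.
#' @export
interval_total_bases <- function(intervals, by_category = FALSE) {
  if (nrow(intervals) == 0) return(0)
  attr(merge_intervals(intervals, by_category = by_category), "total_bases")
}

#' Non-redundant repeat accounting
#'
#' Builds the standard repeat ledger for an annotated assembly: per-method
#' totals (each annotation program's union, e.g. homology search, protein
#' homology, de novo model, LTR finder, tandem-repeat finder), per-category
#' combined totals (each transposable-element class unioned across
#' methods), the combined TE union across all methods excluding tandem
#' repeats, and the grand total including them. Percentages use
#' `genome_bases` as the denominator; the gap-free contig total is the
#' conventional choice, configurable to the scaffold total.
#'
#' @param intervals Interval tibble with an additional `method` column.
#' @param genome_bases Denominator for percent-of-genome (> 0).
#' @param tandem_category Category label treated as tandem repeats and
#'   excluded from the combined TE union (default `"tandem"`).
#' @return A `repeat_ledger` object; `tidy()` gives the per-method and
#'   per-category tables, `glance()` the combined totals.
#' @export
repeat_fractions <- function(intervals, genome_bases,
                             tandem_category = "tandem") {
  if (genome_bases <= 0) abort("genome_bases must be > 0")
  if (!"method" %in% names(intervals)) intervals$method <- "all"
  te <- intervals[intervals$category != tandem_category, ]

  per_method <- purrr::map_dfr(
    dplyr::group_split(group_by(intervals, .data$method)),
    function(g) tibble(method = g$method[1],
                       bases = interval_total_bases(g))
  )
  per_category <- purrr::map_dfr(
    dplyr::group_split(group_by(intervals, .data$category)),
    function(g) tibble(category = g$category[1],
                       bases = interval_total_bases(g))
  )
  combined_te <- interval_total_bases(te)
  grand_total <- interval_total_bases(intervals)

  pct <- function(b) 100 * b / genome_bases
  structure(
    list(
      per_method = mutate(per_method, percent = pct(.data$bases)),
      per_category = mutate(per_category, percent = pct(.data$bases)),
      combined_te = tibble(bases = combined_te, percent = pct(combined_te)),
      grand_total = tibble(bases = grand_total, percent = pct(grand_total)),
      genome_bases = genome_bases
    ),
    class = "repeat_ledger"
  )
}

#' @export
print.repeat_ledger <- function(x, ...) {
  cat("Repeat ledger (denominator ", format(x$genome_bases, big.mark = ","),
      " bp)\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.repeat_ledger <- function(x, ...) {
  bind_rows(
    mutate(x$per_method, group = "method", label = .data$method,
           .keep = "unused"),
    mutate(x$per_category, group = "category", label = .data$category,
           .keep = "unused"),
    tibble(bases = x$combined_te$bases, percent = x$combined_te$percent,
           group = "combined", label = "TE union"),
    tibble(bases = x$grand_total$bases, percent = x$grand_total$percent,
           group = "combined", label = "all repeats")
  ) |>
    mutate(percent_display = round_half_up(.data$percent, 2)) |>
    select("group", "label", "bases", "percent", "percent_display")
}

#' @export
glance.repeat_ledger <- function(x, ...) {
  tibble(combined_te_bases = x$combined_te$bases,
         combined_te_percent = x$combined_te$percent,
         total_repeat_bases = x$grand_total$bases,
         total_repeat_percent = x$grand_total$percent,
         genome_bases = x$genome_bases)
}

#' Summary statistics of gene models
#'
#' Takes gene models as a tidy exon table and reports the conventional
#' annotation summary: gene count, single-exon gene count, and means of
#' gene length (genomic span including introns), mRNA length (exon sum),
#' exons per gene, exon length (over all exons), and intron length (over
#' all introns of all genes; introns are the gaps between consecutive
#' exons).
#'
#' @param exons Tibble with columns `gene_id`, `start`, `end` (one row
#'   per exon, 0-based half-open; a `seq_id` column is allowed and
#'   ignored).
#' @return One-row tibble: `n_genes`, `single_exon_genes`,
#'   `mean_gene_length`, `mean_mrna_length`, `mean_exons_per_gene`,
#'   `mean_exon_length`, `mean_intron_length` (`NA` when no gene has an
#'   intron).
#' @examples
#' gene_model_stats(tibble::tibble(gene_id = "g1",
#'                                 start = c(0, 150), end = c(100, 250)))
#' @export
gene_model_stats <- function(exons) {
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  if (nrow(exons) == 0) abort("No exons supplied")
  exons <- arrange(exons, .data$gene_id, .data$start)
  per_gene <- exons |>
    group_by(.data$gene_id) |>
    summarise(
      n_exons = n(),
      span = max(.data$end) - min(.data$start),
      mrna = sum(.data$end - .data$start),
      overlap = any(.data$start[-1] < .data$end[-n()]),
      .groups = "drop"
    )
  if (any(per_gene$overlap)) {
    abort(paste0("Overlapping exons in gene model: ",
                 per_gene$gene_id[per_gene$overlap][1]))
  }
  introns <- exons |>
    group_by(.data$gene_id) |>
    summarise(lens = list(.data$start[-1] - .data$end[-n()]),
              .groups = "drop")
  intron_lens <- unlist(introns$lens, use.names = FALSE)
  all_exon_lens <- exons$end - exons$start
  tibble(
    n_genes = nrow(per_gene),
    single_exon_genes = sum(per_gene$n_exons == 1),
    mean_gene_length = mean(per_gene$span),
    mean_mrna_length = mean(per_gene$mrna),
    mean_exons_per_gene = mean(per_gene$n_exons),
    mean_exon_length = mean(all_exon_lens),
    mean_intron_length = if (length(intron_lens) == 0) NA_real_
                         else mean(intron_lens)
  )
}

#' Read gene models (exon structure) from GFF3
#'
#' Collects `exon` features and resolves each to its gene via the
#' `Parent` chain (exon -> mRNA -> gene when mRNA features are present,
#' else the exon's parent directly).
#'
#' @param path GFF3 file.
#' @return Tidy exon tibble (`gene_id`, `seq_id`, `start`, `end`),
#'   0-based half-open, suitable for [gene_model_stats()].
#' @export
read_gene_models <- function(path) {
  g <- parse_gff3(readr::read_lines(path), path)
  attr_val <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  mrna <- g[g$category %in% c("mRNA", "transcript"), ]
  tx2gene <- stats::setNames(attr_val(mrna$attributes, "Parent"),
                             attr_val(mrna$attributes, "ID"))
  ex <- g[g$category == "exon", ]
  if (nrow(ex) == 0) abort(paste0("No exon features in ", path))
  parent <- attr_val(ex$attributes, "Parent")
  gene <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
  tibble(gene_id = unname(gene), seq_id = ex$seq_id,
         start = ex$start, end = ex$end) |>
    arrange(.data$gene_id, .data$start)
}

#' RPKM: reads per kilobase of gene per million mapped reads
#'
#' @param count Reads assigned to the gene.
#' @param gene_length_bp Gene length in bp (> 0).
#' @param mapped_total Total mapped reads in the sample (> 0).
#' @return `count * 1e9 / (gene_length_bp * mapped_total)`.
#' @examples
#' rpkm(1, 1000, 1e6)  # 1
#' @export
rpkm <- function(count, gene_length_bp, mapped_total) {
  if (any(gene_length_bp <= 0)) abort("gene_length_bp must be > 0")
  if (any(mapped_total <= 0)) abort("mapped_total must be > 0")
  if (any(count < 0)) abort("count must be >= 0")
  count * 1e9 / (gene_length_bp * mapped_total)
}

#' RPKM for a wide count table
#'
#' @param counts Tibble with `gene_id`, `gene_length` and one column of
#'   read counts per sample.
#' @param mapped_totals Named numeric vector of per-sample mapped-read
#'   totals; names must match the sample columns. Defaults to each
#'   column's sum.
#' @return Long tibble (`gene_id`, `gene_length`, `sample`, `count`,
#'   `rpkm`).
#' @export
rpkm_table <- function(counts, mapped_totals = NULL) {
  stopifnot(all(c("gene_id", "gene_length") %in% names(counts)))
  samples <- setdiff(names(counts), c("gene_id", "gene_length"))
  if (length(samples) == 0) abort("No sample columns in counts")
  if (is.null(mapped_totals)) {
    mapped_totals <- vapply(counts[samples], sum, numeric(1))
  }
  missing <- setdiff(samples, names(mapped_totals))
  if (length(missing) > 0) {
    abort(paste0("mapped_totals missing sample: ", missing[1]))
  }
  long <- tidyr::pivot_longer(counts, all_of(samples),
                              names_to = "sample", values_to = "count")
  mutate(long, rpkm = rpkm(.data$count, .data$gene_length,
                           mapped_totals[.data$sample]))
}

#' Expression-support ratios at RPKM thresholds
#'
#' For each sample, counts genes whose RPKM strictly exceeds each
#' threshold, plus a `Combined` row counting genes exceeding the threshold
#' in at least one sample; percentages are taken against the total number
#' of annotated genes.
#'
#' @param rpkm_long Long tibble (`gene_id`, `sample`, `rpkm`), e.g. from
#'   [rpkm_table()].
#' @param thresholds RPKM thresholds (default 0, 1, 5); comparisons are
#'   strict (`>`).
#' @param total_annotated Denominator for the percentage; defaults to the
#'   number of distinct genes in the table.
#' @return Tibble (`sample`, `threshold`, `n_genes`, `percent`), the
#'   `Combined` rows last.
#' @export
support_ratios <- function(rpkm_long, thresholds = c(0, 1, 5),
                           total_annotated = NULL) {
  stopifnot(all(c("gene_id", "sample", "rpkm") %in% names(rpkm_long)))
  if (is.null(total_annotated)) {
    total_annotated <- dplyr::n_distinct(rpkm_long$gene_id)
  }
  if (total_annotated <= 0) abort("total_annotated must be > 0")
  per_sample <- purrr::map_dfr(thresholds, function(th) {
    rpkm_long |>
      group_by(sample = .data$sample) |>
      summarise(n_genes = sum(.data$rpkm > th), .groups = "drop") |>
      mutate(threshold = th)
  })
  combined <- purrr::map_dfr(thresholds, function(th) {
    n <- rpkm_long |>
      group_by(.data$gene_id) |>
      summarise(hit = any(.data$rpkm > th), .groups = "drop")
    tibble(sample = "Combined", n_genes = sum(n$hit), threshold = th)
  })
  bind_rows(per_sample, combined) |>
    mutate(percent = percent_of(.data$n_genes, total_annotated, 2)) |>
    select("sample", "threshold", "n_genes", "percent")
}
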