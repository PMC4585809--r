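pipeline_stages <- function() c("simulate", "genome_size", "assembly", "gc",
                                "annotation")

config_defaults <- function() {
  list(
    stages = pipeline_stages(),
    out_dir = NULL,
    seed = 1,
    # simulate stage
    genome_length = 1e5, heterozygosity = 0.0085, coverage = 30,
    read_length = 125, repeat_fraction = c(LINE = 0.122),
    # genome_size stage
    k = 17, min_copy_floor = 2,
    # assembly stage
    min_gap_run = 1, thresholds = c(100, 2000),
    # gc stage
    window_sizes = c(5, 10, 20, 40) * 1000, max_n_fraction = 0.5,
    # input paths (required when the simulate stage is not run)
    reads = NULL, assembly = NULL, repeats = NULL, partition = NULL,
    counts = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks that every requested
#' stage has its inputs (either a path or the `simulate` stage ahead of
#' it) before anything runs.
#'
#' @param config Named list of configuration values; see
#'   [run_pipeline()].
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key: ", unknown[1]))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) abort("config$out_dir is required")
  if (length(cfg$stages) == 0) abort("config$stages must name at least one stage")
  bad <- setdiff(cfg$stages, pipeline_stages())
  if (length(bad) > 0) {
    abort(paste0("Unknown stage '", bad[1], "'; allowed: ",
                 paste(pipeline_stages(), collapse = ", ")))
  }
  simulated <- "simulate" %in% cfg$stages
  needs <- list(genome_size = "reads", assembly = "assembly",
                annotation = "repeats", gc = "assembly")
  for (st in intersect(cfg$stages, names(needs))) {
    if (!simulated && is.null(cfg[[needs[[st]]]])) {
      abort(paste0("Stage '", st, "' requires config$", needs[[st]],
                   " (or the simulate stage)"))
    }
  }
  cfg
}

#' Run the end-to-end genome-landscape pipeline
#'
#' Executes the requested stages in dependency order and writes one TSV
#' per result table plus a single `summary.json` carrying the headline
#' numbers, the package version, a configuration hash and the seed. A
#' run directory is write-once: rerunning into a populated directory
#' requires `overwrite = TRUE`. Reruns with the same configuration are
#' byte-identical.
#'
#' Stages: `simulate` (generate a diploid genome, reads, a gappy
#' assembly and annotations with known truth), `genome_size` (k-mer
#' spectrum, modes, depth, size), `assembly` (contiguity/gap summary),
#' `gc` (window GC and SD-versus-scale), `annotation` (repeat ledger and
#' expression support).
#'
#' @param config Named list: `out_dir` (required), `stages`, `seed`, and
#'   stage parameters / input paths — see [validate_config()].
#' @param overwrite Allow writing into a populated run directory.
#' @return The summary list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary_path <- file.path(cfg$out_dir, "summary.json")
  if (file.exists(summary_path) && !overwrite) {
    abort(paste0("Run directory already contains summary.json: ",
                 cfg$out_dir, " (outputs are write-once; set overwrite = TRUE)"))
  }
  summary <- list(
    tool = "glkit",
    version = as.character(utils::packageVersion("glkit")),
    config_hash = rlang::hash(cfg),
    seed = cfg$seed
  )
  truth <- NULL
  log_stage <- function(st) message("[glkit] stage=", st)

  if ("simulate" %in% cfg$stages) {
    log_stage("simulate")
    dip <- make_diploid_genome(cfg$genome_length,
                               heterozygosity = cfg$heterozygosity,
                               seed = cfg$seed)
    reads <- simulate_reads(c(dip$hapA, dip$hapB), coverage = cfg$coverage,
                            read_length = cfg$read_length, seed = cfg$seed + 1L)
    asm <- make_assembly(seed = cfg$seed + 2L)
    ann <- plant_repeats(asm$seqs, cfg$repeat_fraction, seed = cfg$seed + 3L)
    expr <- make_expression(seed = cfg$seed + 4L)
    cfg$reads <- file.path(cfg$out_dir, "reads.fastq")
    write_fastq(reads, cfg$reads)
    cfg$assembly <- file.path(cfg$out_dir, "assembly.fa")
    write_fasta(asm$seqs, cfg$assembly)
    cfg$repeats <- file.path(cfg$out_dir, "repeats.bed")
    write_intervals(ann$intervals, cfg$repeats)
    truth <- list(genome_length = dip$truth$length,
                  realized_h = dip$truth$realized_h,
                  assembly = asm$truth, repeat_union = as.list(ann$truth))
    jsonlite::write_json(truth, file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$truth <- truth
    expr_counts <- expr$counts
    expr_totals <- expr$mapped_totals
  } else {
    expr_counts <- NULL
  }

  if ("genome_size" %in% cfg$stages) {
    log_stage("genome_size")
    spec <- count_kmers(cfg$reads, k = cfg$k)
    reads_seq <- sequences_of(cfg$reads)
    total_bases <- sum(nchar(reads_seq))
    gs <- genome_size_from_spectrum(spec, read_length = cfg$read_length,
                                    total_bases = total_bases,
                                    min_copy_floor = cfg$min_copy_floor)
    write_spectrum(spec, file.path(cfg$out_dir, "spectrum.tsv"))
    readr::write_tsv(gs, file.path(cfg$out_dir, "genome_size.tsv"))
    summary$genome_size <- as.list(gs)
    summary$genome_size$total_bases <- total_bases
  }

  if ("assembly" %in% cfg$stages) {
    log_stage("assembly")
    seqs <- read_fasta(cfg$assembly)
    sm <- summarize_assembly(seqs, thresholds = cfg$thresholds,
                             min_gap_run = cfg$min_gap_run)
    readr::write_tsv(tidy(sm), file.path(cfg$out_dir, "assembly_stats.tsv"))
    summary$assembly <- as.list(glance(sm))
  }

  if ("gc" %in% cfg$stages) {
    log_stage("gc")
    seqs <- read_fasta(cfg$assembly)
    part <- if (!is.null(cfg$partition)) read_partition(cfg$partition)
    ws <- cfg$window_sizes[cfg$window_sizes <= max(seqs$length)]
    if (length(ws) == 0) ws <- max(64, 2^floor(log2(max(seqs$length) / 4)))
    track <- window_gc(seqs, ws[1], max_n_fraction = cfg$max_n_fraction)
    readr::write_tsv(track, file.path(cfg$out_dir, "gc_windows.tsv"))
    gsum <- gc_summary(track, partition = part)
    curve <- sd_vs_scale(seqs, window_sizes = ws, partition = part,
                         max_n_fraction = cfg$max_n_fraction)
    readr::write_tsv(curve, file.path(cfg$out_dir, "gc_scale_curve.tsv"))
    summary$gc <- list(mean = gsum$mean, sd = gsum$sd,
                       window_size = gsum$window_size,
                       n_windows = gsum$n_windows)
  }

  if ("annotation" %in% cfg$stages) {
    log_stage("annotation")
    seqs <- read_fasta(cfg$assembly)
    genome_bases <- sum(seqs$length) -
      sum(stringr::str_count(seqs$seq, stringr::fixed("N")))
    reps <- read_intervals(cfg$repeats, dialect = "bed")
    reps$method <- "sim"
    ledger <- repeat_fractions(reps, genome_bases = genome_bases)
    readr::write_tsv(tidy(ledger), file.path(cfg$out_dir, "repeat_ledger.tsv"))
    summary$annotation <- as.list(glance(ledger))
    if (!is.null(cfg$counts) || !is.null(expr_counts)) {
      counts <- if (!is.null(cfg$counts)) {
        readr::read_tsv(cfg$counts, show_col_types = FALSE)
      } else expr_counts
      totals <- if (!is.null(cfg$counts)) NULL else expr_totals
      long <- rpkm_table(counts, mapped_totals = totals)
      sup <- support_ratios(long)
      readr::write_tsv(sup, file.path(cfg$out_dir, "expression_support.tsv"))
      summary$annotation$support <- as.list(
        sup[sup$sample == "Combined" & sup$threshold == 0, ])
    }
  }

  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
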