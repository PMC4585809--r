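#' GC models for synthetic genomes
#'
#' `gc_uniform(p)` describes compositionally homogeneous sequence: every
#' base is G or C independently with probability `p` (default 0.418, a
#' typical squamate genome-wide mean). `gc_blocks()` describes a
#' block-isochore genome: consecutive blocks of `block_length` bp each
#' drawn at a GC level sampled from `levels` with probabilities
#' `proportions`, giving long-range GC structure that a homogeneous model
#' lacks.
#'
#' @param p Per-base probability of G or C.
#' @param block_length Isochore block length in bp (default 1 Mbp).
#' @param levels GC levels the blocks alternate among (default 0.35 and
#'   0.55).
#' @param proportions Sampling weights over `levels`; must sum to 1.
#' @return A GC-model specification list.
#' @export
gc_uniform <- function(p = 0.418) {
  stopifnot(p >= 0, p <= 1)
  list(model = "uniform", p = p)
}

#' @rdname gc_uniform
#' @export
gc_blocks <- function(block_length = 1e6, levels = c(0.35, 0.55),
                      proportions = rep(1 / length(levels), length(levels))) {
  stopifnot(block_length >= 1, all(levels >= 0 & levels <= 1),
            length(proportions) == length(levels),
            abs(sum(proportions) - 1) < 1e-9)
  list(model = "blocks", block_length = block_length, levels = levels,
       proportions = proportions)
}

random_dna <- function(n, gc_p) {
  probs <- c(A = (1 - gc_p) / 2, C = gc_p / 2, G = gc_p / 2, T = (1 - gc_p) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a haploid genome sequence under a GC model
#'
#' Deterministic given `seed`: the generator is a pure function of its
#' arguments.
#'
#' @param length Genome length in bp.
#' @param gc A GC model from [gc_uniform()] or [gc_blocks()].
#' @param seed Integer seed.
#' @return List with `seq` (character string) and `truth` (the realised
#'   block layout for block models).
#' @export
make_genome <- function(length, gc = gc_uniform(), seed = 1) {
  stopifnot(length >= 1)
  withr::with_seed(seed, {
    if (gc$model == "uniform") {
      list(seq = random_dna(length, gc$p),
           truth = list(model = "uniform", p = gc$p, length = length,
                        seed = seed))
    } else {
      n_blocks <- ceiling(length / gc$block_length)
      lv <- sample(gc$levels, n_blocks, replace = TRUE, prob = gc$proportions)
      pieces <- character(n_blocks)
      remaining <- length
      for (i in seq_len(n_blocks)) {
        n <- min(gc$block_length, remaining)
        pieces[i] <- random_dna(n, lv[i])
        remaining <- remaining - n
      }
      list(seq = paste(pieces, collapse = ""),
           truth = list(model = "blocks", block_length = gc$block_length,
                        block_levels = lv, length = length, seed = seed))
    }
  })
}

#' Generate a diploid genome with known heterozygosity
#'
#' Haplotype A is drawn from the GC model; haplotype B is A with
#' substitutions at per-base rate `heterozygosity` at uniformly chosen
#' sites (each substituted base becomes one of the other three bases).
#' The truth record stores the exact variant positions and the realised
#' rate. The default rate 0.0085 matches the high heterozygosity of a
#' wild-caught outbred individual.
#'
#' @param length Genome length in bp.
#' @param gc GC model ([gc_uniform()] / [gc_blocks()]).
#' @param heterozygosity Per-base substitution rate between haplotypes.
#' @param seed Integer seed.
#' @return List with `hapA`, `hapB` (character strings) and `truth`
#'   (`variant_positions` 1-based, `realized_h`, `length`, `seed`).
#' @export
make_diploid_genome <- function(length, gc = gc_uniform(),
                                heterozygosity = 0.0085, seed = 1) {
  stopifnot(heterozygosity >= 0, heterozygosity <= 1)
  g <- make_genome(length, gc, seed = seed)
  withr::with_seed(seed + 1L, {
    hapA <- g$seq
    sites <- which(stats::runif(length) < heterozygosity)
    hapB <- hapA
    if (length(sites) > 0) {
      bases <- c("A", "C", "G", "T")
      old <- substring(hapA, sites, sites)
      new <- vapply(old, function(b) sample(setdiff(bases, b), 1),
                    character(1), USE.NAMES = FALSE)
      for (i in seq_along(sites)) {
        substr(hapB, sites[i], sites[i]) <- new[i]
      }
    }
    list(hapA = hapA, hapB = hapB,
         truth = list(variant_positions = sites,
                      realized_h = length(sites) / length,
                      length = length, heterozygosity = heterozygosity,
                      seed = seed, gc = g$truth))
  })
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate shotgun reads from one or two haplotypes
#'
#' Uniform random start positions; coverage is split equally across the
#' supplied haplotypes. Substitution errors only (no indels) at
#' `error_rate` per base. In paired mode each fragment of `insert_size`
#' emits a forward mate from its left end and a reverse-complemented mate
#' from its right end. Deterministic given `seed`.
#'
#' @param haplotypes Character vector of 1 or 2 haplotype sequences.
#' @param coverage Total fold coverage to emit.
#' @param read_length Read length in bp (default 125).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param paired Emit mate pairs (default FALSE).
#' @param insert_size Fragment length for paired mode (default 500).
#' @param seed Integer seed.
#' @return Tibble (`id`, `seq`) of reads.
#' @export
simulate_reads <- function(haplotypes, coverage, read_length = 125,
                           error_rate = 0, paired = FALSE, insert_size = 500,
                           seed = 1) {
  stopifnot(coverage > 0, read_length >= 1)
  glen <- unique(nchar(haplotypes))
  if (any(read_length > nchar(haplotypes))) {
    abort("read_length exceeds a haplotype length")
  }
  if (paired && any(insert_size > nchar(haplotypes))) {
    abort("insert_size exceeds a haplotype length")
  }
  withr::with_seed(seed, {
    per_hap <- coverage / length(haplotypes)
    all_reads <- purrr::imap(haplotypes, function(hap, h) {
      n <- nchar(hap)
      span <- if (paired) insert_size else read_length
      unit <- if (paired) 2 * read_length else read_length
      n_frag <- max(1L, as.integer(round(per_hap * n / unit)))
      starts <- sample.int(n - span + 1L, n_frag, replace = TRUE)
      if (paired) {
        fwd <- substring(hap, starts, starts + read_length - 1L)
        rev_start <- starts + insert_size - read_length
        rev <- vapply(substring(hap, rev_start, rev_start + read_length - 1L),
                      revcomp, character(1), USE.NAMES = FALSE)
        tibble(
          id = paste0("h", h, "_f", rep(seq_len(n_frag), each = 2),
                      "/", rep(1:2, n_frag)),
          seq = as.vector(rbind(fwd, rev))
        )
      } else {
        tibble(id = paste0("h", h, "_r", seq_len(n_frag)),
               seq = substring(hap, starts, starts + read_length - 1L))
      }
    })
    reads <- bind_rows(all_reads)
    if (error_rate > 0) {
      reads$seq <- vapply(reads$seq, function(s) {
        hits <- which(stats::runif(nchar(s)) < error_rate)
        if (length(hits) == 0) return(s)
        bases <- c("A", "C", "G", "T")
        for (i in hits) {
          substr(s, i, i) <- sample(setdiff(bases, substr(s, i, i)), 1)
        }
        s
      }, character(1), USE.NAMES = FALSE)
    }
    reads
  })
}

#' Write reads as FASTQ
#'
#' Qualities are constant placeholders (`I`); this simulator models
#' substitution errors, not quality profiles.
#'
#' @param reads Tibble (`id`, `seq`).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Construct a gappy assembly with known statistics
#'
#' Builds scaffolds by joining random-length contigs with N-run gaps, and
#' records exact ground truth (contig and scaffold lengths, gap bases,
#' gap ratio, N50) computed from the construction itself, so assembly
#' statistics can be verified without re-deriving them from the sequence.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param contigs_per_scaffold Integer range (min, max) of contigs per
#'   scaffold.
#' @param contig_length Range (min, max) of contig lengths in bp.
#' @param gap_run Range (min, max) of gap lengths in bp, or `"none"` for
#'   a gap-free assembly.
#' @param gc_p GC probability of contig sequence.
#' @param seed Integer seed.
#' @return List with `seqs` (sequence tibble) and `truth` (list with
#'   `contig_lengths`, `scaffold_lengths`, `gap_bases`, `gap_ratio`,
#'   `n50`, `n50_count`, `contig_n50`).
#' @export
make_assembly <- function(n_scaffolds = 20, contigs_per_scaffold = c(1, 5),
                          contig_length = c(200, 5000), gap_run = c(1, 100),
                          gc_p = 0.418, seed = 1) {
  withr::with_seed(seed, {
    scaffolds <- character(n_scaffolds)
    contig_lengths <- list()
    gap_bases <- 0
    for (i in seq_len(n_scaffolds)) {
      nc <- sample(contigs_per_scaffold[1]:contigs_per_scaffold[2], 1)
      cl <- sample(contig_length[1]:contig_length[2], nc, replace = TRUE)
      contigs <- vapply(cl, random_dna, character(1), gc_p = gc_p)
      if (identical(gap_run, "none")) {
        gaps <- rep("", max(0, nc - 1))
      } else if (nc == 1) {
        gaps <- character(0)
      } else {
        gl <- sample(gap_run[1]:gap_run[2], nc - 1, replace = TRUE)
        gap_bases <- gap_bases + sum(gl)
        gaps <- strrep("N", gl)
      }
      pieces <- character(2 * nc - 1)
      pieces[seq(1, 2 * nc - 1, by = 2)] <- contigs
      if (nc > 1) pieces[seq(2, 2 * nc - 2, by = 2)] <- gaps
      scaffolds[i] <- paste(pieces, collapse = "")
      contig_lengths[[i]] <- cl
    }
    names(scaffolds) <- paste0("scaffold_", seq_len(n_scaffolds))
    scaffold_lengths <- nchar(scaffolds)
    total <- sum(scaffold_lengths)
    # truth N50 by direct cumulative accounting over the constructed lengths
    n50_of <- function(lens) {
      s <- sort(unname(lens), decreasing = TRUE)
      i <- which(cumsum(as.numeric(s)) >= 0.5 * sum(as.numeric(s)))[1]
      list(size = s[i], count = i)
    }
    sc50 <- n50_of(scaffold_lengths)
    ct50 <- n50_of(unlist(contig_lengths))
    list(
      seqs = seq_tbl(scaffolds),
      truth = list(
        contig_lengths = unlist(contig_lengths),
        scaffold_lengths = unname(scaffold_lengths),
        gap_bases = gap_bases,
        gap_ratio = gap_bases / total,
        n50 = sc50$size, n50_count = sc50$count,
        contig_n50 = ct50$size,
        seed = seed
      )
    )
  })
}

# Place disjoint intervals totalling exactly `target` bases on a linear
# space of `total` bases by stick-breaking, then map to per-sequence
# coordinates. Returns 0-based half-open intervals.
plant_disjoint <- function(seq_lengths, target, piece_range = c(200, 2000)) {
  total <- sum(seq_lengths)
  stopifnot(target <= total)
  lens <- integer(0)
  remaining <- target
  while (remaining > 0) {
    l <- min(remaining, sample(piece_range[1]:piece_range[2], 1))
    # avoid a terminal fragment shorter than 1
    lens <- c(lens, l)
    remaining <- remaining - l
  }
  m <- length(lens)
  slack <- total - target
  # random gaps before each piece plus after the last, summing to slack
  cuts <- sort(stats::runif(m, 0, 1))
  gaps <- round(diff(c(0, cuts)) / max(cuts[m], .Machine$double.eps) * slack)
  gaps <- pmax(gaps, 0)
  overshoot <- sum(gaps) + sum(lens) - total
  if (overshoot > 0) gaps[which.max(gaps)] <- gaps[which.max(gaps)] - overshoot
  starts <- cumsum(gaps) + c(0, cumsum(lens[-m]))
  # map linear coordinates back to sequences, splitting at boundaries
  bounds <- cumsum(c(0, seq_lengths))
  out <- list()
  for (i in seq_len(m)) {
    s <- starts[i]; e <- starts[i] + lens[i]
    for (j in seq_along(seq_lengths)) {
      lo <- max(s, bounds[j]); hi <- min(e, bounds[j + 1])
      if (hi > lo) {
        out[[length(out) + 1]] <-
          list(idx = j, start = lo - bounds[j], end = hi - bounds[j])
      }
    }
  }
  out
}

#' Plant repeat annotations with a known genome fraction
#'
#' For each named category, places intervals whose union covers exactly
#' `round(fraction * total_bases)` bases, then adds redundant
#' sub-intervals (contained in planted ones, so the union is unchanged)
#' to exercise non-redundant accounting. Categories are placed
#' independently and may overlap one another.
#'
#' @param seqs Sequence table the annotations refer to.
#' @param fractions Named numeric vector, e.g. `c(LINE = 0.122)`.
#' @param redundancy Fraction of planted intervals duplicated as
#'   contained sub-intervals (default 0.2).
#' @param seed Integer seed.
#' @return List with `intervals` (tibble with `method` column `"sim"`)
#'   and `truth` (named vector of exact union bases per category).
#' @export
plant_repeats <- function(seqs, fractions, redundancy = 0.2, seed = 1) {
  seqs <- as_seq_tbl(seqs)
  stopifnot(!is.null(names(fractions)), all(fractions >= 0 & fractions < 1))
  withr::with_seed(seed, {
    total <- sum(seqs$length)
    rows <- list()
    truth <- stats::setNames(numeric(length(fractions)), names(fractions))
    for (cat in names(fractions)) {
      target <- round(fractions[[cat]] * total)
      truth[[cat]] <- target
      if (target == 0) next
      placed <- plant_disjoint(seqs$length, target)
      for (p in placed) {
        rows[[length(rows) + 1]] <- tibble(
          seq_id = seqs$id[p$idx], start = as.integer(p$start),
          end = as.integer(p$end), category = cat, method = "sim")
      }
      # redundant contained copies: union unchanged
      n_dup <- floor(length(placed) * redundancy)
      if (n_dup > 0) {
        for (p in sample(placed, n_dup)) {
          w <- p$end - p$start
          if (w < 2) next
          s2 <- p$start + sample.int(w - 1, 1) - 1L
          e2 <- s2 + sample.int(p$end - s2, 1)
          rows[[length(rows) + 1]] <- tibble(
            seq_id = seqs$id[p$idx], start = as.integer(s2),
            end = as.integer(e2), category = cat, method = "sim")
        }
      }
    }
    list(intervals = bind_rows(rows), truth = truth)
  })
}

#' Generate gene models with known summary statistics
#'
#' Genes are laid end to end on a nominal sequence with randomly drawn
#' exon counts and exon/intron lengths; the truth record keeps the drawn
#' values so the model-summary means can be verified by direct
#' arithmetic.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (min, max).
#' @param exon_length Integer range (min, max) in bp.
#' @param intron_length Integer range (min, max) in bp.
#' @param seq_id Sequence id the models are placed on.
#' @param seed Integer seed.
#' @return List with `exons` (tidy exon tibble) and `truth` (per-gene
#'   exon counts and drawn lengths).
#' @export
make_gene_models <- function(n_genes = 100, exons_per_gene = c(1, 12),
                             exon_length = c(50, 400),
                             intron_length = c(100, 5000),
                             seq_id = "chr_sim", seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    truth <- list()
    cursor <- 0L
    for (g in seq_len(n_genes)) {
      ne <- sample(exons_per_gene[1]:exons_per_gene[2], 1)
      el <- sample(exon_length[1]:exon_length[2], ne, replace = TRUE)
      il <- if (ne > 1) {
        sample(intron_length[1]:intron_length[2], ne - 1, replace = TRUE)
      } else integer(0)
      starts <- cursor + cumsum(c(0L, el[-ne] + il))
      gid <- sprintf("gene_%04d", g)
      rows[[g]] <- tibble(gene_id = gid, seq_id = seq_id,
                          start = as.integer(starts),
                          end = as.integer(starts + el))
      truth[[gid]] <- list(exon_lengths = el, intron_lengths = il)
      cursor <- max(starts + el) + 1000L
    }
    list(exons = bind_rows(rows), truth = truth)
  })
}

#' Generate an expression count table with known RPKM
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param zero_fraction Fraction of gene-sample cells with zero counts
#'   (unexpressed), default 0.1.
#' @param seed Integer seed.
#' @return List with `counts` (wide tibble: `gene_id`, `gene_length`,
#'   one column per sample), `mapped_totals` (named vector) and `truth`
#'   (long tibble of closed-form RPKM values).
#' @export
make_expression <- function(n_genes = 200, n_samples = 4,
                            zero_fraction = 0.1, seed = 1) {
  withr::with_seed(seed, {
    lens <- sample(500:5000, n_genes, replace = TRUE)
    samples <- paste0("sample_", seq_len(n_samples))
    counts <- tibble(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                     gene_length = lens)
    for (s in samples) {
      x <- stats::rnbinom(n_genes, mu = lens / 50, size = 2)
      x[stats::runif(n_genes) < zero_fraction] <- 0L
      counts[[s]] <- x
    }
    mapped_totals <- vapply(counts[samples], function(x) sum(x) + 1e6,
                            numeric(1))
    truth <- tidyr::pivot_longer(counts, all_of(samples),
                                 names_to = "sample", values_to = "count")
    truth$rpkm <- truth$count * 1e9 /
      (truth$gene_length * mapped_totals[truth$sample])
    list(counts = counts, mapped_totals = mapped_totals, truth = truth)
  })
}

#' One-call synthetic annotation bundle
#'
#' Convenience wrapper combining [plant_repeats()], [make_gene_models()]
#' and [make_expression()] with a shared seed.
#'
#' @param seqs Sequence table to annotate.
#' @param repeat_fractions Named fractions passed to [plant_repeats()].
#' @param n_genes,n_samples Sizes for the gene-model and expression
#'   generators.
#' @param seed Integer seed.
#' @return List with `repeats`, `genes`, `expression` (each carrying its
#'   own truth record).
#' @export
make_annotations <- function(seqs, repeat_fractions = c(LINE = 0.122),
                             n_genes = 100, n_samples = 4, seed = 1) {
  list(
    repeats = plant_repeats(seqs, repeat_fractions, seed = seed),
    genes = make_gene_models(n_genes = n_genes, seed = seed + 1L),
    expression = make_expression(n_genes = n_genes, n_samples = n_samples,
                                 seed = seed + 2L)
  )
}
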