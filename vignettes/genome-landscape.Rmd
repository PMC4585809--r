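---
title: "Methods: genome-size estimation, assembly statistics and the GC landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-size estimation, assembly statistics and the GC landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glkit)
```

This vignette documents the models, conventions and numerical choices
behind every statistic `glkit` computes, in enough detail that a reader
can predict the output on paper. Where a convention was genuinely open,
the choice made here is stated together with its rationale.

## Coordinates and sequence representation

All internal coordinates are 0-based half-open, so an interval's length is
always `end - start` and abutting intervals share a boundary without
overlapping. Conversions happen only at I/O boundaries: BED is native,
GFF3 and RepeatMasker `.out` are 1-based inclusive and are shifted on
read. A single internal convention eliminates the usual off-by-one bug
class; the round-trip property (convert in, convert out, compare) is
tested on random interval sets.

Sequences are held as uppercase strings in a tibble. Lowercase
(soft-masked) input is folded to uppercase, but the masked runs are kept
as a per-record run table so masked fractions remain recoverable and
`write_fasta()` can restore the original case. IUPAC ambiguity codes
other than N are retained in the sequence but treated as "not A/C/G/T"
by the GC and k-mer logic — there is no universally agreed handling, and
excluding them from both numerator and denominator is the conservative
choice. Strand is ignored throughout: every statistic in scope (GC,
lengths, repeat fractions) is strand-symmetric.

## The k-mer spectrum and genome size

A read set is decomposed into all windows of length $k$; each window
containing only A/C/G/T is counted once under its canonical form, the
lexicographic minimum of the window and its reverse complement, so both
strands of a molecule contribute to one entity. Palindromic even-$k$
windows are counted once; both odd and even $k$ are allowed. $k$ is
capped at 31 so a 2-bit encoding fits one 64-bit word; the counter is a
small C++ hash-map kernel, feasible at $k = 17$ where a dense $4^k$
table is not. The histogram tail is pooled above copy number 10,000
(deep-repeat k-mers carry no information about the single-copy modes and
the cap bounds memory).

For a genome sequenced to per-base depth $D$ with reads of length $L$, a
single-copy k-mer is seen once per read covering it, and a read covers
$L - k + 1$ k-mer start positions, so the homozygous single-copy mode
$M$ of the spectrum sits at $D\,(L-k+1)/L$. Inverting:

$$\mathrm{depth} = M \cdot \frac{L}{L-k+1}, \qquad
  \mathrm{genome\ size} = \frac{\text{total read bases}}{\mathrm{depth}}.$$

`average_read_depth()` accepts $L = k$ (the correction factor becomes
$M \cdot L$, still well defined) and rejects only $L < k$, where no
window fits in a read.

In a diploid, a heterozygous site splits its covering k-mers between the
two haplotypes, so heterozygous single-copy sequence forms a second peak
at $M/2$. `find_modes()` works on the histogram densified over
$1..\max$ and smoothed with a centred moving average of window 3
(applied to both valley and peak finding — the contract only requires it
for the mode, but an unsmoothed valley is fragile to single-bin noise).
The error valley is the smallest copy number at or above
`min_copy_floor` (default 2, since copy number 1 is dominated by
sequencing error in real data) that is a plateau-tolerant local minimum:
no higher than either neighbour and strictly lower than at least one.
The homozygous mode is the argmax above the valley, ties breaking toward
the lower copy number; the heterozygous mode is the local maximum below
the homozygous peak nearest half its copy number, provided it rises
above the valley count. On error-free (simulated) read sets there is no
error spike, so the first local minimum is the het–hom dip itself; the
het search therefore scans all local maxima below the homozygous peak
rather than only those above the valley. Each integer peak is refined by
fitting a parabola through the three surrounding histogram points and
reporting the vertex, which is how fractional modes such as 48.5 arise;
the refinement is a declared convention, not a claim about how any
particular published value was interpolated. A het/hom ratio outside
[0.4, 0.6] triggers a diploid-consistency warning.

## Sequencing-effort accounting

The C-value conversion uses $1\,\mathrm{pg} = 0.978 \times 10^9$ bp (the
Doležel flow-cytometry convention). Read depth is total bases over
genome size; physical coverage of a paired library is
$n_{\mathrm{pairs}} \times \mathrm{insert} / \mathrm{genome}$, verified
in the tests against a span-painting simulation on a circular genome.
`percent_of()` rounds half away from zero at the requested precision —
the convention printed tables follow — while every analysis function
retains unrounded values and rounds only in display columns.
`library_effort()` derives pair counts as
$\mathrm{bases} / (2L)$ for fixed-length reads; variable-length read
sets must supply pair counts directly, since $bases/(2L)$ is undefined
without a fixed $L$.

## Assembly statistics

`scaffolds_to_contigs()` splits scaffolds at every maximal run of at
least `min_gap_run` N characters. The default is 1 — every N is a gap —
because it is the only convention under which contig totals, scaffold
totals and the gap ratio are mutually consistent
(contig bases + N bases = scaffold bases, an identity the tests assert
on every synthetic assembly). Assemblers with "scaftig" conventions can
set 10 or more.

The Nx ladder sorts lengths descending and reports, for each $x$, the
length at which the cumulative sum first reaches $x\%$ of the total,
paired with the count of sequences up to and including that one. No
minimum-length filter is applied before the ladder: the ≥100 bp and
≥2 kbp rows are reported counts, not filters. Nx monotonicity
(N50 ≥ N60 ≥ … ≥ N90, counts weakly increasing) and permutation
invariance are property-tested.

## The GC landscape

Windows tile each sequence from its origin and never span sequences
(scaffolds are independent coordinate systems); the trailing partial
window is dropped rather than rescaled so that every window at one scale
has identical length and SDs are comparable across scales. Per window,
GC is $(G+C)/(A+C+G+T)$: non-ACGT characters are excluded from the
denominator rather than counted as AT, so assembly gaps do not deflate
GC. A window whose non-ACGT fraction exceeds `max_n_fraction` (default
0.5) is marked invalid and carries no value — without such a rule,
window summaries over gappy scaffolds are ill defined. SD uses the
$n-1$ (sample) denominator.

For an i.i.d. sequence with per-base GC probability $p$, window GC at
window size $W$ is Binomial$(W, p)/W$, so its SD is
$\sqrt{p(1-p)/W}$ — the closed form the tests check at $W = 5$ kbp on
1 Mbp of simulated sequence — and halves for every fourfold increase in
$W$. A genome organised into isochores (blocks of homogeneous GC much
longer than the largest window) keeps its between-block variance at
every scale, so the SD-versus-scale curve plateaus. The
`isochore_contrast()` ratio (SD at the largest scale over SD at the
smallest) separates the two regimes: near 1 for block genomes, near
$\sqrt{W_{\min}/W_{\max}}$ (0.125 for 5 kbp vs 320 kbp) for homogeneous
ones; the tests use >0.8 and <0.3 as the decision band.

`component_gc()` computes GC over the union of each annotation
category's bases within each chromosome class, deduplicating overlapping
intervals before counting so a base annotated twice contributes once;
the weighted average of component GC over a partition of all bases
reconstructs whole-sequence GC to 1e-9, which the tests assert.

## Annotation accounting

Interval merging unions overlapping and book-ended intervals per
sequence and category (IRanges reduction); it is idempotent and
order-invariant. The repeat ledger reports per-method unions,
per-category unions across methods, the combined transposable-element
union excluding the tandem-repeat category, and the grand total
including it. The percent-of-genome denominator is the gap-free
(contig) base total by default — the denominator under which the
standard repeat-table percentages are internally consistent —
and is configurable to the scaffold total.

Gene length is the genomic span of the transcript including introns;
mRNA length is the exon sum; introns are the gaps between consecutive
exons, and the intron mean is taken over all introns of all genes.
Overlapping exons within one gene are rejected by name. RPKM is
$\mathrm{count} \times 10^9 / (\mathrm{length} \times
\mathrm{mapped\ total})$; support thresholds are strict (RPKM > 0, > 1,
> 5), and the Combined row counts genes exceeding the threshold in at
least one sample — a declared any-sample rule, since pooled-sample
recomputation would need per-sample mapped totals to be re-weighted and
reproduces no additional published quantity.

## The synthetic-data generators

Every generator is a pure function of its explicit seed (via
`withr::with_seed`; no hidden global state) and emits a truth record
sufficient to verify the downstream statistic without re-deriving it.

* `make_diploid_genome()` draws haplotype A from the GC model and
  creates haplotype B by substituting at per-base rate $h$ at uniformly
  chosen sites; default $h$ = 0.0085, the rate typical of a wild-caught
  outbred squamate. Variant positions are recorded exactly.
* `simulate_reads()` draws uniform start positions, splits coverage
  equally across haplotypes, and applies substitution errors only — no
  indels, no quality profiles, no GC-coverage bias. This suffices for
  every statistic in scope; it does *not* exercise error-spike
  structure in the k-mer spectrum (an error-free spectrum has no
  copy-number-1 spike), which is why the mode finder is tested on both
  simulated and constructed histograms.
* `make_assembly()` joins random contigs with N gaps and records the
  exact component lengths, so the assembly summary can be checked
  against construction rather than against itself.
* `plant_repeats()` places intervals whose union is exactly the
  requested genome fraction (stick-breaking placement), then adds
  redundant contained sub-intervals that leave the union unchanged, to
  exercise non-redundant accounting.
* The isochore generator defaults (1 Mbp blocks at GC 0.35/0.55, i.i.d.
  baseline $p$ = 0.418) give the plateau-versus-decay contrast at the
  5–320 kbp scales at which isochore structure is conventionally
  assessed.

What the generators do **not** emulate — real error profiles, indels,
structural variation, transposon sequence similarity, GC-biased
coverage — bounds what passing tests show: they validate the statistics'
arithmetic and conventions, not robustness to every artefact of real
sequencing.

## Problem sizes and runtime

The test suite and the worked examples use sizes chosen to make every
check statistically meaningful while keeping a full run comfortable on a
laptop: 100 kbp diploid genomes at 30× for parameter-recovery checks
(spectrum estimates land within a few percent; the 5 % acceptance band
reflects Poisson sampling of k-mer coverage at this depth), 1 Mbp of
i.i.d. sequence for the binomial SD check (200 windows at 5 kbp, giving
a ~5 % standard error on the SD), and 20 Mbp genomes for the
SD-versus-scale contrast (60+ windows at the 320 kbp scale).

## The pipeline

`run_pipeline()` validates its configuration up front (unknown keys and
missing stage inputs fail before any computation), executes the
requested stages in dependency order, and writes one TSV per result
table plus a `summary.json` embedding the package version, a
configuration hash and the seed. Run directories are write-once;
re-running the same configuration into a fresh directory is
byte-identical. The package is a library first: the pipeline function,
not a shell wrapper, is the orchestration surface, and
`scripts/acceptance.R` shows the intended scripted use.

## Known limitations

* The genome-size estimator assumes most of the genome is single-copy
  at the spectrum's homozygous mode; highly repetitive or polyploid
  genomes violate this and need mixture-model profiling, which is out
  of scope.
* Mode detection assumes a resolvable valley; spectra from very low
  coverage (hom mode below ~8) merge the peaks and trigger the
  monotone-histogram warning path.
* The parabolic refinement is exact for a locally quadratic peak; on
  strongly skewed peaks it biases slightly toward the heavy tail.
* `count_kmers()` is in-memory; read sets beyond a few Gbp should be
  counted with a disk-based external counter and imported via
  `read_spectrum()`.
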