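Package: glkit
Title: Genome Landscape Toolkit: K-mer Genome-Size Estimation, Assembly
    Statistics and GC Isochore Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-pass characterisation of a de novo genome
    assembly project: canonical k-mer spectrum counting and mode-based
    genome-size estimation from read sets, sequencing-effort accounting
    (read depth, physical coverage, picogram-to-basepair C-value
    conversion), assembly contiguity and gap statistics (Nx ladders,
    scaffold-to-contig decomposition, gap ratio), non-redundant repeat
    accounting over annotation intervals, gene-model summary statistics,
    RPKM expression-support ratios, and multi-scale windowed GC analysis
    with chromosome-class and genome-component breakdowns for detecting
    isochore structure. A synthetic-data module generates diploid
    genomes, read sets, gappy assemblies and annotations with known
    ground truth so every analysis can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    withr,
    IRanges,
    Biostrings,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
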