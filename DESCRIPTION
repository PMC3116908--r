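Package: imprintcall
Title: Parent-of-Origin Expression Calling from Reciprocal-Cross Allele-Specific Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of maternally and paternally expressed genes (MEGs and
    PEGs) in triploid endosperm from reciprocal-cross short-read data. Reads
    are assigned to parental haplotypes through 71-nt allele-specific SNP
    windows, per-gene maternal/paternal counts are tested against the 2m:1p
    endosperm null with a one-sided binomial test, reciprocal crosses are
    combined through the second-order joint p-value max(p1,p2)^2, and genes
    are selected by false-discovery rate. Downstream tools cover tissue
    signal-log-ratio expression filters, accession-dependence classification,
    parental splicing tests, transposable-element vicinity enrichment,
    sliding-window cluster detection with a permutation null, homolog and GO
    term enrichment, and metagene profiling of chromatin and methylation
    tracks. A seeded simulator generates complete synthetic input bundles
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
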