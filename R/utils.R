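#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. `N` maps to
#' `N`; input may be upper case only.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run `expr` under a temporary RNG state when `seed` is given, otherwise use
# the session RNG stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# genes/tes tibbles use 0-based half-open [start, end); IRanges is 1-based
# inclusive
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

check_fractions <- function(x, names) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    config_error(paste0(
      "fractions out of [0,1]: ",
      paste(names[bad], collapse = ", ")
    ))
  }
  invisible(TRUE)
}
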