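#' Assign reads to SNP windows and alleles
#'
#' Every read is aligned full-length and ungapped at every offset of every
#' non-discarded window, in forward and reverse-complement orientation; the
#' best score is the fewest mismatches, with at most `max_mismatches`
#' tolerated and `N` counting as a mismatch. Outcomes:
#' \describe{
#'   \item{assigned}{all best alignments fall in windows of one SNP and one
#'     allele (or of several SNPs of the same gene, same allele — the read
#'     is counted once for that gene).}
#'   \item{allele_ambiguous}{best alignments tie between the A and B
#'     windows (the read does not cover the discriminating position), or
#'     between different alleles of SNPs of one gene.}
#'   \item{locus_ambiguous}{best alignments touch SNPs that do not share a
#'     single gene.}
#'   \item{too_many_mismatches}{no alignment with `<= max_mismatches`.}
#' }
#'
#' @param reads tibble with `read_id` and `seq` (reads no longer than the
#'   windows).
#' @param windows window tibble from [assign_gene_to_windows()].
#' @param max_mismatches maximum tolerated mismatches (default 2).
#' @return tibble `read_id`, `snp_id`, `allele`, `gene_id`, `mismatches`,
#'   `status`; exactly one row per read.
#' @export
assign_reads <- function(reads, windows, max_mismatches = 2L) {
  live <- windows[is.na(windows$discarded), ]
  if (nrow(live) == 0) config_error("empty window set")
  if (any(nchar(reads$seq) > min(nchar(live$seq)))) {
    config_error("read length exceeds window length")
  }
  scan <- scan_reads_cpp(reads$seq, live$seq, as.integer(max_mismatches))
  n_hits <- lengths(scan$hits)
  hit_long <- tibble(
    read = rep.int(seq_len(nrow(reads)), n_hits),
    win = unlist(scan$hits, use.names = FALSE)
  )
  hit_long$snp_id <- live$snp_id[hit_long$win]
  hit_long$allele <- live$allele[hit_long$win]
  hit_long$gene_id <- live$gene_id[hit_long$win]

  verdict <- hit_long |>
    group_by(.data$read) |>
    summarise(
      n_snp = n_distinct(.data$snp_id),
      n_allele = n_distinct(.data$allele),
      one_gene = n_distinct(.data$gene_id) == 1 && !is.na(.data$gene_id[1]),
      snp_id = .data$snp_id[1],
      allele = .data$allele[1],
      gene_id = .data$gene_id[1],
      .groups = "drop"
    ) |>
    mutate(
      status = case_when(
        .data$n_snp == 1 & .data$n_allele > 1 ~ "allele_ambiguous",
        .data$n_snp == 1 ~ "assigned",
        .data$one_gene & .data$n_allele == 1 ~ "assigned",
        .data$one_gene ~ "allele_ambiguous",
        TRUE ~ "locus_ambiguous"
      )
    )

  out <- tibble(
    read_id = reads$read_id,
    snp_id = NA_character_,
    allele = NA_character_,
    gene_id = NA_character_,
    mismatches = ifelse(
      scan$best_mm > max_mismatches, NA_integer_, scan$best_mm
    ),
    status = ifelse(
      scan$best_mm > max_mismatches, "too_many_mismatches", NA_character_
    )
  )
  keep <- verdict$status == "assigned"
  out$status[verdict$read] <- verdict$status
  out$snp_id[verdict$read[keep]] <- verdict$snp_id[keep]
  out$allele[verdict$read[keep]] <- verdict$allele[keep]
  out$gene_id[verdict$read[keep]] <- verdict$gene_id[keep]
  out
}

#' Aggregate read assignments into a per-gene allele count table
#'
#' In cross `AxB` (A as mother) allele-A reads are maternal; in cross
#' `BxA` they are paternal. Only assigned reads whose window has a gene are
#' counted; genes listed in `genes` with no assigned reads appear with
#' `m = p = 0`.
#'
#' @param assignments tibble from [assign_reads()].
#' @param cross_design `"AxB"` or `"BxA"`.
#' @param genes optional character vector (or tibble with `gene_id`) fixing
#'   the gene universe.
#' @return tibble `gene_id`, `cross`, `m`, `p`.
#' @export
count_alleles <- function(assignments, cross_design = c("AxB", "BxA"),
                          genes = NULL) {
  cross_design <- match.arg(cross_design)
  maternal_allele <- if (cross_design == "AxB") "A" else "B"
  a <- assignments |>
    filter(.data$status == "assigned", !is.na(.data$gene_id))
  counts <- a |>
    group_by(.data$gene_id) |>
    summarise(
      m = sum(.data$allele == maternal_allele),
      p = sum(.data$allele != maternal_allele),
      .groups = "drop"
    )
  if (!is.null(genes)) {
    universe <- if (is.data.frame(genes)) genes$gene_id else genes
    counts <- tibble(gene_id = universe) |>
      left_join(counts, by = "gene_id") |>
      mutate(
        m = tidyr::replace_na(.data$m, 0L),
        p = tidyr::replace_na(.data$p, 0L)
      )
  }
  counts |>
    mutate(cross = cross_design, .after = "gene_id") |>
    arrange(.data$gene_id)
}

#' Per-SNP allele counts for the parental splicing test
#'
#' @inheritParams count_alleles
#' @return tibble `gene_id`, `snp_id`, `cross`, `m`, `p`.
#' @export
count_alleles_by_snp <- function(assignments, cross_design = c("AxB", "BxA")) {
  cross_design <- match.arg(cross_design)
  maternal_allele <- if (cross_design == "AxB") "A" else "B"
  assignments |>
    filter(.data$status == "assigned", !is.na(.data$gene_id)) |>
    group_by(.data$gene_id, .data$snp_id) |>
    summarise(
      m = sum(.data$allele == maternal_allele),
      p = sum(.data$allele != maternal_allele),
      .groups = "drop"
    ) |>
    mutate(cross = cross_design, .after = "snp_id")
}
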