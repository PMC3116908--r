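#' Metagene profile of one gene
#'
#' Bins a per-position signal track around a gene into 60 ordered bins:
#' 20 fixed-width flank bins upstream (covering `flank` bp in
#' `flank_bin`-bp steps), 20 gene-body bins each covering 5% of the gene
#' length (body bin `i` spans genomic offsets
#' `[floor((i-1) L / 20), floor(i L / 20))`, an exact partition), and 20
#' flank bins downstream. Bin 1 of each segment is always at the 5' end:
#' minus-strand genes have flanks and bin order mirrored. Bin values are
#' means over positions present in the track; positions without data
#' (including flanks running off a chromosome end) are excluded, and a bin
#' with no data is `NA` with coverage 0.
#'
#' @param track tibble `chrom`, `pos` (0-based), `value` (see
#'   [read_signal_track()]).
#' @param gene one-row tibble (or list) with `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param flank flank width in bp (default 2000).
#' @param flank_bin flank bin width in bp (default 100).
#' @param body_bins number of gene-body bins (default 20).
#' @return tibble of class `metagene_profile`: `segment`
#'   (`upstream`/`body`/`downstream`), `bin` (1..60 overall), `mean`,
#'   `n` (positions with data).
#' @export
gene_profile <- function(track, gene, flank = 2000L, flank_bin = 100L,
                         body_bins = 20L) {
  gene <- as.list(gene)
  L <- gene$end - gene$start
  if (L < body_bins) {
    config_error(sprintf(
      "gene shorter than %d bp cannot form %d non-empty body bins",
      body_bins, body_bins
    ))
  }
  n_flank <- flank %/% flank_bin
  # genomic breakpoints of the 60 bins, 5' to 3' in transcription direction
  body_cuts <- gene$start + floor(seq(0, body_bins) * L / body_bins)
  if (gene$strand == "-") {
    up <- lapply(seq_len(n_flank), function(j) {
      c(gene$end + flank - j * flank_bin, gene$end + flank - (j - 1) * flank_bin)
    })
    body <- lapply(seq_len(body_bins), function(i) {
      c(gene$end - (body_cuts[i + 1] - gene$start),
        gene$end - (body_cuts[i] - gene$start))
    })
    down <- lapply(seq_len(n_flank), function(j) {
      c(gene$start - j * flank_bin, gene$start - (j - 1) * flank_bin)
    })
  } else {
    up <- lapply(seq_len(n_flank), function(j) {
      c(gene$start - flank + (j - 1) * flank_bin,
        gene$start - flank + j * flank_bin)
    })
    body <- lapply(seq_len(body_bins), function(i) {
      c(body_cuts[i], body_cuts[i + 1])
    })
    down <- lapply(seq_len(n_flank), function(j) {
      c(gene$end + (j - 1) * flank_bin, gene$end + j * flank_bin)
    })
  }
  bins <- c(up, body, down)
  seg <- rep(
    c("upstream", "body", "downstream"),
    c(n_flank, body_bins, n_flank)
  )
  tr <- track[track$chrom == gene$chrom, ]
  stats <- vapply(bins, function(b) {
    v <- tr$value[tr$pos >= b[1] & tr$pos < b[2]]
    c(mean = if (length(v) > 0) mean(v) else NA_real_, n = length(v))
  }, numeric(2))
  structure(
    tibble(
      segment = seg,
      bin = seq_along(bins),
      mean = stats["mean", ],
      n = as.integer(stats["n", ])
    ),
    class = c("metagene_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Averaged metagene profile of a gene set
#'
#' Per-bin unweighted mean over the per-gene profiles (genes lacking data
#' in a bin do not contribute to it), with the number of contributing
#' genes per bin, and the reference level at the transcription start: the
#' mean over a reference gene set of the first gene-body bin.
#'
#' @param track tibble `chrom`, `pos`, `value`.
#' @param genes tibble of genes (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`); genes shorter than `body_bins` bp are skipped with a
#'   warning.
#' @param reference optional gene tibble for the TSS reference line
#'   (defaults to `genes`).
#' @inheritParams gene_profile
#' @return tibble of class `metagene_profile` with attribute
#'   `tss_reference`. Supports [autoplot()].
#' @export
group_profile <- function(track, genes, reference = NULL, flank = 2000L,
                          flank_bin = 100L, body_bins = 20L) {
  if (nrow(genes) == 0) config_error("empty gene set")
  prof_set <- function(gs) {
    short <- gs$end - gs$start < body_bins
    if (any(short)) {
      warn(sprintf("%d gene(s) shorter than %d bp skipped",
                   sum(short), body_bins))
      gs <- gs[!short, ]
    }
    if (nrow(gs) == 0) config_error("no profilable gene")
    lapply(seq_len(nrow(gs)), function(i) {
      gene_profile(track, gs[i, ], flank, flank_bin, body_bins)
    })
  }
  profs <- prof_set(genes)
  stacked <- bind_rows(profs, .id = "gene")
  out <- stacked |>
    group_by(.data$segment, .data$bin) |>
    summarise(
      mean = if (any(.data$n > 0)) mean(.data$mean[.data$n > 0]) else NA_real_,
      n = sum(.data$n > 0),
      .groups = "drop"
    ) |>
    arrange(.data$bin)
  ref_profs <- if (is.null(reference)) profs else prof_set(reference)
  first_body <- vapply(ref_profs, function(p) {
    p$mean[p$segment == "body"][1]
  }, numeric(1))
  tss_ref <- if (all(is.na(first_body))) NA_real_ else
    mean(first_body, na.rm = TRUE)
  structure(
    out,
    tss_reference = tss_ref,
    class = c("metagene_profile", class(out))
  )
}

#' @rdname group_profile
#' @param object a `metagene_profile`.
#' @param ... unused.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  tss_ref <- attr(object, "tss_reference")
  body_rng <- range(object$bin[object$segment == "body"])
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$bin, .data$mean)) +
    ggplot2::geom_vline(
      xintercept = c(body_rng[1] - 0.5, body_rng[2] + 0.5),
      linetype = 3, colour = "grey50"
    ) +
    ggplot2::geom_line(colour = "#c0392b") +
    ggplot2::labs(
      x = "bin (20 upstream | 20 gene body | 20 downstream)",
      y = "mean signal"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(tss_ref) && !is.na(tss_ref)) {
    p <- p + ggplot2::geom_hline(
      yintercept = tss_ref, linetype = 2, colour = "grey30"
    )
  }
  p
}
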