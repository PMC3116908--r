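#' Transposable elements in the vicinity of genes
#'
#' Flags genes with at least one TE intersecting the interval
#' `[gene_start - vicinity_bp, gene_end + vicinity_bp)`, reports which
#' superfamilies do so, and measures the signed distance from the nearest
#' TE edge to the strand-aware transcription start (5') and stop (3'),
#' zero when the TE overlaps the point, positive downstream in
#' transcription direction, negative upstream.
#'
#' @param genes tibble `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param tes tibble `te_id`, `chrom`, `start`, `end`, `superfamily`.
#' @param vicinity_bp flank width in bp (default 2000).
#' @return tibble `gene_id`, `has_te`, `superfamilies` (list column),
#'   `dist_5prime`, `dist_3prime` (`NA` when the chromosome has no TE).
#' @export
te_vicinity <- function(genes, tes, vicinity_bp = 2000L) {
  vic <- genes
  vic$start <- pmax(genes$start - vicinity_bp, 0L)
  vic$end <- genes$end + vicinity_bp
  if (nrow(tes) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(vic), as_granges0(tes))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
  } else {
    qh <- integer()
    sh <- integer()
  }
  fams <- lapply(seq_len(nrow(genes)), function(i) {
    sort(unique(tes$superfamily[sh[qh == i]]))
  })
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  tes_pos <- ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  dist_to <- function(point, strand) {
    vapply(seq_along(point), function(i) {
      t <- tes[tes$chrom == genes$chrom[i], ]
      if (nrow(t) == 0) return(NA_real_)
      inside <- point[i] >= t$start & point[i] < t$end
      if (any(inside)) return(0)
      d_right <- t$start - point[i]   # TE entirely right of the point
      d_left <- point[i] - (t$end - 1L)
      d <- ifelse(d_right > 0, d_right, -d_left)
      d_signed <- if (strand[i] == "-") -d else d
      d_signed[which.min(abs(d))]
    }, numeric(1))
  }
  tibble(
    gene_id = genes$gene_id,
    has_te = tabulate(qh, nbins = nrow(genes)) > 0,
    superfamilies = fams,
    dist_5prime = dist_to(tss, genes$strand),
    dist_3prime = dist_to(tes_pos, genes$strand)
  )
}

#' Long-format per-superfamily TE flags
#'
#' @param vicinity output of [te_vicinity()].
#' @param superfamilies optional character vector fixing the superfamily
#'   set (defaults to all observed).
#' @return tibble `gene_id`, `superfamily`, `has_te`.
#' @export
te_superfamily_flags <- function(vicinity, superfamilies = NULL) {
  fams <- superfamilies %||%
    sort(unique(unlist(vicinity$superfamilies)))
  tidyr::expand_grid(
    gene_id = vicinity$gene_id, superfamily = fams
  ) |>
    left_join(
      vicinity |> select("gene_id", "superfamilies"),
      by = "gene_id"
    ) |>
    mutate(
      has_te = purrr::map2_lgl(
        .data$superfamily, .data$superfamilies, ~ .x %in% .y
      )
    ) |>
    select("gene_id", "superfamily", "has_te")
}

#' Hypergeometric and permutation enrichment test
#'
#' Upper-tail hypergeometric probability of observing at least
#' `flagged_in_sample` flagged genes in a sample of `sample_size` drawn
#' from a population of `population_size` containing
#' `flagged_in_population` flagged genes, together with a permutation
#' p-value from `n_perm` random samples drawn without replacement
#' (`(1 + #{X* >= x}) / (n_perm + 1)`).
#'
#' @param flagged_in_sample,sample_size,flagged_in_population,population_size
#'   counts; sample counts must be consistent with the population.
#' @param n_perm permutation draws (default 10000).
#' @param seed optional integer seed.
#' @return one-row tibble `k`, `n`, `K`, `N`, `hyper_p`, `perm_p`,
#'   `n_perm`.
#' @export
enrichment_test <- function(flagged_in_sample, sample_size,
                            flagged_in_population, population_size,
                            n_perm = 10000, seed = NULL) {
  k <- flagged_in_sample
  n <- sample_size
  K <- flagged_in_population
  N <- population_size
  if (k > n || K > N || n > N || k > K || k < 0) {
    config_error("inconsistent enrichment counts")
  }
  hyper_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  flags <- rep(c(TRUE, FALSE), c(K, N - K))
  perm <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(flags[sample.int(N, n)])
    }, numeric(1))
  })
  perm_p <- (1 + sum(perm >= k)) / (n_perm + 1)
  tibble(
    k = k, n = n, K = K, N = N,
    hyper_p = hyper_p, perm_p = perm_p, n_perm = n_perm
  )
}

#' Sliding-window cluster scan with a permutation null
#'
#' Slides a window of `window_w` genes (step one gene, trailing partial
#' windows dropped) along each chromosome's genomic gene order and counts
#' flagged genes per window. The null distribution pools per-window counts
#' from `n_perm` permutations in which the same number of flags is placed
#' uniformly at random over all genes. A window is significant when
#' `P_null(count >= observed) < alpha`; overlapping significant windows
#' are merged into clusters.
#'
#' @param gene_order tibble `gene_id`, `chrom` with rows in genomic order
#'   (or a character vector of gene ids for a single chromosome).
#' @param flagged character vector of flagged gene ids.
#' @param window_w window size in genes (default 50).
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed.
#' @return object of class `window_scan`: list with `windows` tibble
#'   (`chrom`, `win`, `start_gene`, `end_gene`, `count`, `p`,
#'   `significant`), `clusters` tibble (`chrom`, `start_gene`,
#'   `end_gene`, `n_flagged`, `members` list column, `p`), `null_counts`
#'   tabulation, and `params`. Supports [autoplot()].
#' @export
scan_clusters <- function(gene_order, flagged, window_w = 50L,
                          n_perm = 1000, alpha = 0.05, seed = NULL) {
  if (is.character(gene_order)) {
    gene_order <- tibble(gene_id = gene_order, chrom = "chr")
  }
  stray <- setdiff(flagged, gene_order$gene_id)
  if (length(stray) > 0) {
    config_error(paste0(
      "flagged gene(s) not in gene order: ", paste(head(stray, 5),
                                                   collapse = ", ")
    ))
  }
  n_genes <- nrow(gene_order)
  if (window_w > n_genes) {
    config_error("window_w exceeds the number of genes")
  }
  chrom_sizes <- table(gene_order$chrom)[unique(gene_order$chrom)]
  flag_vec <- gene_order$gene_id %in% flagged
  window_counts <- function(fv) {
    unlist(lapply(split(fv, gene_order$chrom)[unique(gene_order$chrom)],
                  function(v) {
      if (length(v) < window_w) return(integer())
      cs <- c(0L, cumsum(v))
      cs[(window_w + 1):length(cs)] - cs[1:(length(cs) - window_w)]
    }), use.names = FALSE)
  }
  obs <- window_counts(flag_vec)
  if (length(obs) == 0 || length(flagged) == 0) {
    empty <- tibble(
      chrom = character(), win = integer(), start_gene = character(),
      end_gene = character(), count = integer(), p = numeric(),
      significant = logical()
    )
    return(structure(
      list(
        windows = empty,
        clusters = tibble(
          chrom = character(), start_gene = character(),
          end_gene = character(), n_flagged = integer(),
          members = list(), p = numeric()
        ),
        null_counts = integer(),
        params = list(window_w = window_w, n_perm = n_perm, alpha = alpha)
      ),
      class = "window_scan"
    ))
  }
  n_flag <- sum(flag_vec)
  null_counts <- with_seed_if(seed, {
    unlist(lapply(seq_len(n_perm), function(i) {
      fv <- logical(n_genes)
      fv[sample.int(n_genes, n_flag)] <- TRUE
      window_counts(fv)
    }), use.names = FALSE)
  })
  null_tab <- tabulate(null_counts + 1L, nbins = window_w + 1L)
  n_null <- length(null_counts)
  # P(count >= c) from the pooled tabulation, +1/(N+1) estimator
  upper_tail <- rev(cumsum(rev(null_tab)))
  p_of <- function(cnt) (1 + upper_tail[cnt + 1L]) / (n_null + 1)
  chrom_of_win <- rep(
    names(chrom_sizes),
    pmax(as.integer(chrom_sizes) - window_w + 1L, 0L)
  )
  win_in_chrom <- unlist(lapply(
    pmax(as.integer(chrom_sizes) - window_w + 1L, 0L), seq_len
  ))
  offset <- c(0L, cumsum(as.integer(chrom_sizes)))[
    match(chrom_of_win, names(chrom_sizes))
  ]
  start_idx <- offset + win_in_chrom
  windows <- tibble(
    chrom = chrom_of_win,
    win = win_in_chrom,
    start_gene = gene_order$gene_id[start_idx],
    end_gene = gene_order$gene_id[start_idx + window_w - 1L],
    count = obs,
    p = p_of(obs),
    significant = p_of(obs) < alpha
  )
  clusters <- merge_windows(windows, gene_order, flag_vec, start_idx, window_w)
  structure(
    list(
      windows = windows, clusters = clusters, null_counts = null_tab,
      params = list(window_w = window_w, n_perm = n_perm, alpha = alpha)
    ),
    class = "window_scan"
  )
}

merge_windows <- function(windows, gene_order, flag_vec, start_idx,
                          window_w) {
  sig <- which(windows$significant)
  if (length(sig) == 0) {
    return(tibble(
      chrom = character(), start_gene = character(),
      end_gene = character(), n_flagged = integer(),
      members = list(), p = numeric()
    ))
  }
  s <- start_idx[sig]
  e <- s + window_w - 1L
  grp <- cumsum(
    c(TRUE, s[-1] > head(e, -1) + 0L |
        windows$chrom[sig][-1] != head(windows$chrom[sig], -1))
  )
  out <- lapply(split(seq_along(sig), grp), function(ix) {
    lo <- min(s[ix])
    hi <- max(e[ix])
    members <- gene_order$gene_id[lo:hi][flag_vec[lo:hi]]
    tibble(
      chrom = windows$chrom[sig[ix[1]]],
      start_gene = gene_order$gene_id[lo],
      end_gene = gene_order$gene_id[hi],
      n_flagged = length(members),
      members = list(members),
      p = min(windows$p[sig[ix]])
    )
  })
  bind_rows(out)
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf(
    "<window_scan> %d windows of %d genes; %d significant (alpha %g), %d cluster(s)\n",
    nrow(x$windows), x$params$window_w,
    sum(x$windows$significant), x$params$alpha, nrow(x$clusters)
  ))
  invisible(x)
}

#' @rdname scan_clusters
#' @param object a `window_scan` object.
#' @param ... unused.
#' @method autoplot window_scan
#' @export
autoplot.window_scan <- function(object, ...) {
  d <- object$windows |>
    group_by(.data$chrom) |>
    mutate(x = row_number()) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$count)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(
      data = d |> filter(.data$significant),
      colour = "#c0392b", size = 1.5
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "window start (gene index)",
      y = sprintf("flagged genes per %d-gene window", object$params$window_w)
    ) +
    ggplot2::theme_minimal()
}

#' Close-homolog frequency enrichment
#'
#' Flags each gene that has at least one close homolog other than itself
#' and tests whether the sample set is enriched for such genes relative to
#' the gene universe, via [enrichment_test()].
#'
#' @param homologs tibble of homolog pairs with columns `gene_id`,
#'   `homolog` (directed pairs; self-hits ignored). See
#'   [read_blast_pairs()].
#' @param universe character vector of genes forming the population.
#' @param sample_set character vector of sample genes (must be in the
#'   universe).
#' @inheritParams enrichment_test
#' @return one-row tibble as [enrichment_test()].
#' @export
homolog_frequency <- function(homologs, universe, sample_set,
                              n_perm = 10000, seed = NULL) {
  stray <- setdiff(sample_set, universe)
  if (length(stray) > 0) {
    config_error(paste0(
      "sample gene(s) absent from universe: ",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  pairs <- homologs |> filter(.data$gene_id != .data$homolog)
  has_hom <- universe %in% pairs$gene_id
  enrichment_test(
    flagged_in_sample = sum(sample_set %in% universe[has_hom]),
    sample_size = length(sample_set),
    flagged_in_population = sum(has_hom),
    population_size = length(universe),
    n_perm = n_perm, seed = seed
  )
}

#' Read BLAST tabular output (outfmt 6) into homolog pairs
#'
#' @param path BLAST outfmt-6 TSV (qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' @param max_evalue e-value cutoff (default 0.01).
#' @return tibble `gene_id`, `homolog`, `evalue`.
#' @export
read_blast_pairs <- function(path, max_evalue = 0.01) {
  x <- readr::read_tsv(
    path,
    col_names = c(
      "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
      "qstart", "qend", "sstart", "send", "evalue", "bitscore"
    ),
    show_col_types = FALSE
  )
  x |>
    filter(.data$evalue <= max_evalue) |>
    transmute(
      gene_id = .data$qseqid, homolog = .data$sseqid, evalue = .data$evalue
    )
}

#' GO-term enrichment by hypergeometric test
#'
#' Per term annotating at least one universe gene, computes the upper-tail
#' hypergeometric p-value of the sample membership, adjusts across terms
#' by the Benjamini-Hochberg step-up, and reports terms with adjusted
#' p below `p_crit`.
#'
#' @param annotations tibble `gene_id`, `term`.
#' @param sample_set,universe character vectors of gene ids.
#' @param p_crit critical adjusted p-value (default 5.0e-3).
#' @return tibble `term`, `k`, `n`, `K`, `N`, `p`, `p_adj`,
#'   `significant`, ascending in `p`.
#' @export
go_enrichment <- function(annotations, sample_set, universe,
                          p_crit = 5.0e-3) {
  if (length(universe) == 0) config_error("empty gene universe")
  ann <- annotations |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$term)
  if (nrow(ann) == 0) config_error("no term annotates any universe gene")
  res <- ann |>
    group_by(.data$term) |>
    summarise(
      K = n_distinct(.data$gene_id),
      k = n_distinct(.data$gene_id[.data$gene_id %in% sample_set]),
      .groups = "drop"
    ) |>
    mutate(
      n = length(sample_set),
      N = length(universe),
      p = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                 lower.tail = FALSE),
      p_adj = p.adjust(.data$p, method = "BH"),
      significant = .data$p_adj < p_crit
    ) |>
    select("term", "k", "n", "K", "N", "p", "p_adj", "significant") |>
    arrange(.data$p)
  res
}
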