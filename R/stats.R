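#' One-sided binomial test against the 2m:1p endosperm null
#'
#' The triploid endosperm carries two maternal genomes and one paternal
#' genome, so unbiased biallelic expression predicts a maternal read
#' fraction of 2/3. The maternal direction returns the exact upper tail
#' `P(X >= m)` for `X ~ Binomial(m + p, maternal_null)`; the paternal
#' direction returns `P(X >= p)` under success probability
#' `1 - maternal_null`. Exact tail sums; vectorised over `m` and `p`.
#'
#' @param m,p maternal and paternal read counts (non-negative integers,
#'   `m + p >= 1`).
#' @param maternal_null maternal fraction under the null (default 2/3).
#' @param direction `"maternal"` or `"paternal"`.
#' @return numeric vector of p-values.
#' @export
binom_onesided <- function(m, p, maternal_null = 2 / 3,
                           direction = c("maternal", "paternal")) {
  direction <- match.arg(direction)
  if (any(m < 0 | p < 0)) config_error("negative counts")
  n <- m + p
  if (any(n < 1)) {
    config_error("binom_onesided undefined for m + p = 0")
  }
  if (maternal_null <= 0 || maternal_null >= 1) {
    config_error("maternal_null must lie strictly in (0, 1)")
  }
  if (direction == "maternal") {
    pbinom(m - 1, n, maternal_null, lower.tail = FALSE)
  } else {
    pbinom(p - 1, n, 1 - maternal_null, lower.tail = FALSE)
  }
}

#' Joint p-value of two reciprocal crosses
#'
#' Combines the two one-sided p-values of the reciprocal crosses through
#' the distribution of the second-order statistic: for independent uniform
#' p-values, `P(max(P1, P2) <= x) = x^2`, so `max(p1, p2)^2` is the joint
#' p-value demanding consistency in both crosses.
#'
#' @param p1,p2 p-values in `[0, 1]` (vectorised).
#' @return numeric vector `pmax(p1, p2)^2`.
#' @export
joint_p <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    config_error("p-values must lie in [0, 1]")
  }
  pmax(p1, p2)^2
}

#' Rank-based FDR selection
#'
#' Sorts joint p-values ascending and computes `q_raw = p * n / i` for rank
#' `i` of `n`, then applies the step-up monotonisation (cumulative minimum
#' from the largest rank) and clips at 1, so that selection at a q
#' threshold is consistent; tied p-values share the smaller q.
#'
#' @param joint_ps named numeric vector (names are gene ids) or plain
#'   numeric vector of p-values.
#' @param q_threshold selection threshold (default 0.05).
#' @return tibble `gene_id`, `p`, `rank`, `q_raw`, `q`, `selected`, in
#'   ascending p order.
#' @export
fdr_select <- function(joint_ps, q_threshold = 0.05) {
  if (length(joint_ps) == 0) {
    return(tibble(
      gene_id = character(), p = numeric(), rank = integer(),
      q_raw = numeric(), q = numeric(), selected = logical()
    ))
  }
  if (any(joint_ps < 0 | joint_ps > 1)) {
    config_error("p-values must lie in [0, 1]")
  }
  ids <- names(joint_ps) %||% as.character(seq_along(joint_ps))
  ord <- order(joint_ps)
  p <- unname(joint_ps[ord])
  n <- length(p)
  q_raw <- p * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q_raw))), 1)
  tibble(
    gene_id = ids[ord], p = p, rank = seq_len(n),
    q_raw = q_raw, q = q, selected = q <= q_threshold
  )
}

#' Call maternally and paternally expressed genes from reciprocal crosses
#'
#' For each gene testable in both crosses (at least one informative read
#' per cross), computes the four one-sided binomial p-values against the
#' 2m:1p null, combines each direction across crosses with
#' [joint_p()], and runs [fdr_select()] separately on the maternal and the
#' paternal joint p-values over the same gene universe. Genes with
#' `q <= q_threshold` in the maternal direction are called MEGs, in the
#' paternal direction PEGs; a gene selected in both directions (possible
#' only pathologically) is set to `none` with a warning.
#'
#' @param counts tibble `gene_id`, `cross` (`"AxB"`/`"BxA"`), `m`, `p`.
#' @param maternal_null maternal fraction under the null.
#' @param q_threshold FDR threshold.
#' @return object of class `imprint_calls`: list with `calls` tibble
#'   (per-gene p-values, joint p-values, raw and monotone q, `call`),
#'   `params`, `n_tested`, `excluded` (genes testable in only one cross).
#'   Supports [tidy()], [glance()], and [autoplot()].
#' @export
call_imprinting <- function(counts, maternal_null = 2 / 3,
                            q_threshold = 0.05) {
  if (!all(c("AxB", "BxA") %in% counts$cross)) {
    config_error("counts must contain both crosses AxB and BxA")
  }
  wide <- counts |>
    filter(.data$m + .data$p >= 1) |>
    tidyr::pivot_wider(
      id_cols = "gene_id", names_from = "cross",
      values_from = c("m", "p")
    )
  excluded <- wide$gene_id[
    is.na(wide$m_AxB) | is.na(wide$m_BxA)
  ]
  if (length(excluded) > 0) {
    message(sprintf(
      "%d gene(s) testable in only one cross excluded", length(excluded)
    ))
  }
  wide <- wide[!wide$gene_id %in% excluded, ]
  calls <- wide |>
    mutate(
      p_maternal_cross1 = binom_onesided(
        .data$m_AxB, .data$p_AxB, maternal_null, "maternal"
      ),
      p_maternal_cross2 = binom_onesided(
        .data$m_BxA, .data$p_BxA, maternal_null, "maternal"
      ),
      p_paternal_cross1 = binom_onesided(
        .data$m_AxB, .data$p_AxB, maternal_null, "paternal"
      ),
      p_paternal_cross2 = binom_onesided(
        .data$m_BxA, .data$p_BxA, maternal_null, "paternal"
      ),
      joint_p_maternal = joint_p(
        .data$p_maternal_cross1, .data$p_maternal_cross2
      ),
      joint_p_paternal = joint_p(
        .data$p_paternal_cross1, .data$p_paternal_cross2
      )
    )
  fdr_mat <- fdr_select(
    setNames(calls$joint_p_maternal, calls$gene_id), q_threshold
  )
  fdr_pat <- fdr_select(
    setNames(calls$joint_p_paternal, calls$gene_id), q_threshold
  )
  calls <- calls |>
    left_join(
      fdr_mat |>
        select("gene_id", q_raw_maternal = "q_raw", q_maternal = "q"),
      by = "gene_id"
    ) |>
    left_join(
      fdr_pat |>
        select("gene_id", q_raw_paternal = "q_raw", q_paternal = "q"),
      by = "gene_id"
    ) |>
    mutate(
      call = case_when(
        .data$q_maternal <= q_threshold &
          .data$q_paternal <= q_threshold ~ "both",
        .data$q_maternal <= q_threshold ~ "MEG",
        .data$q_paternal <= q_threshold ~ "PEG",
        TRUE ~ "none"
      )
    )
  if (any(calls$call == "both")) {
    warn(sprintf(
      "%d gene(s) significant in both directions set to 'none'",
      sum(calls$call == "both")
    ))
    calls$call[calls$call == "both"] <- "none"
  }
  structure(
    list(
      calls = calls,
      params = list(
        maternal_null = maternal_null, q_threshold = q_threshold
      ),
      n_tested = nrow(calls),
      excluded = excluded
    ),
    class = "imprint_calls"
  )
}

#' @export
print.imprint_calls <- function(x, ...) {
  cat(sprintf(
    "<imprint_calls> %d genes tested (null maternal fraction %.4f)\n",
    x$n_tested, x$params$maternal_null
  ))
  cat(sprintf(
    "  MEG: %d  PEG: %d  (q <= %g)\n",
    sum(x$calls$call == "MEG"), sum(x$calls$call == "PEG"),
    x$params$q_threshold
  ))
  invisible(x)
}

#' @rdname call_imprinting
#' @param x an `imprint_calls` object.
#' @param ... unused.
#' @method tidy imprint_calls
#' @export
tidy.imprint_calls <- function(x, ...) {
  x$calls
}

#' @rdname call_imprinting
#' @method glance imprint_calls
#' @export
glance.imprint_calls <- function(x, ...) {
  tibble(
    n_tested = x$n_tested,
    n_meg = sum(x$calls$call == "MEG"),
    n_peg = sum(x$calls$call == "PEG"),
    n_excluded = length(x$excluded),
    maternal_null = x$params$maternal_null,
    q_threshold = x$params$q_threshold
  )
}

#' @rdname call_imprinting
#' @param object an `imprint_calls` object.
#' @method autoplot imprint_calls
#' @export
autoplot.imprint_calls <- function(object, ...) {
  d <- object$calls |>
    mutate(
      mf_AxB = .data$m_AxB / (.data$m_AxB + .data$p_AxB),
      mf_BxA = .data$m_BxA / (.data$m_BxA + .data$p_BxA)
    )
  ggplot2::ggplot(
    d, ggplot2::aes(.data$mf_AxB, .data$mf_BxA, colour = .data$call)
  ) +
    ggplot2::geom_hline(
      yintercept = object$params$maternal_null, linetype = 2, colour = "grey50"
    ) +
    ggplot2::geom_vline(
      xintercept = object$params$maternal_null, linetype = 2, colour = "grey50"
    ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(MEG = "#c0392b", PEG = "#2980b9", none = "grey70")
    ) +
    ggplot2::labs(
      x = "maternal read fraction, cross A×B",
      y = "maternal read fraction, cross B×A",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' Classify accession dependence of imprinted calls
#'
#' Compares, within each accession, the maternal against the paternal
#' expression of the same alleles across the reciprocal crosses: for
#' accession A, the maternal count from cross A×B against the paternal
#' count from cross B×A (and symmetrically for B). A MEG is imprinted in an
#' accession when its maternal alleles exceed the paternal allele
#' `meg_fold`-fold (default 5); a PEG when the paternal allele exceeds the
#' maternal alleles `peg_fold`-fold (default 3). Imprinted in both
#' accessions is `reciprocal`, in one `A_only`/`B_only`. Counts are
#' normalised per million gene-assigned reads per cross library unless
#' `library_norm = FALSE`. A zero denominator with a positive numerator is
#' an infinite ratio; 0/0 gives `not_applicable`.
#'
#' @param counts tibble `gene_id`, `cross`, `m`, `p`.
#' @param calls an `imprint_calls` object or a tibble with `gene_id` and
#'   `call`.
#' @param meg_fold,peg_fold fold thresholds.
#' @param library_norm normalise per million assigned reads per cross.
#' @return tibble `gene_id`, `call`, `ratio_A`, `ratio_B`,
#'   `accession_class`.
#' @export
classify_accession_dependence <- function(counts, calls, meg_fold = 5,
                                          peg_fold = 3, library_norm = TRUE) {
  calls_df <- if (inherits(calls, "imprint_calls")) calls$calls else calls
  totals <- counts |>
    group_by(.data$cross) |>
    summarise(total = sum(.data$m + .data$p), .groups = "drop")
  wide <- counts |>
    left_join(totals, by = "cross") |>
    mutate(
      scale = if (library_norm) 1e6 / .data$total else 1,
      m_n = .data$m * .data$scale,
      p_n = .data$p * .data$scale
    ) |>
    tidyr::pivot_wider(
      id_cols = "gene_id", names_from = "cross",
      values_from = c("m_n", "p_n")
    )
  ratio <- function(num, den) {
    ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
  }
  calls_df |>
    select("gene_id", "call") |>
    inner_join(wide, by = "gene_id") |>
    mutate(
      # maternal A alleles are observed in AxB, the paternal A allele in BxA
      ratio_A = ifelse(
        .data$call == "MEG",
        ratio(.data$m_n_AxB, .data$p_n_BxA),
        ratio(.data$p_n_BxA, .data$m_n_AxB)
      ),
      ratio_B = ifelse(
        .data$call == "MEG",
        ratio(.data$m_n_BxA, .data$p_n_AxB),
        ratio(.data$p_n_AxB, .data$m_n_BxA)
      ),
      fold = ifelse(.data$call == "MEG", meg_fold, peg_fold),
      in_A = !is.na(.data$ratio_A) & .data$ratio_A >= .data$fold,
      in_B = !is.na(.data$ratio_B) & .data$ratio_B >= .data$fold,
      accession_class = case_when(
        !.data$call %in% c("MEG", "PEG") ~ "not_applicable",
        is.na(.data$ratio_A) & is.na(.data$ratio_B) ~ "not_applicable",
        .data$in_A & .data$in_B ~ "reciprocal",
        .data$in_A ~ "A_only",
        .data$in_B ~ "B_only",
        TRUE ~ "not_applicable"
      )
    ) |>
    select("gene_id", "call", "ratio_A", "ratio_B", "accession_class")
}

#' Parental splicing test across the SNPs of a gene
#'
#' If both parental alleles are spliced identically, the maternal:paternal
#' ratio should be homogeneous across the SNPs of a gene. Tests the 2-by-k
#' table (rows maternal/paternal, columns SNPs) with the Pearson chi-square
#' statistic and a Monte-Carlo p-value from tables drawn under fixed
#' margins, using the `(1 + #{T* >= T}) / (n_mc + 1)` estimator.
#'
#' @param snp_counts tibble `snp_id`, `m`, `p` (one gene), or a 2-by-k
#'   matrix with rows maternal/paternal.
#' @param n_mc number of Monte-Carlo tables (default 2000).
#' @param seed optional integer seed.
#' @return list with `statistic`, `p_value` (`NA` when fewer than 2 usable
#'   SNP columns), `df`, `n_mc`.
#' @export
splicing_chisq <- function(snp_counts, n_mc = 2000, seed = NULL) {
  tab <- if (is.matrix(snp_counts)) {
    snp_counts
  } else {
    rbind(m = snp_counts$m, p = snp_counts$p)
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) {
    return(list(
      statistic = NA_real_, p_value = NA_real_, df = NA_integer_,
      n_mc = n_mc
    ))
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) {
    # degenerate: one parent unobserved everywhere, no heterogeneity testable
    return(list(
      statistic = 0, p_value = 1, df = ncol(tab) - 1L, n_mc = n_mc
    ))
  }
  stat <- pearson_stat(tab)
  null_stats <- with_seed_if(seed, {
    vapply(r2dtable(n_mc, rs, cs), pearson_stat, numeric(1))
  })
  p <- (1 + sum(null_stats >= stat - 1e-9)) / (n_mc + 1)
  list(statistic = stat, p_value = p, df = ncol(tab) - 1L, n_mc = n_mc)
}

pearson_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
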