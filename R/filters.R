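#' Tissue-expression filters for candidate imprinted genes
#'
#' Maternally biased calls in whole-seed RNA are contaminated by the
#' maternal seed coat, long-lived gametophytic RNAs, and (for paternal
#' bias) the embryo. These filters use a genes-by-tissues signal-log-ratio
#' (SLR) matrix with a tissue sidecar (`tissue`, `compartment`, `stage`) to
#' separate genuinely endosperm-expressed candidates.
#'
#' `filter_endosperm_preferred()`: a gene passes when, at some seed stage,
#' its best endosperm-domain SLR is at least `fold_high` times the
#' seed-coat SLR of the same stage (or `fold_low` times when the gene's
#' total assigned read count lies in `low_count_range`), and all
#' vegetative SLRs are below `veg_max_slr`. A seed-coat SLR of zero or
#' less makes the ratio ill-defined; the clause then passes when the
#' endosperm SLR reaches `veg_max_slr`.
#'
#' @param slr long tibble `gene_id`, `tissue`, `slr`.
#' @param tissues tibble `tissue`, `compartment`, `stage`; endosperm
#'   compartments start with `"endosperm"`.
#' @param read_counts optional tibble `gene_id`, `reads` (total assigned
#'   reads) switching the `fold_low` branch.
#' @param fold_high,fold_low fold requirements (defaults 5 and 3).
#' @param low_count_range inclusive read-count range using `fold_low`
#'   (default `c(10, 30)`).
#' @param veg_max_slr vegetative SLR ceiling (default 5, strict).
#' @return tibble `gene_id`, `endosperm_clause`, `vegetative_clause`,
#'   `pass`, `reason` (failed clauses, `""` when passing).
#' @export
filter_endosperm_preferred <- function(slr, tissues, read_counts = NULL,
                                       fold_high = 5, fold_low = 3,
                                       low_count_range = c(10, 30),
                                       veg_max_slr = 5) {
  x <- join_tissues(slr, tissues)
  if (!any(x$compartment == "seed_coat")) {
    config_error("no seed_coat tissue in SLR matrix")
  }
  if (!any(startsWith(x$compartment, "endosperm"))) {
    config_error("no endosperm tissue in SLR matrix")
  }
  folds <- tibble(gene_id = unique(slr$gene_id), fold = fold_high)
  if (!is.null(read_counts)) {
    folds <- folds |>
      left_join(read_counts, by = "gene_id") |>
      mutate(fold = ifelse(
        !is.na(.data$reads) & .data$reads >= low_count_range[1] &
          .data$reads <= low_count_range[2],
        fold_low, fold_high
      )) |>
      select("gene_id", "fold")
  }
  by_stage <- x |>
    filter(
      startsWith(.data$compartment, "endosperm") |
        .data$compartment == "seed_coat",
      !is.na(.data$stage)
    ) |>
    group_by(.data$gene_id, .data$stage) |>
    summarise(
      endo = max(.data$slr[startsWith(.data$compartment, "endosperm")]),
      sc = max(.data$slr[.data$compartment == "seed_coat"]),
      .groups = "drop"
    ) |>
    left_join(folds, by = "gene_id") |>
    mutate(stage_pass = ifelse(
      .data$sc > 0,
      .data$endo >= .data$fold * .data$sc,
      .data$endo >= veg_max_slr
    )) |>
    group_by(.data$gene_id) |>
    summarise(endosperm_clause = any(.data$stage_pass), .groups = "drop")
  veg <- x |>
    filter(.data$compartment == "vegetative") |>
    group_by(.data$gene_id) |>
    summarise(
      vegetative_clause = all(.data$slr < veg_max_slr), .groups = "drop"
    )
  by_stage |>
    left_join(veg, by = "gene_id") |>
    mutate(
      vegetative_clause = tidyr::replace_na(.data$vegetative_clause, TRUE),
      pass = .data$endosperm_clause & .data$vegetative_clause,
      reason = paste0(
        ifelse(.data$endosperm_clause, "", "endosperm_ratio;"),
        ifelse(.data$vegetative_clause, "", "vegetative;")
      )
    )
}

#' @rdname filter_endosperm_preferred
#' @param slr_min strict lower SLR bound for endosperm expression
#'   (default 4.5).
#' @details `filter_endosperm_expressed()`: a gene counts as endosperm
#'   expressed when any endosperm-domain SLR exceeds `slr_min` (strictly).
#' @export
filter_endosperm_expressed <- function(slr, tissues, slr_min = 4.5) {
  x <- join_tissues(slr, tissues)
  endo <- x |> filter(startsWith(.data$compartment, "endosperm"))
  if (nrow(endo) == 0) config_error("no endosperm tissue in SLR matrix")
  endo |>
    group_by(.data$gene_id) |>
    summarise(pass = any(.data$slr > slr_min), .groups = "drop")
}

#' @rdname filter_endosperm_preferred
#' @param margin flag requires the embryo maximum to exceed the endosperm
#'   maximum by more than `margin` (default 0, strict).
#' @details `filter_embryo_predominant()`: genes whose expression peaks in
#'   the embryo mimic paternal bias (the embryo inherits alleles 1m:1p)
#'   and are flagged for exclusion from PEG candidates. Maxima are taken
#'   over the seed stages present for both compartments.
#' @export
filter_embryo_predominant <- function(slr, tissues, margin = 0) {
  x <- join_tissues(slr, tissues)
  if (!any(x$compartment == "embryo")) {
    config_error("no embryo tissue in SLR matrix")
  }
  stages <- intersect(
    unique(x$stage[x$compartment == "embryo"]),
    unique(x$stage[startsWith(x$compartment, "endosperm")])
  )
  x |>
    filter(
      .data$stage %in% stages,
      .data$compartment == "embryo" |
        startsWith(.data$compartment, "endosperm")
    ) |>
    group_by(.data$gene_id) |>
    summarise(
      flagged = max(.data$slr[.data$compartment == "embryo"]) >
        max(.data$slr[startsWith(.data$compartment, "endosperm")]) + margin,
      .groups = "drop"
    )
}

#' @rdname filter_endosperm_preferred
#' @details `flag_maternal_carryover()`: a maternal call could reflect
#'   long-lived RNA stored in the female gametophyte rather than endosperm
#'   transcription; such genes are expected to show lower expression in
#'   4 DAP seeds than in stage-12 flowers. The flag (seed SLR minus flower
#'   SLR below zero) is reported but does not remove genes.
#' @export
flag_maternal_carryover <- function(slr, tissues) {
  x <- join_tissues(slr, tissues)
  has_flower <- any(x$compartment == "flower_st12")
  has_seed <- any(x$compartment == "seed_whole")
  if (!has_flower || !has_seed) {
    warn("flower_st12 or whole-seed tissue missing; carryover flag skipped")
    return(tibble(
      gene_id = unique(slr$gene_id), flagged = NA, seed_minus_flower = NA_real_
    ))
  }
  x |>
    filter(.data$compartment %in% c("flower_st12", "seed_whole")) |>
    group_by(.data$gene_id) |>
    summarise(
      seed_minus_flower =
        max(.data$slr[.data$compartment == "seed_whole"]) -
        max(.data$slr[.data$compartment == "flower_st12"]),
      flagged = .data$seed_minus_flower < 0,
      .groups = "drop"
    ) |>
    select("gene_id", "flagged", "seed_minus_flower")
}

join_tissues <- function(slr, tissues) {
  missing <- setdiff(unique(slr$tissue), tissues$tissue)
  if (length(missing) > 0) {
    config_error(paste0(
      "tissue(s) without compartment metadata: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  left_join(slr, tissues, by = "tissue")
}

#' Assemble final MEG and PEG candidate lists
#'
#' Combines the statistical calls with the tissue filters: MEGs are
#' maternal calls that are endosperm preferred (the maternal-carryover
#' flag is reported but does not exclude); PEGs are paternal calls that
#' are endosperm expressed and not embryo predominant. Every gene carries
#' the ordered list of rules applied to it.
#'
#' @param calls an `imprint_calls` object or tibble with `gene_id`,
#'   `call`.
#' @param endosperm_preferred output of [filter_endosperm_preferred()].
#' @param endosperm_expressed output of [filter_endosperm_expressed()].
#' @param embryo_predominant output of [filter_embryo_predominant()].
#' @param maternal_carryover optional output of
#'   [flag_maternal_carryover()].
#' @return tibble `gene_id`, `call`, filter columns, `final`
#'   (`"MEG"`/`"PEG"`/`"none"`), `rules` (semicolon-separated trace).
#' @export
assemble_candidates <- function(calls, endosperm_preferred,
                                endosperm_expressed, embryo_predominant,
                                maternal_carryover = NULL) {
  calls_df <- if (inherits(calls, "imprint_calls")) calls$calls else calls
  d <- calls_df |>
    select("gene_id", "call") |>
    left_join(
      endosperm_preferred |>
        select("gene_id", endosperm_preferred = "pass"),
      by = "gene_id"
    ) |>
    left_join(
      endosperm_expressed |>
        select("gene_id", endosperm_expressed = "pass"),
      by = "gene_id"
    ) |>
    left_join(
      embryo_predominant |>
        select("gene_id", embryo_predominant = "flagged"),
      by = "gene_id"
    )
  d$maternal_carryover <- if (!is.null(maternal_carryover)) {
    maternal_carryover$flagged[
      match(d$gene_id, maternal_carryover$gene_id)
    ]
  } else {
    NA
  }
  d |>
    mutate(
      final = case_when(
        .data$call == "MEG" &
          tidyr::replace_na(.data$endosperm_preferred, FALSE) ~ "MEG",
        .data$call == "PEG" &
          tidyr::replace_na(.data$endosperm_expressed, FALSE) &
          !tidyr::replace_na(.data$embryo_predominant, FALSE) ~ "PEG",
        TRUE ~ "none"
      ),
      rules = case_when(
        .data$call == "MEG" ~ paste0(
          "maternal_call;",
          ifelse(
            tidyr::replace_na(.data$endosperm_preferred, FALSE),
            "endosperm_preferred_pass;", "endosperm_preferred_fail;"
          ),
          ifelse(
            tidyr::replace_na(.data$maternal_carryover, FALSE),
            "carryover_flagged", "carryover_clear"
          )
        ),
        .data$call == "PEG" ~ paste0(
          "paternal_call;",
          ifelse(
            tidyr::replace_na(.data$endosperm_expressed, FALSE),
            "endosperm_expressed_pass;", "endosperm_expressed_fail;"
          ),
          ifelse(
            tidyr::replace_na(.data$embryo_predominant, FALSE),
            "embryo_predominant_excluded", "embryo_clear"
          )
        ),
        TRUE ~ "no_call"
      )
    )
}
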