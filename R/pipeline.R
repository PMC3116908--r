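#' Run the full imprinting discovery pipeline
#'
#' Orchestrates windows -> gene association -> read assignment -> allele
#' counting -> statistical calling -> accession classification -> tissue
#' filtering (-> genome context when TEs are given, -> metagene profile
#' when a signal track is given) as one reproducible, seeded run. Every
#' stage logs one line with its record counts; all stage outputs are
#' written as TSV and summarised in a JSON manifest with MD5 checksums, so
#' rerunning an identical configuration reproduces identical files.
#'
#' @param config named list. Required paths: `genome`, `snps`, `genes`
#'   (GFF3), `reads_AxB`, `reads_BxA`, `slr`, `tissues`; optional paths:
#'   `tes`, `track`; `out_dir` (required), and optional parameters
#'   `seed` (default 1), `max_mismatches` (2), `window_flank` (35),
#'   `maternal_null` (2/3), `q_threshold` (0.05), `meg_fold` (5),
#'   `peg_fold` (3), `n_mc` (2000), `vicinity_bp` (2000), `window_w` (50),
#'   `n_perm` (1000), `alpha` (0.05). Unknown keys are rejected.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_imprinting_pipeline <- function(config) {
  known <- c(
    "genome", "snps", "genes", "reads_AxB", "reads_BxA", "slr", "tissues",
    "tes", "track", "out_dir", "seed", "max_mismatches", "window_flank",
    "maternal_null", "q_threshold", "meg_fold", "peg_fold", "n_mc",
    "vicinity_bp", "window_w", "n_perm", "alpha"
  )
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    config_error(paste0(
      "unknown configuration key(s): ", paste(unknown, collapse = ", ")
    ))
  }
  required <- c(
    "genome", "snps", "genes", "reads_AxB", "reads_BxA", "slr", "tissues",
    "out_dir"
  )
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    config_error(paste0(
      "missing configuration key(s): ", paste(missing, collapse = ", ")
    ))
  }
  prm <- function(key, default) config[[key]] %||% default
  seed <- as.integer(prm("seed", 1))
  paths <- config[intersect(names(config), c(
    "genome", "snps", "genes", "reads_AxB", "reads_BxA", "slr", "tissues",
    "tes", "track"
  ))]
  absent <- names(paths)[!file.exists(unlist(paths))]
  if (length(absent) > 0) {
    config_error(paste0(
      "input file(s) not found: ",
      paste(unlist(paths[absent]), collapse = ", ")
    ))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, fmt, ...) message(sprintf(
    "[%s] %s", name, sprintf(fmt, ...)
  ))

  genome <- read_genome(config$genome)
  snps <- read_snp_table(config$snps)
  ann <- read_gene_annotation(config$genes)
  stage("load", "%d chromosomes, %d SNPs, %d genes",
        length(genome), nrow(snps), nrow(ann$genes))

  windows <- build_snp_windows(genome, snps, prm("window_flank", 35L))
  windows <- assign_gene_to_windows(windows, ann$genes)
  stage(
    "windows", "%d windows (%d edge_truncated, %d multi_gene, %d intergenic)",
    nrow(windows),
    sum(windows$discarded == "edge_truncated", na.rm = TRUE),
    sum(windows$discarded == "multi_gene", na.rm = TRUE),
    sum(is.na(windows$discarded) & is.na(windows$gene_id))
  )

  counts <- list()
  snp_counts <- list()
  for (cross in c("AxB", "BxA")) {
    reads <- read_reads_fastq(config[[paste0("reads_", cross)]], cross)
    asn <- assign_reads(reads, windows, prm("max_mismatches", 2L))
    stage(
      paste0("assign_", cross),
      "%d reads: %d assigned, %d allele_ambiguous, %d locus_ambiguous, %d unmatched",
      nrow(asn), sum(asn$status == "assigned"),
      sum(asn$status == "allele_ambiguous"),
      sum(asn$status == "locus_ambiguous"),
      sum(asn$status == "too_many_mismatches")
    )
    counts[[cross]] <- count_alleles(asn, cross, ann$genes)
    snp_counts[[cross]] <- count_alleles_by_snp(asn, cross)
  }
  counts <- bind_rows(counts)
  snp_counts <- bind_rows(snp_counts)

  calls <- call_imprinting(
    counts, prm("maternal_null", 2 / 3), prm("q_threshold", 0.05)
  )
  stage("test", "%d genes tested, %d MEG, %d PEG",
        calls$n_tested, sum(calls$calls$call == "MEG"),
        sum(calls$calls$call == "PEG"))

  accession <- classify_accession_dependence(
    counts, calls, prm("meg_fold", 5), prm("peg_fold", 3)
  )

  called <- calls$calls$gene_id[calls$calls$call %in% c("MEG", "PEG")]
  splicing <- purrr::map_dfr(called, function(g) {
    sc <- snp_counts |>
      filter(.data$gene_id == g) |>
      group_by(.data$snp_id) |>
      summarise(m = sum(.data$m), p = sum(.data$p), .groups = "drop")
    res <- splicing_chisq(sc, prm("n_mc", 2000), seed = seed + 7L)
    tibble(gene_id = g, splicing_p = res$p_value)
  })

  slr_in <- read_slr_matrix(config$slr, config$tissues)
  gene_reads <- counts |>
    group_by(.data$gene_id) |>
    summarise(reads = sum(.data$m + .data$p), .groups = "drop")
  ep <- filter_endosperm_preferred(slr_in$slr, slr_in$tissues, gene_reads)
  ee <- filter_endosperm_expressed(slr_in$slr, slr_in$tissues)
  emb <- filter_embryo_predominant(slr_in$slr, slr_in$tissues)
  carry <- flag_maternal_carryover(slr_in$slr, slr_in$tissues)
  candidates <- assemble_candidates(calls, ep, ee, emb, carry)
  stage("filter", "%d final MEG, %d final PEG",
        sum(candidates$final == "MEG"), sum(candidates$final == "PEG"))

  context <- NULL
  if (!is.null(config$tes)) {
    tes <- read_te_table(config$tes)
    vic <- te_vicinity(ann$genes, tes, prm("vicinity_bp", 2000L))
    detectable <- gene_reads$gene_id[gene_reads$reads > 0]
    final_set <- candidates$gene_id[candidates$final != "none"]
    te_enrich <- if (length(final_set) > 0 && length(detectable) > 0) {
      enrichment_test(
        sum(final_set %in% vic$gene_id[vic$has_te]),
        length(final_set),
        sum(detectable %in% vic$gene_id[vic$has_te]),
        length(detectable),
        n_perm = prm("n_perm", 1000), seed = seed + 11L
      )
    } else {
      NULL
    }
    order_tbl <- ann$genes |>
      arrange(.data$chrom, .data$start) |>
      select("gene_id", "chrom")
    scan <- if (length(final_set) > 0 &&
                nrow(order_tbl) >= prm("window_w", 50L)) {
      scan_clusters(
        order_tbl, final_set, prm("window_w", 50L),
        prm("n_perm", 1000), prm("alpha", 0.05), seed = seed + 13L
      )
    } else {
      NULL
    }
    context <- list(vicinity = vic, te_enrichment = te_enrich, scan = scan)
    stage("context", "%d genes with TE in vicinity; %d cluster(s)",
          sum(vic$has_te), if (is.null(scan)) 0L else nrow(scan$clusters))
  }

  profile <- NULL
  if (!is.null(config$track)) {
    track <- read_signal_track(config$track)
    profile <- group_profile(track, ann$genes)
    stage("profile", "60-bin profile over %d genes",
          max(profile$n))
  }

  outputs <- list(
    windows = windows |> select(-"seq"),
    counts = counts,
    snp_counts = snp_counts,
    calls = tidy(calls) |>
      left_join(accession |> select("gene_id", "ratio_A", "ratio_B",
                                    "accession_class"), by = "gene_id") |>
      left_join(splicing, by = "gene_id"),
    candidates = candidates
  )
  written <- character()
  for (nm in names(outputs)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(outputs[[nm]], f)
    written[nm] <- f
  }
  if (!is.null(context)) {
    f <- file.path(out_dir, "te_vicinity.tsv")
    readr::write_tsv(
      context$vicinity |>
        mutate(superfamilies = vapply(
          .data$superfamilies, paste, character(1), collapse = ","
        )),
      f
    )
    written["te_vicinity"] <- f
    if (!is.null(context$scan) && nrow(context$scan$clusters) > 0) {
      f <- file.path(out_dir, "clusters.tsv")
      readr::write_tsv(
        context$scan$clusters |>
          mutate(members = vapply(
            .data$members, paste, character(1), collapse = ","
          )),
        f
      )
      written["clusters"] <- f
    }
  }
  if (!is.null(profile)) {
    f <- file.path(out_dir, "profile.tsv")
    readr::write_tsv(as_tibble(profile), f)
    written["profile"] <- f
  }
  manifest <- list(
    config = config,
    outputs = as.list(tools::md5sum(unname(written)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(list(
    windows = windows, counts = counts, calls = calls,
    accession = accession, candidates = candidates, context = context,
    profile = profile, manifest = manifest_path
  ))
}
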