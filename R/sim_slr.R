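#' Simulate a tissue signal-log-ratio (SLR) expression matrix
#'
#' Emulates per-gene microarray SLR values across vegetative tissues,
#' flowers, and seed compartments (embryo, micropylar/peripheral/chalazal
#' endosperm, seed coat) at three seed stages, plus a whole-seed 4 DAP
#' sample. Truth imprinted genes are given expression patterns that satisfy
#' the tissue filters they must pass (endosperm-preferred for MEGs,
#' endosperm-expressed and not embryo-predominant for PEGs), while a
#' configurable fraction of unbiased "decoy" genes each violate exactly one
#' filter clause (vegetative expression, endosperm/seed-coat ratio,
#' embryo predominance, maternal carryover).
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param config the same [sim_config()].
#' @return list with `slr` (tibble `gene_id`, `tissue`, `slr`), `tissues`
#'   (tibble `tissue`, `compartment`, `stage`), and `flags` — the filter
#'   outcomes guaranteed by construction (`NA` where the construction does
#'   not pin the outcome).
#' @export
simulate_slr_matrix <- function(sim, config = sim$config) {
  tissues <- slr_tissue_table()
  truth <- sim$truth
  with_seed_if(config$rng_seed + 2L, {
    roles <- slr_roles(truth, config)
    vals <- lapply(seq_len(nrow(truth)), function(i) {
      slr_gene_values(truth$gene_id[i], roles[i], tissues)
    })
    flags <- slr_expected_flags(truth$gene_id, roles)
    list(
      slr = bind_rows(vals),
      tissues = tissues,
      flags = flags,
      roles = tibble(gene_id = truth$gene_id, slr_role = roles)
    )
  })
}

slr_tissue_table <- function() {
  stages <- c("preglobular", "globular", "heart")
  veg <- c("seedling", "cotyledon", "hypocotyl", "leaf", "stem", "root", "SAM")
  bind_rows(
    tibble(tissue = veg, compartment = "vegetative", stage = NA_character_),
    tibble(
      tissue = c("flower_st10", "flower_st12", "flower_st15"),
      compartment = c("flower", "flower_st12", "flower"),
      stage = NA_character_
    ),
    tibble(
      tissue = paste0("embryo_", stages),
      compartment = "embryo", stage = stages
    ),
    tibble(
      tissue = paste0("MPE_", stages),
      compartment = "endosperm_MPE", stage = stages
    ),
    tibble(
      tissue = paste0("PE_", stages),
      compartment = "endosperm_PE", stage = stages
    ),
    tibble(
      tissue = paste0("CZE_", stages),
      compartment = "endosperm_CZE", stage = stages
    ),
    tibble(
      tissue = paste0("seed_coat_", stages),
      compartment = "seed_coat", stage = stages
    ),
    tibble(
      tissue = "seed_4DAP", compartment = "seed_whole", stage = NA_character_
    )
  )
}

slr_roles <- function(truth, config) {
  roles <- rep("background", nrow(truth))
  roles[truth$true_class %in% c("MEG", "MEG_accession_A_only")] <- "imprinted_meg"
  roles[truth$true_class %in% c("PEG", "PEG_accession_A_only")] <- "imprinted_peg"
  nulls <- which(roles == "background")
  n_dec <- round(config$frac_decoy * length(nulls))
  if (n_dec > 0) {
    dec <- sample(nulls, n_dec)
    roles[dec] <- rep_len(
      c("decoy_veg", "decoy_ratio", "decoy_embryo", "decoy_carryover"), n_dec
    )
  }
  roles
}

# value ranges are kept strictly away from the filter boundaries (5x, 3x,
# 4.5, veg < 5) so the intended pass/fail outcome is deterministic
slr_gene_values <- function(gene_id, role, tissues) {
  v <- setNames(runif(nrow(tissues), 0.5, 4.2), tissues$tissue)
  endo <- tissues$tissue[startsWith(tissues$compartment, "endosperm")]
  sc <- tissues$tissue[tissues$compartment == "seed_coat"]
  emb <- tissues$tissue[tissues$compartment == "embryo"]
  meg_like <- function() {
    v[endo] <<- runif(length(endo), 4.6, 6)
    v[sample(endo, 1)] <<- runif(1, 8, 11)
    v[sc] <<- runif(length(sc), 0.8, 1.4)
    v[emb] <<- runif(length(emb), 0.5, 3)
  }
  v["seed_4DAP"] <- v[["flower_st12"]] + runif(1, 0.5, 2)
  switch(role,
    background = {
      v[endo] <- runif(length(endo), 0.5, 4.2)
      v[sc] <- runif(length(sc), 2, 3.5)
    },
    imprinted_meg = meg_like(),
    imprinted_peg = {
      v[endo] <- runif(length(endo), 6, 9)
      v[sc] <- runif(length(sc), 2.5, 3.5)
      v[emb] <- runif(length(emb), 0.5, 3.5)
    },
    decoy_veg = {
      meg_like()
      veg <- tissues$tissue[tissues$compartment == "vegetative"]
      v[sample(veg, 1)] <- runif(1, 5.5, 7)
    },
    decoy_ratio = {
      v[endo] <- runif(length(endo), 7, 8.4)
      v[sc] <- runif(length(sc), 2.9, 3.2)
      v[emb] <- runif(length(emb), 0.5, 3.5)
    },
    decoy_embryo = {
      v[endo] <- runif(length(endo), 4.6, 5.5)
      v[sc] <- runif(length(sc), 2.5, 3.5)
      v[emb] <- runif(length(emb), 8, 10)
    },
    decoy_carryover = {
      meg_like()
      v["seed_4DAP"] <- v[["flower_st12"]] - runif(1, 0.5, 2)
    }
  )
  tibble(gene_id = gene_id, tissue = names(v), slr = unname(v))
}

slr_expected_flags <- function(gene_id, roles) {
  tab <- list(
    background      = c(FALSE, FALSE, NA, FALSE),
    imprinted_meg   = c(TRUE, TRUE, FALSE, FALSE),
    imprinted_peg   = c(NA, TRUE, FALSE, FALSE),
    decoy_veg       = c(FALSE, TRUE, FALSE, FALSE),
    decoy_ratio     = c(FALSE, TRUE, FALSE, FALSE),
    decoy_embryo    = c(FALSE, TRUE, TRUE, FALSE),
    decoy_carryover = c(TRUE, TRUE, FALSE, TRUE)
  )
  m <- unname(do.call(rbind, tab[roles]))
  tibble(
    gene_id = gene_id,
    endosperm_preferred = m[, 1],
    endosperm_expressed = m[, 2],
    embryo_predominant = m[, 3],
    maternal_carryover = m[, 4]
  )
}

#' Simulate a complete input bundle
#'
#' Runs [simulate_genome()], [simulate_reads()], and
#' [simulate_slr_matrix()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `imprint_bundle` with `genome`, `genes`, `exons`,
#'   `snps`, `tes`, `truth` (with SLR filter flags merged in), `reads`,
#'   `slr`, `tissues`, and `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  reads <- simulate_reads(sim, config)
  slr <- simulate_slr_matrix(sim, config)
  truth <- sim$truth |>
    left_join(slr$roles, by = "gene_id") |>
    left_join(slr$flags, by = "gene_id")
  structure(
    list(
      genome = sim$genome, genes = sim$genes, exons = sim$exons,
      snps = sim$snps, tes = sim$tes, truth = truth,
      reads = reads, slr = slr$slr, tissues = slr$tissues,
      config = config
    ),
    class = "imprint_bundle"
  )
}
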