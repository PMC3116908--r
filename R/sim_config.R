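#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic-data
#' generator. The defaults describe the study conditions the pipeline is
#' designed for: a triploid endosperm with an unbiased 2m:1p allelic ratio
#' (maternal fraction 2/3), 36-nt single-end reads, and roughly 7 exonic
#' SNPs per gene between the two accessions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome in bp.
#' @param n_genes total number of genes across chromosomes.
#' @param snps_per_gene_mean Poisson mean of exonic SNPs per gene (minimum 1
#'   is enforced).
#' @param read_length read length in nt; must not exceed the 71-nt SNP
#'   window.
#' @param reads_per_cross total number of reads emitted per reciprocal
#'   cross library.
#' @param error_rate per-base substitution probability in `[0,1]`.
#' @param frac_meg,frac_peg fraction of genes that are reciprocally
#'   imprinted MEGs / PEGs.
#' @param frac_accession_dependent fraction of genes imprinted in accession
#'   A only (split evenly between maternally and paternally expressed).
#' @param maternal_fraction_null maternal read fraction of unbiased genes
#'   (2/3 for triploid endosperm).
#' @param maternal_fraction_meg,maternal_fraction_peg maternal read
#'   fraction of reciprocal MEGs / PEGs in both crosses.
#' @param maternal_fraction_acc_meg maternal fraction of accession-A-only
#'   MEGs in the cross where the A allele is inherited paternally (B x A);
#'   the other cross sits at the null.
#' @param maternal_fraction_acc_peg maternal fraction of accession-A-only
#'   PEGs in the cross where the A alleles are inherited maternally
#'   (A x B); the other cross sits at the null.
#' @param te_density expected number of transposable elements placed in
#'   each gene's 2-kb neighbourhood (Poisson).
#' @param frac_decoy fraction of unbiased genes given expression patterns
#'   that each violate exactly one tissue filter clause.
#' @param rng_seed integer seed; every random choice of the generator is a
#'   function of it.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chromosome_length = 200000L,
                       n_genes = 40L,
                       snps_per_gene_mean = 7,
                       read_length = 36L,
                       reads_per_cross = 12000L,
                       error_rate = 0.002,
                       frac_meg = 0.1,
                       frac_peg = 0.1,
                       frac_accession_dependent = 0,
                       maternal_fraction_null = 2 / 3,
                       maternal_fraction_meg = 0.98,
                       maternal_fraction_peg = 0.2,
                       maternal_fraction_acc_meg = 0.98,
                       maternal_fraction_acc_peg = 0.05,
                       te_density = 0.5,
                       frac_decoy = 0.15,
                       rng_seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    snps_per_gene_mean = snps_per_gene_mean,
    read_length = as.integer(read_length),
    reads_per_cross = as.integer(reads_per_cross),
    error_rate = error_rate,
    frac_meg = frac_meg,
    frac_peg = frac_peg,
    frac_accession_dependent = frac_accession_dependent,
    maternal_fraction_null = maternal_fraction_null,
    maternal_fraction_meg = maternal_fraction_meg,
    maternal_fraction_peg = maternal_fraction_peg,
    maternal_fraction_acc_meg = maternal_fraction_acc_meg,
    maternal_fraction_acc_peg = maternal_fraction_acc_peg,
    te_density = te_density,
    frac_decoy = frac_decoy,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(
    error_rate = cfg$error_rate,
    frac_meg = cfg$frac_meg,
    frac_peg = cfg$frac_peg,
    frac_accession_dependent = cfg$frac_accession_dependent,
    maternal_fraction_null = cfg$maternal_fraction_null,
    maternal_fraction_meg = cfg$maternal_fraction_meg,
    maternal_fraction_peg = cfg$maternal_fraction_peg,
    maternal_fraction_acc_meg = cfg$maternal_fraction_acc_meg,
    maternal_fraction_acc_peg = cfg$maternal_fraction_acc_peg,
    frac_decoy = cfg$frac_decoy
  )
  check_fractions(fr, names(fr))
  if (cfg$frac_meg + cfg$frac_peg + cfg$frac_accession_dependent > 1) {
    config_error("frac_meg + frac_peg + frac_accession_dependent exceeds 1")
  }
  if (cfg$read_length > 71L) {
    config_error("read_length must not exceed the 71-nt SNP window")
  }
  if (cfg$read_length < 1L || cfg$n_genes < 1L || cfg$n_chromosomes < 1L ||
      cfg$reads_per_cross < 0L) {
    config_error("counts must be positive")
  }
  if (cfg$snps_per_gene_mean < 0 || cfg$te_density < 0) {
    config_error("rates must be non-negative")
  }
  invisible(cfg)
}
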