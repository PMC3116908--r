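#' Simulate a genome with genes, exonic SNPs, TEs, and imprinting truth
#'
#' Generates random chromosome sequences, non-overlapping gene models with
#' exon/intron structure, biallelic SNPs restricted to exons (so that
#' transcript reads are informative), transposable elements scattered in
#' gene neighbourhoods, and a ground-truth table assigning each gene an
#' imprinting class with its per-cross maternal read fraction.
#'
#' Cross naming: accession A is the reference; cross `AxB` has A as mother,
#' cross `BxA` has B as mother. Accession-A-only imprinted genes are biased
#' only in the cross where the silenced A-origin allele applies: `BxA` for
#' maternally expressed genes (paternal A allele silenced), `AxB` for
#' paternally expressed genes (maternal A alleles silenced).
#'
#' @param config a [sim_config()].
#' @return a list of class `genome_sim` with elements `genome` (named
#'   character vector of chromosome sequences), `genes`, `exons`, `snps`,
#'   `tes`, and `truth` tibbles. Gene/exon/TE intervals are 0-based
#'   half-open; SNP positions are 1-based.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed_if(config$rng_seed, {
    genome <- sim_chromosomes(config)
    ann <- sim_gene_models(config)
    truth <- sim_truth_classes(ann$genes, config)
    snps <- sim_snps(genome, ann$exons, truth, config)
    tes <- sim_tes(ann$genes, config)
    truth$snp_pos <- lapply(truth$gene_id, function(g) {
      snps$pos[snps$gene_id == g]
    })
    structure(
      list(
        genome = genome, genes = ann$genes, exons = ann$exons,
        snps = snps, tes = tes, truth = truth, config = config
      ),
      class = "genome_sim"
    )
  })
}

sim_chromosomes <- function(config) {
  chroms <- paste0("Chr", seq_len(config$n_chromosomes))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chromosome_length,
                 replace = TRUE), collapse = "")
  }, character(1))
  setNames(seqs, chroms)
}

sim_gene_models <- function(config) {
  chroms <- paste0("Chr", seq_len(config$n_chromosomes))
  per_chr <- diff(round(seq(0, config$n_genes,
                            length.out = config$n_chromosomes + 1)))
  genes <- list()
  exons <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- 0L
    for (k in seq_len(per_chr[ci])) {
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      len <- as.integer(pmin(pmax(round(rnorm(1, 1500, 300)), 600), 3000))
      gap <- as.integer(round(rexp(1, 1 / 1200)) + 400L)
      start <- cursor + gap
      end <- start + len
      if (end > config$chromosome_length) {
        config_error(sprintf(
          "impossible geometry: gene %s does not fit on %s (need %d bp)",
          gid, chroms[ci], end
        ))
      }
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- tibble(
        gene_id = gid, chrom = chroms[ci],
        start = start, end = end, strand = strand
      )
      exons[[gi]] <- sim_exons(gid, chroms[ci], start, end)
      cursor <- end
    }
  }
  list(genes = bind_rows(genes), exons = bind_rows(exons))
}

# cut [start, end) into 1-3 exons separated by short introns; exons keep a
# minimum length so transcripts always exceed the read length
sim_exons <- function(gene_id, chrom, start, end) {
  len <- end - start
  n_ex <- sample(1:3, 1)
  introns <- if (n_ex > 1) sample(80:200, n_ex - 1, replace = TRUE) else integer()
  while (n_ex > 1 && len - sum(introns) < 150L * n_ex) {
    n_ex <- n_ex - 1L
    introns <- introns[seq_len(max(n_ex - 1L, 0L))]
  }
  exonic <- len - sum(introns)
  # random composition of exonic length into n_ex parts, each >= 150
  extra <- exonic - 150L * n_ex
  cuts <- if (n_ex > 1) sort(sample(0:extra, n_ex - 1, replace = TRUE)) else integer()
  parts <- diff(c(0L, cuts, extra)) + 150L
  s <- start
  out <- vector("list", n_ex)
  for (i in seq_len(n_ex)) {
    out[[i]] <- tibble(
      gene_id = gene_id, chrom = chrom,
      start = s, end = s + parts[i], exon = i
    )
    s <- s + parts[i] + if (i < n_ex) introns[i] else 0L
  }
  bind_rows(out)
}

sim_truth_classes <- function(genes, config) {
  n <- nrow(genes)
  n_meg <- round(config$frac_meg * n)
  n_peg <- round(config$frac_peg * n)
  n_acc <- round(config$frac_accession_dependent * n)
  n_acc_meg <- ceiling(n_acc / 2)
  n_acc_peg <- n_acc - n_acc_meg
  cls <- rep("null", n)
  idx <- sample.int(n, n_meg + n_peg + n_acc)
  cls[idx] <- rep(
    c("MEG", "PEG", "MEG_accession_A_only", "PEG_accession_A_only"),
    times = c(n_meg, n_peg, n_acc_meg, n_acc_peg)
  )
  f0 <- config$maternal_fraction_null
  mf <- cbind(
    AxB = rep(f0, n),
    BxA = rep(f0, n)
  )
  mf[cls == "MEG", ] <- config$maternal_fraction_meg
  mf[cls == "PEG", ] <- config$maternal_fraction_peg
  # A-only MEG: A allele silenced when paternal, i.e. in cross B x A
  mf[cls == "MEG_accession_A_only", "BxA"] <- config$maternal_fraction_acc_meg
  # A-only PEG: A alleles silenced when maternal, i.e. in cross A x B
  mf[cls == "PEG_accession_A_only", "AxB"] <- config$maternal_fraction_acc_peg
  tibble(
    gene_id = genes$gene_id,
    true_class = cls,
    maternal_fraction_AxB = mf[, "AxB"],
    maternal_fraction_BxA = mf[, "BxA"]
  )
}

sim_snps <- function(genome, exons, truth, config) {
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    ex <- exons[exons$gene_id == g, ]
    positions <- unlist(Map(function(s, e) seq.int(s, e - 1L), ex$start, ex$end))
    k <- max(1L, rpois(1, config$snps_per_gene_mean))
    k <- min(k, length(positions))
    pos0 <- sort(sample(positions, k))
    chrom <- ex$chrom[1]
    refs <- strsplit(substring(
      genome[[chrom]], pos0[1] + 1L, pos0[length(pos0)] + 1L
    ), "")[[1]][pos0 - pos0[1] + 1L]
    alts <- vapply(refs, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    out[[i]] <- tibble(
      chrom = chrom, pos = pos0 + 1L,
      ref = unname(refs), alt = unname(alts), gene_id = g
    )
  }
  snps <- bind_rows(out)
  snps <- snps[order(snps$chrom, snps$pos), ]
  snps$snp_id <- sprintf("S%05d", seq_len(nrow(snps)))
  snps[, c("snp_id", "chrom", "pos", "ref", "alt", "gene_id")]
}

sim_tes <- function(genes, config) {
  fams <- c("RC/Helitron", "MuDR", "DNA", "LTR/Gypsy", "LTR/Copia", "LINE/L1")
  out <- list()
  ti <- 0L
  for (i in seq_len(nrow(genes))) {
    n_te <- rpois(1, config$te_density)
    for (k in seq_len(n_te)) {
      ti <- ti + 1L
      w <- sample(150:600, 1)
      lo <- max(genes$start[i] - 2000L, 0L)
      hi <- genes$end[i] + 2000L - w
      s <- sample(lo:hi, 1)
      out[[ti]] <- tibble(
        te_id = sprintf("TE%04d", ti), chrom = genes$chrom[i],
        start = s, end = s + w, superfamily = sample(fams, 1)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      te_id = character(), chrom = character(),
      start = integer(), end = integer(), superfamily = character()
    ))
  }
  bind_rows(out)
}

#' Simulate reciprocal-cross RNA-seq reads
#'
#' Draws fixed-length unstranded single-end reads from unspliced transcript
#' sequences (exon concatenations) of either the maternal or the paternal
#' haplotype, according to each gene's true maternal fraction for the given
#' cross. Haplotype B is the reference with all alternate SNP alleles
#' substituted. Sequencing errors are independent per-base substitutions.
#' Read ids encode the ground truth (`g`=gene, `o`=origin maternal/paternal,
#' `a`=accession allele, `s`=transcript start, `st`=orientation) and can be
#' decoded with [parse_read_truth()].
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param config the same [sim_config()]; read simulation consumes a seed
#'   derived from `rng_seed` so genome and reads are independently
#'   reproducible.
#' @return a tibble with columns `read_id`, `seq`, `cross`
#'   (`"AxB"`/`"BxA"`); `reads_per_cross` rows per cross.
#' @export
simulate_reads <- function(sim, config = sim$config) {
  validate_sim_config(config)
  genome_b <- hapB_genome(sim$genome, sim$snps)
  tx <- transcript_pair(sim, genome_b)
  with_seed_if(config$rng_seed + 1L, {
    out <- lapply(c("AxB", "BxA"), function(cross) {
      mf <- if (cross == "AxB") sim$truth$maternal_fraction_AxB else
        sim$truth$maternal_fraction_BxA
      names(mf) <- sim$truth$gene_id
      alloc <- as.vector(stats::rmultinom(
        1, config$reads_per_cross,
        rep(1 / nrow(sim$truth), nrow(sim$truth))
      ))
      reads <- vector("list", nrow(sim$truth))
      for (i in seq_len(nrow(sim$truth))) {
        n <- alloc[i]
        if (n == 0) next
        g <- sim$truth$gene_id[i]
        maternal <- rbinom(n, 1, mf[[g]]) == 1
        # maternal accession is A in AxB, B in BxA
        acc <- ifelse(maternal == (cross == "AxB"), "A", "B")
        reads[[i]] <- draw_gene_reads(g, cross, acc, maternal, tx, config)
      }
      bind_rows(reads)
    })
    bind_rows(out)
  })
}

draw_gene_reads <- function(gene_id, cross, acc, maternal, tx, config) {
  rl <- config$read_length
  seqs <- character(length(acc))
  starts <- integer(length(acc))
  for (a in c("A", "B")) {
    sel <- acc == a
    if (!any(sel)) next
    t_seq <- tx[[a]][[gene_id]]
    L <- nchar(t_seq)
    s <- sample.int(L - rl + 1L, sum(sel), replace = TRUE)
    starts[sel] <- s
    seqs[sel] <- substring(t_seq, s, s + rl - 1L)
  }
  fwd <- rbinom(length(seqs), 1, 0.5) == 1
  seqs[!fwd] <- revcomp(seqs[!fwd])
  seqs <- apply_read_errors(seqs, config$error_rate)
  tibble(
    read_id = sprintf(
      "r%s_%s_%04d|g=%s|o=%s|a=%s|s=%d|st=%s",
      cross, gene_id, seq_along(seqs), gene_id,
      ifelse(maternal, "mat", "pat"), acc, starts,
      ifelse(fwd, "+", "-")
    ),
    seq = seqs,
    cross = cross
  )
}

apply_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  rl <- nchar(seqs[1])
  m <- matrix(runif(length(seqs) * rl) < error_rate, nrow = length(seqs))
  hit <- which(m, arr.ind = TRUE)
  if (nrow(hit) == 0) return(seqs)
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    old <- substring(seqs[i], j, j)
    substring(seqs[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  seqs
}

hapB_genome <- function(genome, snps) {
  out <- genome
  for (ch in names(out)) {
    s <- snps[snps$chrom == ch, ]
    if (nrow(s) == 0) next
    chars <- strsplit(out[[ch]], "")[[1]]
    chars[s$pos] <- s$alt
    out[[ch]] <- paste(chars, collapse = "")
  }
  out
}

# unspliced transcripts (exon concatenation, strand-aware) per haplotype
transcript_pair <- function(sim, genome_b) {
  build <- function(genome) {
    tx <- vector("list", nrow(sim$genes))
    names(tx) <- sim$genes$gene_id
    for (i in seq_len(nrow(sim$genes))) {
      g <- sim$genes$gene_id[i]
      ex <- sim$exons[sim$exons$gene_id == g, ]
      ex <- ex[order(ex$start), ]
      parts <- substring(genome[[sim$genes$chrom[i]]], ex$start + 1L, ex$end)
      s <- paste(parts, collapse = "")
      if (sim$genes$strand[i] == "-") s <- revcomp(s)
      tx[[g]] <- s
    }
    tx
  }
  list(A = build(sim$genome), B = build(genome_b))
}

#' Decode ground truth from simulated read ids
#'
#' @param read_id character vector of read ids produced by
#'   [simulate_reads()].
#' @return tibble with `read_id`, `gene_id`, `origin`
#'   (`"mat"`/`"pat"`), `accession` (`"A"`/`"B"`), `tx_start`, `orientation`.
#' @export
parse_read_truth <- function(read_id) {
  field <- function(key) {
    stringr::str_match(read_id, paste0("\\|", key, "=([^|]+)"))[, 2]
  }
  tibble(
    read_id = read_id,
    gene_id = field("g"),
    origin = field("o"),
    accession = field("a"),
    tx_start = as.integer(field("s")),
    orientation = field("st")
  )
}

#' Simulate per-gene allele count tables directly
#'
#' Bypasses read simulation: per gene and cross, the total read count is
#' Poisson around `mean_reads` (floored at `min_reads`) and the maternal
#' count is binomial with the gene's true maternal fraction. This is the
#' input contract of [call_imprinting()] and is used for large calibration
#' and recovery runs.
#'
#' @param truth truth tibble from [simulate_genome()] (or any tibble with
#'   `gene_id`, `maternal_fraction_AxB`, `maternal_fraction_BxA`).
#' @param mean_reads Poisson mean of reads per gene per cross.
#' @param min_reads lower floor of reads per gene.
#' @param seed optional integer seed.
#' @return tibble `gene_id`, `cross`, `m`, `p`.
#' @export
simulate_allele_counts <- function(truth, mean_reads = 50, min_reads = 1L,
                                   seed = NULL) {
  with_seed_if(seed, {
    out <- lapply(c("AxB", "BxA"), function(cross) {
      mf <- if (cross == "AxB") truth$maternal_fraction_AxB else
        truth$maternal_fraction_BxA
      n <- pmax(rpois(nrow(truth), mean_reads), min_reads)
      m <- rbinom(nrow(truth), n, mf)
      tibble(gene_id = truth$gene_id, cross = cross, m = m, p = n - m)
    })
    bind_rows(out)
  })
}
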