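# small window set shared by the matcher tests: 3 SNPs in one gene, one
# intergenic SNP, built on a synthetic chromosome
make_window_fixture <- function(seed = 51) {
  set.seed(seed)
  chrom <- rand_dna(900)
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "c1", start = 50L, end = 500L, strand = "+"
  )
  pos <- c(120L, 250L, 400L, 700L)
  ref <- substring(chrom, pos, pos)
  snps <- tibble::tibble(
    snp_id = paste0("S", seq_along(pos)), chrom = "c1", pos = pos,
    ref = ref,
    alt = vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  )
  w <- assign_gene_to_windows(build_snp_windows(c(c1 = chrom), snps), genes)
  list(chrom = chrom, genes = genes, snps = snps, windows = w)
}

test_that("exact and near matches assign; three mismatches do not", {
  fx <- make_window_fixture()
  wa <- fx$windows[fx$windows$snp_id == "S1" & fx$windows$allele == "A", ]
  read0 <- substring(wa$seq, 20, 55)   # covers the centre (offset 36)
  set.seed(52)
  reads <- tibble::tibble(
    read_id = c("exact", "two_mm", "three_mm"),
    seq = c(read0, mutate_seq(read0, c(2, 30)),
            mutate_seq(read0, c(2, 18, 30)))
  )
  a <- assign_reads(reads, fx$windows)
  expect_equal(a$status[1], "assigned")
  expect_equal(a$allele[1], "A")
  expect_equal(a$gene_id[1], "g1")
  expect_equal(a$mismatches[1], 0L)
  # the centre mismatch of the B window contributes 1, so 'exact' is
  # unambiguous; 2 extra substitutions still assign, 3 do not
  expect_equal(a$status[2], "assigned")
  expect_equal(a$mismatches[2], 2L)
  expect_equal(a$status[3], "too_many_mismatches")
})

test_that("reads not covering the SNP centre are allele ambiguous", {
  fx <- make_window_fixture()
  wa <- fx$windows[fx$windows$snp_id == "S2" & fx$windows$allele == "A", ]
  flank_read <- substring(wa$seq, 1, 20)   # ends before the centre
  a <- assign_reads(
    tibble::tibble(read_id = "flank", seq = flank_read), fx$windows
  )
  expect_equal(a$status, "allele_ambiguous")
  expect_true(is.na(a$gene_id))
})

test_that("every read gets exactly one status (partition invariant)", {
  fx <- make_window_fixture()
  set.seed(53)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:60),
    seq = vapply(1:60, function(i) {
      if (i <= 30) {
        w <- fx$windows$seq[sample.int(nrow(fx$windows), 1)]
        s <- sample.int(36, 1)
        mutate_seq(substring(w, s, s + 35), sample.int(36, sample(0:3, 1)))
      } else {
        rand_dna(36)
      }
    }, character(1))
  )
  a <- assign_reads(reads, fx$windows)
  expect_equal(nrow(a), 60L)
  expect_true(all(a$status %in% c(
    "assigned", "allele_ambiguous", "locus_ambiguous", "too_many_mismatches"
  )))
  expect_equal(anyDuplicated(a$read_id), 0L)
})

test_that("reverse-complementing every read leaves the count table unchanged", {
  fx <- make_window_fixture()
  set.seed(54)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:40),
    seq = vapply(1:40, function(i) {
      w <- fx$windows$seq[sample.int(nrow(fx$windows), 1)]
      s <- sample.int(36, 1)
      mutate_seq(substring(w, s, s + 35), sample.int(36, sample(0:2, 1)))
    }, character(1))
  )
  a_fwd <- assign_reads(reads, fx$windows)
  a_rev <- assign_reads(
    dplyr::mutate(reads, seq = revcomp(seq)), fx$windows
  )
  expect_identical(
    count_alleles(a_fwd, "AxB", fx$genes),
    count_alleles(a_rev, "AxB", fx$genes)
  )
})

test_that("the matcher agrees with the independent pure-R scan", {
  fx <- make_window_fixture()
  live <- fx$windows[is.na(fx$windows$discarded), ]
  set.seed(55)
  reads <- vapply(1:40, function(i) {
    if (i <= 28) {
      w <- live$seq[sample.int(nrow(live), 1)]
      s <- sample.int(36, 1)
      r <- mutate_seq(substring(w, s, s + 35), sample.int(36, sample(0:3, 1)))
      if (runif(1) < 0.5) revcomp(r) else r
    } else {
      rand_dna(36)
    }
  }, character(1))
  scan <- imprintcall:::scan_reads_cpp(reads, live$seq, 2L)
  for (i in seq_along(reads)) {
    ref <- brute_scan_one(reads[i], live$seq, 2L)
    expect_equal(scan$best_mm[i], ref$best)
    expect_equal(sort(scan$hits[[i]]), ref$hits)
  }
})

test_that("allele counting maps alleles to parents by cross direction", {
  a <- fake_assignments("g1", n_a = 10, n_b = 5)
  genes <- c("g1", "g_zero")
  axb <- count_alleles(a, "AxB", genes)
  expect_equal(axb$m[axb$gene_id == "g1"], 10L)
  expect_equal(axb$p[axb$gene_id == "g1"], 5L)
  bxa <- count_alleles(a, "BxA", genes)
  expect_equal(bxa$m[bxa$gene_id == "g1"], 5L)
  expect_equal(bxa$p[bxa$gene_id == "g1"], 10L)
  # genes with no assigned reads are present with zeros
  expect_equal(axb$m[axb$gene_id == "g_zero"], 0L)
  expect_equal(axb$p[axb$gene_id == "g_zero"], 0L)
  expect_error(count_alleles(a, "CxD"))
})

test_that("error-free counts equal the ground-truth haplotype tallies", {
  cfg <- sim_config(
    n_genes = 6L, reads_per_cross = 1500L, error_rate = 0, rng_seed = 21L,
    frac_meg = 0.2, frac_peg = 0.2
  )
  b <- simulate_bundle(cfg)
  w <- assign_gene_to_windows(build_snp_windows(b$genome, b$snps), b$genes)
  for (cr in c("AxB", "BxA")) {
    reads <- b$reads[b$reads$cross == cr, ]
    a <- assign_reads(reads, w)
    truth <- parse_read_truth(reads$read_id)
    # without errors every assigned read must carry its true accession
    assigned <- a$status == "assigned"
    expect_identical(a$allele[assigned], truth$accession[assigned])
    expect_identical(a$gene_id[assigned], truth$gene_id[assigned])
    observed <- count_alleles(a, cr, b$genes)
    oracle <- dplyr::count(
      tibble::tibble(
        gene_id = truth$gene_id[assigned],
        allele = truth$accession[assigned]
      ),
      gene_id, allele
    )
    mat <- if (cr == "AxB") "A" else "B"
    for (g in unique(oracle$gene_id)) {
      expect_equal(
        observed$m[observed$gene_id == g],
        sum(oracle$n[oracle$gene_id == g & oracle$allele == mat])
      )
    }
  }
})

test_that("haplotype recovery exceeds 99% under realistic error rates", {
  cfg <- sim_config(
    n_genes = 6L, reads_per_cross = 2000L, error_rate = 0.01, rng_seed = 23L
  )
  b <- simulate_bundle(cfg)
  w <- assign_gene_to_windows(build_snp_windows(b$genome, b$snps), b$genes)
  reads <- b$reads[b$reads$cross == "AxB", ]
  a <- assign_reads(reads, w)
  truth <- parse_read_truth(reads$read_id)
  assigned <- a$status == "assigned"
  expect_gt(sum(assigned), 100)
  expect_gte(mean(a$allele[assigned] == truth$accession[assigned]), 0.99)
})

test_that("an empty window set is a contract error", {
  w <- make_window_fixture()$windows
  w$discarded <- "multi_gene"
  expect_error(
    assign_reads(tibble::tibble(read_id = "r", seq = "ACGT"), w),
    class = "imprintcall_config_error"
  )
})
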