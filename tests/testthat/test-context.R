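test_that("hypergeometric tail equals exhaustive enumeration", {
  cases <- list(
    c(k = 8, n = 10, K = 20, N = 100),
    c(k = 0, n = 10, K = 20, N = 100),
    c(k = 3, n = 8, K = 10, N = 40),
    c(k = 5, n = 5, K = 12, N = 60),
    c(k = 1, n = 12, K = 4, N = 55)
  )
  for (cs in cases) {
    res <- enrichment_test(cs["k"], cs["n"], cs["K"], cs["N"],
                           n_perm = 100, seed = 81L)
    expect_equal(
      res$hyper_p,
      enum_hyper_upper(cs["k"], cs["n"], cs["K"], cs["N"]),
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
  # P(X >= 0) is exactly 1
  expect_equal(
    enrichment_test(0, 10, 20, 100, n_perm = 100, seed = 81L)$hyper_p, 1
  )
  expect_error(enrichment_test(11, 10, 20, 100),
               class = "imprintcall_config_error")
})

test_that("permutation and hypergeometric tests agree within Monte-Carlo error", {
  res <- enrichment_test(8, 10, 20, 100, n_perm = 10000, seed = 82L)
  se <- sqrt(res$hyper_p * (1 - res$hyper_p) / res$n_perm)
  expect_lt(abs(res$perm_p - res$hyper_p), 3 * se + 1 / res$n_perm)
  expect_identical(
    res, enrichment_test(8, 10, 20, 100, n_perm = 10000, seed = 82L)
  )
})

test_that("an implanted cluster is detected and dispersed flags are not", {
  genes <- sprintf("G%03d", 1:500)
  clustered <- genes[41:50][c(1, 3, 5, 8, 10)]
  scan <- scan_clusters(genes, clustered, window_w = 50L,
                        n_perm = 1000, seed = 83L)
  expect_gte(nrow(scan$clusters), 1L)
  expect_true(all(clustered %in% unlist(scan$clusters$members)))
  expect_lt(min(scan$clusters$p), 0.05)

  dispersed <- genes[c(50, 150, 250, 350, 450)]
  scan2 <- scan_clusters(genes, dispersed, window_w = 50L,
                         n_perm = 1000, seed = 84L)
  expect_equal(nrow(scan2$clusters), 0L)

  scan3 <- scan_clusters(genes, character(), window_w = 50L, n_perm = 10)
  expect_equal(nrow(scan3$windows), 0L)
  expect_equal(nrow(scan3$clusters), 0L)

  expect_error(scan_clusters(genes[1:10], genes[1], window_w = 50L),
               class = "imprintcall_config_error")
})

test_that("window scan respects chromosome boundaries", {
  order_tbl <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:120),
    chrom = rep(c("c1", "c2"), each = 60)
  )
  scan <- scan_clusters(order_tbl, sprintf("G%03d", 58:62),
                        window_w = 20L, n_perm = 500, seed = 85L)
  # windows never span the chromosome break
  expect_equal(nrow(scan$windows), 2L * (60L - 20L + 1L))
  expect_equal(max(scan$windows$win), 41L)
  # a window belongs to exactly one chromosome, so no cluster can span both
  if (nrow(scan$clusters) > 0) {
    for (i in seq_len(nrow(scan$clusters))) {
      g <- scan$clusters$members[[i]]
      expect_equal(
        length(unique(order_tbl$chrom[order_tbl$gene_id %in% g])), 1L
      )
    }
  }
})

test_that("TE vicinity flags and distances follow the geometry", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus", "far"), chrom = "c1",
    start = c(10000L, 20000L, 40000L), end = c(12000L, 22000L, 42000L),
    strand = c("+", "-", "+")
  )
  tes <- tibble::tibble(
    te_id = c("t1", "t2", "t3"), chrom = "c1",
    start = c(9300L, 22500L, 45000L), end = c(9500L, 22800L, 45200L),
    superfamily = c("RC/Helitron", "MuDR", "DNA")
  )
  vic <- te_vicinity(genes, tes, vicinity_bp = 2000L)
  # t1 ends 500 bp upstream of the plus-strand TSS at 10000
  expect_true(vic$has_te[vic$gene_id == "plus"])
  expect_equal(abs(vic$dist_5prime[vic$gene_id == "plus"]), 501)
  expect_lt(vic$dist_5prime[vic$gene_id == "plus"], 0)
  expect_equal(vic$superfamilies[vic$gene_id == "plus"][[1]], "RC/Helitron")
  # minus-strand gene: t2 lies 5' of the TSS at end - 1
  expect_true(vic$has_te[vic$gene_id == "minus"])
  expect_lt(vic$dist_5prime[vic$gene_id == "minus"], 0)
  # 3000 bp away: not in vicinity
  expect_false(vic$has_te[vic$gene_id == "far"])

  # TE overlapping the gene body touching the TSS gives distance 0
  tes0 <- tibble::tibble(
    te_id = "t", chrom = "c1", start = 9900L, end = 10100L,
    superfamily = "DNA"
  )
  vic0 <- te_vicinity(genes[1, ], tes0)
  expect_equal(vic0$dist_5prime, 0)

  # invariances: TE order and splitting into abutting intervals
  vic_shuf <- te_vicinity(genes, tes[c(3, 1, 2), ], vicinity_bp = 2000L)
  expect_equal(vic$has_te, vic_shuf$has_te)
  split_te <- tibble::tibble(
    te_id = c("a", "b"), chrom = "c1", start = c(9300L, 9400L),
    end = c(9400L, 9500L), superfamily = "RC/Helitron"
  )
  expect_equal(
    te_vicinity(genes[1, ], split_te)$has_te,
    te_vicinity(genes[1, ], tes[1, ])$has_te
  )
})

test_that("homolog frequency flags exclude self-hits and reuse enrichment", {
  universe <- sprintf("g%02d", 1:40)
  homologs <- tibble::tibble(
    gene_id = c(sprintf("g%02d", 1:20), "g30"),
    homolog = c(sprintf("h%02d", 1:20), "g30")   # g30 has only a self-hit
  )
  sample_set <- sprintf("g%02d", 1:10)  # all with homologs, pop rate 50%
  res <- homolog_frequency(homologs, universe, sample_set,
                           n_perm = 2000, seed = 86L)
  expect_equal(res$k, 10)
  expect_equal(res$K, 20)   # g30's self-hit does not count
  expect_lt(res$hyper_p, 0.01)
  expect_error(
    homolog_frequency(homologs, universe, "not_there"),
    class = "imprintcall_config_error"
  )
})

test_that("GO enrichment adjusts hypergeometric tails across terms", {
  universe <- sprintf("g%03d", 1:200)
  sample_set <- sprintf("g%03d", 1:10)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("g%03d", 1:12), term = "focused"),
    tibble::tibble(gene_id = sprintf("g%03d", seq(5, 200, by = 20)),
                   term = "proportional"),
    tibble::tibble(gene_id = sprintf("g%03d", 101:130), term = "absent")
  )
  res <- go_enrichment(ann, sample_set, universe)
  expect_true(res$significant[res$term == "focused"])
  expect_lt(res$p_adj[res$term == "focused"], 5e-3)
  expect_false(res$significant[res$term == "proportional"])
  expect_false(res$significant[res$term == "absent"])

  single <- go_enrichment(
    ann[ann$term == "focused", ], sample_set, universe
  )
  expect_equal(single$p_adj, single$p)
  expect_error(go_enrichment(ann, sample_set, character()),
               class = "imprintcall_config_error")
})

test_that("window scans render with significant windows highlighted", {
  genes <- sprintf("G%03d", 1:200)
  scan <- scan_clusters(genes, genes[50:54], window_w = 20L,
                        n_perm = 200, seed = 87L)
  expect_s3_class(autoplot(scan), "ggplot")
})
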