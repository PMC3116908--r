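test_that("the one-sided binomial tail matches exact enumeration", {
  # worked examples derived by direct enumeration of the binomial mass
  expect_equal(binom_onesided(2, 1, direction = "maternal"), 20 / 27,
               tolerance = 1e-12)
  expect_equal(binom_onesided(10, 0, direction = "maternal"), (2 / 3)^10,
               tolerance = 1e-12)
  expect_equal(binom_onesided(0, 10, direction = "paternal"), (1 / 3)^10,
               tolerance = 1e-12)
  expect_error(binom_onesided(0, 0), class = "imprintcall_config_error")

  # independent oracle: direct summation of dbinom mass over the tail
  for (n in c(1L, 5L, 17L, 60L)) {
    m <- 0:n
    tail_sum <- vapply(m, function(k) {
      sum(dbinom(k:n, n, 2 / 3))
    }, numeric(1))
    expect_equal(binom_onesided(m, n - m, direction = "maternal"),
                 tail_sum, tolerance = 1e-12)
    # complement identity P(X >= m) + P(X <= m - 1) = 1
    expect_equal(
      binom_onesided(m, n - m, direction = "maternal") +
        pbinom(m - 1, n, 2 / 3),
      rep(1, n + 1), tolerance = 1e-12
    )
  }
})

test_that("joint p-value is the squared maximum with its formal properties", {
  expect_equal(joint_p(0.01, 0.04), 0.0016)
  expect_equal(joint_p(1, 1), 1)
  expect_equal(joint_p(0, 0.5), 0.25)
  expect_error(joint_p(-0.1, 0.5), class = "imprintcall_config_error")
  expect_error(joint_p(0.5, 1.2), class = "imprintcall_config_error")

  set.seed(61)
  p1 <- runif(200)
  p2 <- runif(200)
  expect_equal(joint_p(p1, p2), joint_p(p2, p1))
  expect_true(all(joint_p(p1, p2) >= p1 * p2))
  # monotone in each argument
  expect_true(all(joint_p(pmin(p1 + 0.1, 1), p2) >= joint_p(p1, p2)))
})

test_that("fdr_select reproduces hand-computed q-values and the BH step-up", {
  res <- fdr_select(c(a = 0.001, b = 0.01, c = 0.02, d = 0.05))
  expect_equal(res$q_raw, c(0.004, 0.02, 0.02 * 4 / 3, 0.05))
  expect_equal(res$q, c(0.004, 0.02, 0.02 * 4 / 3, 0.05))
  expect_true(all(res$selected))

  res1 <- fdr_select(rep(1, 5))
  expect_true(all(res1$q == 1) && !any(res1$selected))

  res2 <- fdr_select(c(g = 0.04))
  expect_equal(res2$q, 0.04)
  expect_true(res2$selected)

  # tied p-values share the smaller q
  res3 <- fdr_select(c(0.5, 0.5))
  expect_equal(res3$q, c(0.5, 0.5))

  # independent reference: stats::p.adjust step-up on random vectors
  set.seed(62)
  for (i in 1:200) {
    p <- runif(sample(1:80, 1))^sample(1:3, 1)
    res <- fdr_select(p)
    bh <- sort(p.adjust(p, method = "BH"))
    expect_equal(res$q, bh, tolerance = 1e-12)
  }

  expect_equal(nrow(fdr_select(numeric())), 0L)
})

test_that("imprinting calls respond to strong and null count patterns", {
  counts <- tibble::tibble(
    gene_id = rep(c("strong_meg", "balanced"), each = 2),
    cross = rep(c("AxB", "BxA"), 2),
    m = c(300L, 290L, 200L, 200L),
    p = c(3L, 5L, 100L, 100L)
  )
  calls <- call_imprinting(counts)
  td <- tidy(calls)
  expect_equal(td$call[td$gene_id == "strong_meg"], "MEG")
  expect_equal(td$call[td$gene_id == "balanced"], "none")
  expect_lt(td$joint_p_maternal[td$gene_id == "strong_meg"], 1e-10)

  gl <- glance(calls)
  expect_equal(gl$n_tested, 2L)
  expect_equal(gl$n_meg, 1L)

  # a gene observed in only one cross is excluded with a message
  counts2 <- dplyr::bind_rows(
    counts,
    tibble::tibble(gene_id = "half", cross = "AxB", m = 50L, p = 0L)
  )
  expect_message(calls2 <- call_imprinting(counts2), "one cross")
  expect_false("half" %in% tidy(calls2)$gene_id)
})

test_that("accession-dependence classification applies the fold rules", {
  mk_counts <- function(m1, p1, m2, p2) {
    tibble::tibble(
      gene_id = "g", cross = c("AxB", "BxA"),
      m = c(m1, m2), p = c(p1, p2)
    )
  }
  call_of <- function(cl) tibble::tibble(gene_id = "g", call = cl)

  # MEG: maternal-A 100 vs paternal-A 10 (ratio 10), maternal-B 50 vs
  # paternal-B 30 (ratio 1.67) -> imprinted in A only
  res <- classify_accession_dependence(
    mk_counts(100, 30, 50, 10), call_of("MEG"), library_norm = FALSE
  )
  expect_equal(res$ratio_A, 10)
  expect_equal(res$ratio_B, 50 / 30, tolerance = 1e-12)
  expect_equal(res$accession_class, "A_only")

  # zero paternal denominator: infinite ratio counts as imprinted
  res2 <- classify_accession_dependence(
    mk_counts(40, 30, 50, 0), call_of("MEG"), library_norm = FALSE
  )
  expect_true(is.infinite(res2$ratio_A))
  expect_equal(res2$accession_class, "A_only")

  # PEG with paternal/maternal ratios 4 and 3.2 -> reciprocal at fold 3
  res3 <- classify_accession_dependence(
    mk_counts(10, 32, 10, 40), call_of("PEG"), library_norm = FALSE
  )
  expect_equal(res3$ratio_A, 4)
  expect_equal(res3$ratio_B, 3.2)
  expect_equal(res3$accession_class, "reciprocal")

  # uncalled genes are not classifiable
  res4 <- classify_accession_dependence(
    mk_counts(10, 10, 10, 10), call_of("none")
  )
  expect_equal(res4$accession_class, "not_applicable")
})

test_that("per-million normalisation equalises library depth", {
  counts <- tibble::tibble(
    gene_id = rep(c("g", "other"), each = 2),
    cross = rep(c("AxB", "BxA"), 2),
    m = c(100L, 10L, 400L, 40L),
    p = c(100L, 10L, 400L, 40L)
  )
  # library BxA is 10x shallower; normalisation must recover ratio 1
  res <- classify_accession_dependence(
    counts, tibble::tibble(gene_id = "g", call = "MEG")
  )
  expect_equal(res$ratio_A, 1, tolerance = 1e-12)
  expect_equal(res$ratio_B, 1, tolerance = 1e-12)
})

test_that("splicing heterogeneity test behaves at its extremes", {
  hom <- splicing_chisq(rbind(m = c(10, 10), p = c(5, 5)), seed = 63L)
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)

  het <- splicing_chisq(rbind(m = c(20, 0), p = c(0, 10)),
                        n_mc = 2000, seed = 64L)
  expect_lt(het$p_value, 0.01)

  # single usable SNP column: not applicable
  na_res <- splicing_chisq(rbind(m = c(20, 0), p = c(10, 0)))
  expect_true(is.na(na_res$p_value))

  # large balanced table: Monte-Carlo p within binomial error of the
  # asymptotic chi-square p, and of R's own simulated chisq.test
  set.seed(65)
  tab <- rbind(
    m = c(120, 95, 110, 100),
    p = c(60, 55, 48, 52)
  )
  res <- splicing_chisq(tab, n_mc = 4000, seed = 66L)
  asym <- stats::pchisq(res$statistic, df = 3, lower.tail = FALSE)
  se <- sqrt(asym * (1 - asym) / 4000)
  expect_lt(abs(res$p_value - asym), 4 * se)
  ref <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 4000)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(res$p_value - ref$p.value), 4 * se)
})

test_that("call objects plot and summarise through the generic verbs", {
  counts <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:6), each = 2),
    cross = rep(c("AxB", "BxA"), 6),
    m = c(98L, 97L, 10L, 12L, rep(34L, 8)),
    p = c(2L, 3L, 40L, 38L, rep(16L, 8))
  )
  calls <- call_imprinting(counts)
  expect_s3_class(tidy(calls), "tbl_df")
  expect_equal(nrow(glance(calls)), 1L)
  expect_s3_class(autoplot(calls), "ggplot")
})
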