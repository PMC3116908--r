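# Shared fixtures and independent oracles, built in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (j in positions) {
    chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
  }
  paste(chars, collapse = "")
}

# Independent pure-R reference for the matching contract: full-length
# ungapped scan of one read over every window at every offset, both
# orientations; returns the minimum mismatch count (capped at max_mm + 1)
# and the sorted indices of windows attaining it. Deliberately written
# against character matrices, not the package's C++ path.
brute_scan_one <- function(read, windows, max_mm = 2L) {
  best <- max_mm + 1L
  hits <- integer()
  for (seq in c(read, revcomp(read))) {
    rc <- strsplit(seq, "")[[1]]
    L <- length(rc)
    for (w in seq_along(windows)) {
      wc <- strsplit(windows[w], "")[[1]]
      W <- length(wc)
      if (L > W) next
      for (off in 0:(W - L)) {
        piece <- wc[(off + 1):(off + L)]
        mm <- sum(piece != rc | rc == "N" | piece == "N")
        if (mm > max_mm || mm > best) next
        if (mm < best) {
          best <- mm
          hits <- integer()
        }
        hits <- union(hits, w)
      }
    }
  }
  list(best = best, hits = sort(hits))
}

# Exhaustive hypergeometric upper tail by direct enumeration (for small
# populations); the independent oracle for enrichment_test.
enum_hyper_upper <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Minimal SLR fixture: one endosperm domain (CZE), seed coat, one
# vegetative tissue, embryo, flower_st12 and whole seed, single stage.
tiny_tissues <- function() {
  tibble::tribble(
    ~tissue,        ~compartment,     ~stage,
    "CZE_heart",    "endosperm_CZE",  "heart",
    "MPE_heart",    "endosperm_MPE",  "heart",
    "seed_coat_heart", "seed_coat",   "heart",
    "leaf",         "vegetative",     NA,
    "embryo_heart", "embryo",         "heart",
    "flower_st12",  "flower_st12",    NA,
    "seed_4DAP",    "seed_whole",     NA
  )
}

tiny_slr <- function(gene_id, cze = 1, mpe = 1, sc = 1, leaf = 1,
                     embryo = 1, flower = 1, seed = 2) {
  tibble::tibble(
    gene_id = gene_id,
    tissue = c("CZE_heart", "MPE_heart", "seed_coat_heart", "leaf",
               "embryo_heart", "flower_st12", "seed_4DAP"),
    slr = c(cze, mpe, sc, leaf, embryo, flower, seed)
  )
}

# single-cross assignment tibble builder
fake_assignments <- function(gene_id, n_a, n_b, snp_id = "S00001") {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n_a + n_b)),
    snp_id = snp_id,
    allele = rep(c("A", "B"), c(n_a, n_b)),
    gene_id = gene_id,
    mismatches = 0L,
    status = "assigned"
  )
}
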