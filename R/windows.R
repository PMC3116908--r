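#' Build allele-specific SNP windows
#'
#' For every biallelic SNP, extracts the 71-nt genomic window centred on the
#' SNP (position +/- `flank`) from the reference (accession A) and emits two
#' windows: allele A as extracted, and allele B with the centre nucleotide
#' replaced by the alternate allele. SNPs closer than `flank` to a
#' chromosome end are emitted as discarded (`edge_truncated`) and take no
#' part in matching. SNPs whose reference allele disagrees with the genome
#' are skipped and reported in the `errors` attribute.
#'
#' @param genome named character vector of chromosome sequences (see
#'   [read_genome()]).
#' @param snps tibble with `snp_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param flank half-width of the window in bp (default 35, for 71-nt
#'   windows).
#' @return tibble with one row per (SNP, allele): `window_id`, `snp_id`,
#'   `chrom`, `pos`, `allele` (`"A"`/`"B"`), `start`, `end` (0-based
#'   half-open), `seq`, `gene_id` (`NA` until [assign_gene_to_windows()]),
#'   `discarded` (`NA`, `"edge_truncated"`, or `"multi_gene"`). Skipped
#'   SNPs are recorded in `attr(, "errors")`.
#' @export
build_snp_windows <- function(genome, snps, flank = 35L) {
  flank <- as.integer(flank)
  missing_chrom <- setdiff(unique(snps$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    config_error(paste0(
      "SNP chromosome(s) absent from genome: ",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  per_chrom <- split(snps, snps$chrom)
  rows <- list()
  errors <- list()
  for (ch in names(per_chrom)) {
    s <- per_chrom[[ch]]
    chrom_seq <- genome[[ch]]
    clen <- nchar(chrom_seq)
    genome_base <- substring(chrom_seq, s$pos, s$pos)
    mismatch <- genome_base != s$ref
    if (any(mismatch)) {
      errors[[ch]] <- tibble(
        snp_id = s$snp_id[mismatch], chrom = ch, pos = s$pos[mismatch],
        expected = s$ref[mismatch], found = genome_base[mismatch]
      )
      s <- s[!mismatch, ]
    }
    if (nrow(s) == 0) next
    edge <- s$pos - flank < 1L | s$pos + flank > clen
    seq_a <- rep(NA_character_, nrow(s))
    seq_b <- rep(NA_character_, nrow(s))
    ok <- !edge
    seq_a[ok] <- substring(chrom_seq, s$pos[ok] - flank, s$pos[ok] + flank)
    seq_b[ok] <- paste0(
      substring(seq_a[ok], 1L, flank), s$alt[ok],
      substring(seq_a[ok], flank + 2L, 2L * flank + 1L)
    )
    rows[[ch]] <- tibble(
      snp_id = rep(s$snp_id, each = 2),
      chrom = ch,
      pos = rep(s$pos, each = 2),
      allele = rep(c("A", "B"), nrow(s)),
      start = rep(s$pos - flank - 1L, each = 2),
      end = rep(s$pos + flank, each = 2),
      seq = as.vector(rbind(seq_a, seq_b)),
      gene_id = NA_character_,
      discarded = rep(
        ifelse(edge, "edge_truncated", NA_character_), each = 2
      )
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out[order(out$chrom, out$pos, out$allele), ]
    out$window_id <- sprintf("W%06d", seq_len(nrow(out)))
    out <- out[, c(
      "window_id", "snp_id", "chrom", "pos", "allele", "start", "end",
      "seq", "gene_id", "discarded"
    )]
  }
  err <- bind_rows(errors)
  if (nrow(err) > 0) {
    warn(sprintf(
      "%d SNP(s) skipped: reference allele does not match genome (first: %s)",
      nrow(err), err$snp_id[1]
    ))
  }
  attr(out, "errors") <- err
  out
}

#' Associate SNP windows with genes
#'
#' A window is associated with a gene when its interval overlaps or is
#' included in the gene region (gene start to end, ignoring exon/intron
#' structure). Windows touching two or more genes are discarded
#' (`multi_gene`); windows touching none keep `gene_id = NA` and are
#' retained for matching but never counted.
#'
#' @param windows tibble from [build_snp_windows()].
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return `windows` with `gene_id` and `discarded` filled in.
#' @export
assign_gene_to_windows <- function(windows, genes) {
  if (any(genes$end <= genes$start)) {
    config_error("degenerate gene interval(s) in annotation")
  }
  live <- which(is.na(windows$discarded))
  if (length(live) == 0) return(windows)
  gr_w <- as_granges0(windows[live, ])
  gr_g <- as_granges0(genes)
  ov <- GenomicRanges::findOverlaps(gr_w, gr_g)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  n_genes <- tabulate(qh, nbins = length(live))
  first_gene <- rep(NA_character_, length(live))
  first_gene[qh[!duplicated(qh)]] <- genes$gene_id[sh[!duplicated(qh)]]
  windows$gene_id[live] <- ifelse(n_genes == 1, first_gene, NA_character_)
  windows$discarded[live] <- ifelse(
    n_genes >= 2, "multi_gene", windows$discarded[live]
  )
  windows
}
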