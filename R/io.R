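#' Write a simulated bundle to standard file formats
#'
#' Writes the genome (FASTA), reads (FASTQ, constant Phred quality), gene
#' models (GFF3, 1-based inclusive), transposable elements (BED-like TSV,
#' 0-based half-open, with a superfamily column), the SNP table (TSV,
#' 1-based positions), the SLR matrix with its tissue sidecar, the truth
#' table, and a JSON manifest recording the configuration and per-file MD5
#' checksums.
#'
#' @param bundle an `imprint_bundle` from [simulate_bundle()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    reads_AxB = file.path(dir, "reads_AxB.fastq"),
    reads_BxA = file.path(dir, "reads_BxA.fastq"),
    genes = file.path(dir, "genes.gff3"),
    tes = file.path(dir, "tes.bed"),
    snps = file.path(dir, "snps.tsv"),
    slr = file.path(dir, "slr.tsv"),
    tissues = file.path(dir, "tissues.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$genome), paths[["genome"]]
  )
  for (cross in c("AxB", "BxA")) {
    r <- bundle$reads[bundle$reads$cross == cross, ]
    write_fastq(r$seq, r$read_id, paths[[paste0("reads_", cross)]])
  }
  write_gff3_genes(bundle$genes, bundle$exons, paths[["genes"]])
  readr::write_tsv(
    bundle$tes[, c("chrom", "start", "end", "te_id", "superfamily")],
    paths[["tes"]], col_names = FALSE
  )
  readr::write_tsv(
    bundle$snps[, c("chrom", "pos", "ref", "alt")], paths[["snps"]]
  )
  slr_wide <- tidyr::pivot_wider(
    bundle$slr, names_from = "tissue", values_from = "slr"
  )
  readr::write_tsv(slr_wide, paths[["slr"]])
  readr::write_tsv(bundle$tissues, paths[["tissues"]])
  truth_flat <- bundle$truth
  if (is.list(truth_flat$snp_pos)) {
    truth_flat$snp_pos <- vapply(
      truth_flat$snp_pos, paste, character(1), collapse = ","
    )
  }
  readr::write_tsv(truth_flat, paths[["truth"]])
  files <- paths[names(paths) != "manifest"]
  manifest <- list(
    config = unclass(bundle$config),
    files = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(
    manifest, paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  invisible(paths)
}

write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
}

write_gff3_genes <- function(genes, exons, path) {
  gr_gene <- as_granges0(genes)
  S4Vectors::mcols(gr_gene) <- S4Vectors::DataFrame(
    source = "imprintcall", type = "gene", ID = genes$gene_id
  )
  GenomicRanges::strand(gr_gene) <- genes$strand
  ex <- left_join(exons, genes[, c("gene_id", "strand")], by = "gene_id")
  gr_ex <- as_granges0(ex)
  S4Vectors::mcols(gr_ex) <- S4Vectors::DataFrame(
    source = "imprintcall", type = "exon",
    ID = sprintf("%s.exon%d", ex$gene_id, ex$exon),
    Parent = ex$gene_id
  )
  GenomicRanges::strand(gr_ex) <- ex$strand
  rtracklayer::export(c(gr_gene, gr_ex), path, format = "gff3")
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}

#' Read single-end reads from FASTQ
#'
#' Performs a light structural validation (4-line records, `@`/`+`
#' markers, sequence/quality length agreement) and aborts naming the first
#' corrupt record.
#'
#' @param path FASTQ file (uncompressed).
#' @param cross optional cross label attached as a column.
#' @return tibble `read_id`, `seq` (and `cross` when given).
#' @export
read_reads_fastq <- function(path, cross = NULL) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    data_error(sprintf(
      "corrupt FASTQ record %d in %s: truncated file",
      length(lines) %/% 4 + 1, path
    ))
  }
  n <- length(lines) %/% 4
  hd <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  pl <- lines[seq(3, by = 4, length.out = n)]
  qu <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(
    !startsWith(hd, "@") | !startsWith(pl, "+") | nchar(sq) != nchar(qu)
  )
  if (length(bad) > 0) {
    data_error(sprintf("corrupt FASTQ record %d in %s", bad[1], path))
  }
  out <- tibble(read_id = sub("^@", "", sub("\\s.*$", "", hd)), seq = sq)
  if (!is.null(cross)) out$cross <- cross
  out
}

#' Read a SNP table
#'
#' Tab-separated `chrom`, `pos` (1-based), `ref`, `alt`; header optional,
#' `#` comment lines ignored.
#'
#' @param path TSV file.
#' @return tibble `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom|pos", tolower(first))
  x <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_names = if (has_header) TRUE else c("chrom", "pos", "ref", "alt")
  )
  names(x)[1:4] <- c("chrom", "pos", "ref", "alt")
  x <- x[, 1:4]
  x$pos <- as.integer(x$pos)
  bad <- !x$ref %in% c("A", "C", "G", "T") | !x$alt %in% c("A", "C", "G", "T") |
    x$ref == x$alt
  if (any(bad)) {
    data_error(sprintf(
      "invalid SNP record(s) at line(s) %s of %s",
      paste(head(which(bad), 5), collapse = ", "), path
    ))
  }
  tibble(
    snp_id = sprintf("S%05d", seq_len(nrow(x))),
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt
  )
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` and (optionally) `exon` features.
#' @return list with `genes` and `exons` tibbles in 0-based half-open
#'   coordinates.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  g <- df[df$type == "gene", ]
  genes <- tibble(
    gene_id = as.character(g$ID),
    chrom = as.character(g$seqnames),
    start = g$start - 1L, end = g$end,
    strand = ifelse(as.character(g$strand) == "-", "-", "+")
  )
  e <- df[df$type == "exon", ]
  exons <- if (nrow(e) > 0) {
    parent <- vapply(e$Parent, function(p) as.character(p)[1], character(1))
    tibble(
      gene_id = parent,
      chrom = as.character(e$seqnames),
      start = e$start - 1L, end = e$end
    ) |>
      arrange(.data$gene_id, .data$start) |>
      group_by(.data$gene_id) |>
      mutate(exon = row_number()) |>
      ungroup()
  } else {
    genes |>
      transmute(
        gene_id = .data$gene_id, chrom = .data$chrom,
        start = .data$start, end = .data$end, exon = 1L
      )
  }
  list(genes = genes, exons = exons)
}

#' Read a BED-like transposable-element table
#'
#' Columns: chrom, start, end (0-based half-open), te_id, superfamily; no
#' header.
#'
#' @param path TSV/BED file.
#' @return tibble `te_id`, `chrom`, `start`, `end`, `superfamily`.
#' @export
read_te_table <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "te_id", "superfamily"),
    show_col_types = FALSE
  )
  x[, c("te_id", "chrom", "start", "end", "superfamily")]
}

#' Read an SLR matrix and its tissue sidecar
#'
#' @param slr_path wide TSV: `gene_id` column plus one column per tissue.
#' @param tissues_path TSV `tissue`, `compartment`, `stage`.
#' @return list with long `slr` tibble (`gene_id`, `tissue`, `slr`) and
#'   `tissues` metadata tibble.
#' @export
read_slr_matrix <- function(slr_path, tissues_path) {
  wide <- readr::read_tsv(slr_path, show_col_types = FALSE)
  slr <- tidyr::pivot_longer(
    wide, -"gene_id", names_to = "tissue", values_to = "slr"
  )
  tissues <- readr::read_tsv(tissues_path, show_col_types = FALSE)
  list(slr = slr, tissues = tissues)
}

#' Read a bedGraph-like signal track into per-position form
#'
#' @param path TSV: chrom, start, end (0-based half-open), value; no
#'   header, `#`/`track` lines ignored.
#' @return tibble `chrom`, `pos` (0-based), `value`, one row per covered
#'   position.
#' @export
read_signal_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  x <- readr::read_tsv(
    I(paste(lines, collapse = "\n")),
    col_names = c("chrom", "start", "end", "value"),
    show_col_types = FALSE
  )
  n <- x$end - x$start
  tibble(
    chrom = rep(x$chrom, n),
    pos = unlist(Map(function(s, e) seq.int(s, e - 1L), x$start, x$end)),
    value = rep(x$value, n)
  )
}
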