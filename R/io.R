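# Readers and writers for the pipeline's on-disk formats: beta matrices as
# TSV (probes in rows), genomes as FASTA, gene models as BED6 (0-based
# half-open) or GFF3 (1-based inclusive), probe manifests and phenotype
# sheets as CSV, gene sets as GMT, truth sets and run manifests as JSON.

#' Write a beta matrix as TSV
#'
#' Probes in rows, first column `probe_id`, header = sample IDs; missing
#' values written as `NA`.
#'
#' @param beta A [beta_matrix].
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(inherits(beta, "beta_matrix"))
  df <- data.frame(probe_id = beta$probe_ids, beta$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta matrix from TSV
#'
#' Validates uniqueness of IDs, numeric cells and the `[0, 1]` range,
#' reporting the offending probe/sample coordinates on failure. Missing-value
#' tokens become masked (`NA`) entries, not zeros.
#'
#' @param path TSV written by [write_beta_matrix()].
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "probe_id") stop("first column must be probe_id")
  probe_ids <- df[[1]]
  sample_ids <- names(df)[-1]
  vals <- matrix(NA_real_, length(probe_ids), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & !col %in% c("NA", "", "NaN"))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value at (%s, %s): '%s'",
                   probe_ids[bad[1]], sample_ids[j], col[bad[1]]))
    out_of_range <- which(!is.na(num) & (num < 0 | num > 1))
    if (length(out_of_range) > 0)
      stop(sprintf("beta value out of [0,1] at (%s, %s): %s",
                   probe_ids[out_of_range[1]], sample_ids[j],
                   col[out_of_range[1]]))
    vals[, j] <- num
  }
  beta_matrix(vals, probe_ids, sample_ids)
}

#' Write a genome as FASTA
#' @param genome A [genome_bundle()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_bundle"))
  seqs <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read genome chromosomes from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, name = genes$gene_id)
}

granges_to_genes <- function(gr) {
  nm <- if (!is.null(gr$name)) gr$name else
    if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  data.frame(gene_id = nm, chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, start = start0, end = end0,
             tss = ifelse(strand == "+", start0, end0 - 1L),
             stringsAsFactors = FALSE)
}

#' Write gene models as BED6 (0-based half-open) or GFF3 (1-based inclusive)
#'
#' @param genes Gene table of a [genome_bundle()].
#' @param path Output path; dialect chosen by `format`.
#' @param format `"bed"` or `"gff3"`.
#' @export
write_genes <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- genes_to_granges(genes)
  if (format == "bed") {
    gr$score <- 0
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' Both dialects are converted to the internal 0-based half-open convention.
#'
#' @param path Input path.
#' @param format `"bed"` or `"gff3"` (guessed from the extension if missing).
#' @return Gene data.frame (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else
    "GFF3")
  granges_to_genes(gr)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                       character(1))
  out
}

#' Write gene sets as GMT
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest (settings, seed, shapes) as JSON
#' @param manifest Named list.
#' @param path Output path.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
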