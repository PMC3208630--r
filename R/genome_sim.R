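# Toy genome construction with planted 50-nt probe classes covering every
# branch of the probe-validity criteria.

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Genome bundle container
#'
#' A small genome plus gene annotation used for probe-validity testing.
#' Coordinates are 0-based half-open throughout; `tss` equals `start` on the
#' `+` strand and `end - 1` on the `-` strand.
#'
#' @param chromosomes Named character vector of nucleotide sequences.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(chromosomes, genes) {
  stopifnot(is.character(chromosomes), !is.null(names(chromosomes)))
  req <- c("gene_id", "chrom", "strand", "start", "end", "tss")
  stopifnot(all(req %in% names(genes)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(chromosomes)) stop("gene on unknown chromosome")
    if (g$start < 0 || g$end > nchar(chromosomes[[g$chrom]]))
      stop("gene span outside chromosome bounds")
    expected_tss <- if (g$strand == "+") g$start else g$end - 1L
    if (g$tss != expected_tss) stop("tss inconsistent with strand")
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_bundle")
}

mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- sample(alt, 1)
  }
  paste(ch, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome with planted probe-validity classes
#'
#' Builds a small random genome with non-overlapping genes, then plants 50-nt
#' probes in seven classes with known validity outcomes:
#' (a) exact match ending in a genomic CG; (b) 1-3 internal mismatches;
#' (c) 4 internal mismatches (fails the mismatch criterion); (d) perfect body
#' but mismatched 3'-terminal CG anchor; (e) multi-mapper with exactly one
#' 100% hit; (f) multi-mapper with no 100% hit; (g) clean alignment outside
#' any promoter/gene-body window. Replicates alternate between `+` and `-`
#' strand placements.
#'
#' @param config A [sim_config()]; the `genome_*` fields set genome shape.
#' @param seed Integer seed.
#' @param n_per_class Planted probes per class.
#' @return List with `genome` ([genome_bundle]), `manifest` (data.frame:
#'   `probe_id`, `sequence`, `gene_symbol`, `chrom`, `pos`, `strand`), and
#'   `truth` (class `truth_set` with a `planted_validity` data.frame).
#' @export
generate_genome_and_probes <- function(config, seed = config$seed,
                                       n_per_class = 2L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    n_chrom <- config$genome_n_chrom
    len <- config$genome_chrom_length
    if (len < 5000) stop("genome too short to host requested probes")
    chrom_names <- sprintf("chr%d", seq_len(n_chrom))
    chrs <- lapply(seq_len(n_chrom), function(i) {
      strsplit(random_dna(len), "")[[1]]
    })
    names(chrs) <- chrom_names

    # Evenly spaced genes with 2 kb intergenic gaps (room for 1.5 kb
    # promoter windows); strands alternate.
    per_chrom <- ceiling(config$genome_n_genes / n_chrom)
    gene_len <- 2500L; gap <- 2000L
    genes <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
      k <- min(per_chrom, config$genome_n_genes - (ci - 1L) * per_chrom)
      if (k <= 0) return(NULL)
      starts <- gap + (seq_len(k) - 1L) * (gene_len + gap)
      if (max(starts) + gene_len > len - 3000L)
        stop("genome too short to host requested genes")
      strand <- rep(c("+", "-"), length.out = k)
      data.frame(gene_id = sprintf("GENE%02d", (ci - 1L) * per_chrom +
                                     seq_len(k)),
                 chrom = chrom_names[ci], strand = strand,
                 start = starts, end = starts + gene_len,
                 tss = ifelse(strand == "+", starts, starts + gene_len - 1L),
                 stringsAsFactors = FALSE)
    }))

    used <- lapply(chrom_names, function(x) matrix(numeric(0), 0, 2))
    names(used) <- chrom_names
    reserve <- function(chrom, start) {
      iv <- used[[chrom]]
      ok <- all(start + 50 <= iv[, 1] | start >= iv[, 2]) || nrow(iv) == 0
      if (ok) used[[chrom]] <<- rbind(iv, c(start, start + 50))
      ok
    }
    pick_window <- function(chrom, lo, hi) {
      for (try in 1:200) {
        s <- sample(seq.int(lo, hi - 50L), 1)
        if (reserve(chrom, s)) return(s)
      }
      stop("genome too short to host requested probes")
    }

    # Write an oriented 50-mer into the genome at (chrom, start, strand):
    # '+' writes the sequence as-is, '-' writes its reverse complement.
    write_window <- function(chrom, start, strand, oriented) {
      s <- if (strand == "+") oriented else revcomp_chr(oriented)
      chrs[[chrom]][(start + 1):(start + 50)] <<- strsplit(s, "")[[1]]
    }
    read_window <- function(chrom, start, strand) {
      s <- paste(chrs[[chrom]][(start + 1):(start + 50)], collapse = "")
      if (strand == "+") s else revcomp_chr(s)
    }

    classes <- c("a", "b", "c", "d", "e", "f", "g")
    rows <- list(); truth_rows <- list(); pid <- 0L
    # round-robin host genes for genic classes
    gene_ptr <- 0L
    next_gene <- function() {
      gene_ptr <<- gene_ptr %% nrow(genes) + 1L
      genes[gene_ptr, ]
    }

    for (cls in classes) {
      for (rep_i in seq_len(n_per_class)) {
        pid <- pid + 1L
        strand <- if (rep_i %% 2L == 1L) "+" else "-"
        if (cls == "g") {
          # chromosome tail: > 1.5 kb from every TSS and outside all bodies
          chrom <- chrom_names[(pid %% n_chrom) + 1L]
          gstart <- pick_window(chrom, len - 1400L, len - 60L)
          on_chrom <- genes[genes$chrom == chrom, ]
          host_gene <- on_chrom$gene_id[nrow(on_chrom)]
        } else {
          g <- next_gene()
          chrom <- g$chrom
          gstart <- pick_window(chrom, g$start + 10L, g$end - 60L)
          host_gene <- g$gene_id
        }
        # design the oriented genomic 50-mer with the required anchor
        o <- random_dna(50)
        substr(o, 49, 50) <- if (cls == "d") "AT" else "CG"
        write_window(chrom, gstart, strand, o)
        probe <- o
        if (cls == "b") probe <- mutate_at(probe, c(10, 20, 30))
        if (cls == "c") probe <- mutate_at(probe, c(10, 20, 30, 40))
        if (cls == "d") substr(probe, 49, 50) <- "CG"
        if (cls == "e") {
          # second, imperfect copy elsewhere
          chrom2 <- chrom_names[(match(chrom, chrom_names) %% n_chrom) + 1L]
          s2 <- pick_window(chrom2, len - 2900L, len - 60L)
          write_window(chrom2, s2, "+", mutate_at(o, c(15, 35)))
        }
        if (cls == "f") {
          probe <- mutate_at(o, 25)       # 1 mismatch at the design locus
          chrom2 <- chrom_names[(match(chrom, chrom_names) %% n_chrom) + 1L]
          s2 <- pick_window(chrom2, len - 2900L, len - 60L)
          write_window(chrom2, s2, "+", mutate_at(o, 35))  # 2 vs probe
        }
        probe_id <- sprintf("pv%03d", pid)
        rows[[pid]] <- data.frame(probe_id = probe_id, sequence = probe,
                                  gene_symbol = host_gene, chrom = chrom,
                                  pos = gstart, strand = strand,
                                  stringsAsFactors = FALSE)
        expected <- switch(cls,
          a = c(TRUE, "PASS"), b = c(TRUE, "PASS"),
          c = c(FALSE, "TOO_MANY_MISMATCHES"),
          d = c(FALSE, "ANCHOR_FAIL"),
          e = c(TRUE, "PASS"),
          f = c(FALSE, "AMBIGUOUS_NO_PERFECT_TOP"),
          g = c(FALSE, "ANNOTATION_FAIL"))
        truth_rows[[pid]] <- data.frame(
          probe_id = probe_id, class = cls,
          expected_valid = as.logical(expected[1]),
          expected_reason = expected[2],
          expected_chrom = chrom, expected_start = gstart,
          expected_strand = strand, stringsAsFactors = FALSE)
      }
    }

    chromosomes <- vapply(chrs, paste, character(1), collapse = "")
    genome <- genome_bundle(chromosomes, genes)
    manifest <- do.call(rbind, rows)
    truth <- structure(list(planted_validity = do.call(rbind, truth_rows)),
                       class = "truth_set")
    list(genome = genome, manifest = manifest, truth = truth)
  })
}
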