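# Cross-species probe validity: each human-designed 50-nt probe interrogates
# its CpG by single-base extension at the 3' end, so a probe is only
# experimentally meaningful on another genome if (1) its 3'-terminal CG
# dinucleotide matches the genome exactly, (2) it aligns with at most 3
# mismatches (identity >= 94%), and (3) when it hits multiple places, exactly
# one hit is a 100% match (that locus is taken). Surviving probes must still
# map within 1.5 kb upstream of the expected gene's TSS or overlap its body.

#' Align a 50-nt probe to a genome (ungapped, both strands)
#'
#' Finds every ungapped placement with at most `max_mismatches` substitutions
#' on either strand. `N` in the probe counts as a mismatch. Hits are sorted
#' by mismatch count, then chromosome, start and strand for determinism.
#' Coordinates are 0-based half-open; a hit covers `[start, start + 50)`.
#'
#' @param probe_seq Character, exactly 50 nt over ACGTN.
#' @param genome A [genome_bundle()].
#' @param max_mismatches Maximum substitutions per hit (default 5, so that
#'   criterion-2 failures at 4-5 mismatches are still observed as hits).
#' @return data.frame: `chrom`, `start`, `strand`, `mismatch_count`,
#'   `identity`, `three_prime_anchor_ok`.
#' @export
align_probe <- function(probe_seq, genome, max_mismatches = 5L) {
  stopifnot(inherits(genome, "genome_bundle"))
  probe_seq <- toupper(probe_seq)
  if (nchar(probe_seq) != 50) stop("probe length must be exactly 50")
  if (!grepl("^[ACGTN]+$", probe_seq)) stop("probe alphabet must be ACGTN")
  probe <- Biostrings::DNAString(probe_seq)
  probe_chars <- strsplit(probe_seq, "")[[1]]
  hits <- list()
  for (chrom in names(genome$chromosomes)) {
    subject <- Biostrings::DNAString(genome$chromosomes[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") probe else Biostrings::reverseComplement(probe)
      mt <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE)
      if (length(mt) == 0) next
      starts <- Biostrings::start(mt) - 1L   # to 0-based
      for (s in starts) {
        seg <- substr(genome$chromosomes[[chrom]], s + 1, s + 50)
        oriented <- if (strand == "+") seg else revcomp_chr(seg)
        seg_chars <- strsplit(oriented, "")[[1]]
        mism <- probe_chars != seg_chars | probe_chars == "N"
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = s, strand = strand,
          mismatch_count = sum(mism),
          identity = (50 - sum(mism)) / 50,
          three_prime_anchor_ok = !mism[49] && !mism[50],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatch_count = integer(0),
                      identity = numeric(0),
                      three_prime_anchor_ok = logical(0)))
  out <- do.call(rbind, hits)
  out <- out[out$mismatch_count <= max_mismatches, , drop = FALSE]
  out[order(out$mismatch_count, out$chrom, out$start, out$strand), ,
      drop = FALSE]
}

empty_verdict <- function(probe_id, valid, reason) {
  structure(list(probe_id = probe_id, valid = valid, reason = reason,
                 chosen_hit = NULL, mapped_gene = NA_character_),
            class = "validity_verdict")
}

#' Apply the experimental-validity criteria to alignment hits
#'
#' Criterion 1: the chosen hit's 3'-terminal CG anchor must match exactly
#' (required for single-base extension). Criterion 2: at most 3 mismatches of
#' the 50 nt (identity >= 94%). Criterion 3: if multiple hits exist, the
#' probe is valid only when exactly one hit has 100% identity, and that hit
#' is chosen; a unique hit is judged by criteria 1-2 alone.
#'
#' @param hits data.frame from [align_probe()].
#' @param probe_id Identifier carried into the verdict.
#' @return A `validity_verdict`: `probe_id`, `valid`, `reason` (one of PASS,
#'   ANCHOR_FAIL, TOO_MANY_MISMATCHES, AMBIGUOUS_NO_PERFECT_TOP, NO_HIT,
#'   ANNOTATION_FAIL), `chosen_hit`, `mapped_gene`.
#' @export
apply_validity_criteria <- function(hits, probe_id = NA_character_) {
  if (is.null(hits) || nrow(hits) == 0)
    return(empty_verdict(probe_id, FALSE, "NO_HIT"))
  if (nrow(hits) > 1) {
    perfect <- which(hits$mismatch_count == 0)
    if (length(perfect) != 1)
      return(empty_verdict(probe_id, FALSE, "AMBIGUOUS_NO_PERFECT_TOP"))
    hit <- hits[perfect, , drop = FALSE]
  } else {
    hit <- hits
  }
  if (!hit$three_prime_anchor_ok) {
    v <- empty_verdict(probe_id, FALSE, "ANCHOR_FAIL")
    v$chosen_hit <- hit
    return(v)
  }
  if (hit$mismatch_count > 3) {
    v <- empty_verdict(probe_id, FALSE, "TOO_MANY_MISMATCHES")
    v$chosen_hit <- hit
    return(v)
  }
  v <- empty_verdict(probe_id, TRUE, "PASS")
  v$chosen_hit <- hit
  v
}

# Strand-aware annotation windows, 0-based half-open: on '+' the upstream
# window is [tss - 1500, tss); on '-' it is [tss, tss + 1500) (tss = end - 1).
gene_windows <- function(gene) {
  if (gene$strand == "+") {
    up <- c(max(0, gene$tss - 1500L), gene$tss)
  } else {
    up <- c(gene$tss, gene$tss + 1500L)
  }
  list(upstream = up, body = c(gene$start, gene$end))
}

overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end && b_start < a_end
}

#' Check a passing probe against the expected gene annotation
#'
#' The probe keeps its validity only if the chosen hit overlaps the expected
#' gene's 1.5 kb upstream window (strand-aware) or its gene body, confirming
#' the human-derived annotation transfers to the target genome.
#'
#' @param verdict A passing `validity_verdict` with a chosen hit.
#' @param genes Gene table of a [genome_bundle()] (0-based half-open).
#' @param expected_gene Gene ID the probe was annotated to at design time.
#' @return Updated `validity_verdict` (`mapped_gene` set, or reason
#'   `ANNOTATION_FAIL`).
#' @export
map_to_annotation <- function(verdict, genes, expected_gene) {
  stopifnot(inherits(verdict, "validity_verdict"))
  if (nrow(genes) == 0) stop("gene list is empty")
  if (!verdict$valid) return(verdict)
  hit <- verdict$chosen_hit
  g <- genes[genes$gene_id == expected_gene & genes$chrom == hit$chrom, ,
             drop = FALSE]
  ok <- FALSE
  for (i in seq_len(nrow(g))) {
    w <- gene_windows(g[i, ])
    if (overlaps(hit$start, hit$start + 50, w$body[1], w$body[2]) ||
        overlaps(hit$start, hit$start + 50, w$upstream[1], w$upstream[2])) {
      ok <- TRUE; break
    }
  }
  if (!ok) {
    verdict$valid <- FALSE
    verdict$reason <- "ANNOTATION_FAIL"
  } else {
    verdict$mapped_gene <- expected_gene
  }
  verdict
}

#' Validate a probe manifest against a genome
#'
#' Runs [align_probe()], [apply_validity_criteria()] and
#' [map_to_annotation()] for every probe in a manifest.
#'
#' @param manifest data.frame with `probe_id`, `sequence`, `gene_symbol`.
#' @param genome A [genome_bundle()].
#' @param max_mismatches Passed to [align_probe()].
#' @return data.frame: `probe_id`, `valid`, `reason`, `chrom`, `start`,
#'   `strand`, `mismatches`, `identity`, `mapped_gene`.
#' @export
validate_probes <- function(manifest, genome, max_mismatches = 5L) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    hits <- align_probe(m$sequence, genome, max_mismatches)
    v <- apply_validity_criteria(hits, m$probe_id)
    v <- if (v$valid) map_to_annotation(v, genome$genes, m$gene_symbol) else v
    hit <- v$chosen_hit
    data.frame(probe_id = m$probe_id, valid = v$valid, reason = v$reason,
               chrom = if (is.null(hit)) NA_character_ else hit$chrom,
               start = if (is.null(hit)) NA_integer_ else hit$start,
               strand = if (is.null(hit)) NA_character_ else hit$strand,
               mismatches = if (is.null(hit)) NA_integer_ else
                 hit$mismatch_count,
               identity = if (is.null(hit)) NA_real_ else hit$identity,
               mapped_gene = v$mapped_gene, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
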