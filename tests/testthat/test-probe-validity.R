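toy_genome <- function(seed = 1, len = 3000) {
  set.seed(seed)
  chr1 <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      start = 2000L, end = 2600L, tss = 2000L,
                      stringsAsFactors = FALSE)
  genome_bundle(c(chr1 = chr1), genes)
}

test_that("align_probe finds verbatim copies and planted mismatches", {
  g <- toy_genome(2)
  probe <- substr(g$chromosomes[["chr1"]], 101, 150)
  hits <- align_probe(probe, g)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 100)
  expect_equal(hits$mismatch_count, 0)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$strand, "+")
  # three substitutions give 94% identity
  p3 <- probe
  for (pos in c(5, 15, 25))
    substr(p3, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                    substr(p3, pos, pos))[1]
  h3 <- align_probe(p3, g)
  expect_equal(h3$mismatch_count, 3)
  expect_equal(h3$identity, 0.94)
  expect_error(align_probe(substr(probe, 1, 49), g), "exactly 50")
  expect_error(align_probe(gsub("A", "X", probe), g), "alphabet")
})

test_that("align_probe agrees with the brute-force sliding-window oracle", {
  g <- toy_genome(3, len = 5000)
  set.seed(3)
  probes <- c(
    substr(g$chromosomes[["chr1"]], 501, 550),                 # exact +
    revcomp_probe <- {
      s <- substr(g$chromosomes[["chr1"]], 1201, 1250)
      chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    },                                                          # exact -
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
          collapse = ""))                                       # random
  p4 <- substr(g$chromosomes[["chr1"]], 2001, 2050)
  for (pos in c(3, 30, 44, 50))
    substr(p4, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                    substr(p4, pos, pos))[1]
  probes <- c(probes, p4)                                       # 4 mismatches
  for (pr in probes) {
    got <- align_probe(pr, g, max_mismatches = 5)
    want <- oracle_align(pr, g$chromosomes, 5)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("validity criteria decide each boundary case", {
  hit <- function(mm, anchor, start = 100, chrom = "chr1") {
    data.frame(chrom = chrom, start = start, strand = "+",
               mismatch_count = mm, identity = (50 - mm) / 50,
               three_prime_anchor_ok = anchor, stringsAsFactors = FALSE)
  }
  # single hit, 3 mismatches, anchor ok: the criterion-2 boundary passes
  v <- apply_validity_criteria(hit(3, TRUE), "p1")
  expect_true(v$valid); expect_equal(v$reason, "PASS")
  # 4 mismatches fail criterion 2
  v <- apply_validity_criteria(hit(4, TRUE), "p2")
  expect_false(v$valid); expect_equal(v$reason, "TOO_MANY_MISMATCHES")
  # perfect body but broken CG anchor fails criterion 1
  v <- apply_validity_criteria(hit(0, FALSE), "p3")
  expect_false(v$valid); expect_equal(v$reason, "ANCHOR_FAIL")
  # multiple hits without a unique perfect top fail criterion 3
  v <- apply_validity_criteria(rbind(hit(1, TRUE), hit(2, TRUE, 900)), "p4")
  expect_false(v$valid); expect_equal(v$reason, "AMBIGUOUS_NO_PERFECT_TOP")
  # two perfect hits are ambiguous too
  v <- apply_validity_criteria(rbind(hit(0, TRUE), hit(0, TRUE, 900)), "p5")
  expect_false(v$valid); expect_equal(v$reason, "AMBIGUOUS_NO_PERFECT_TOP")
  # a unique perfect top among multiple hits is chosen
  v <- apply_validity_criteria(rbind(hit(0, TRUE), hit(2, TRUE, 900)), "p6")
  expect_true(v$valid); expect_equal(v$chosen_hit$start, 100)
  # no hits at all
  v <- apply_validity_criteria(align_probe(strrep("A", 50), toy_genome(5)),
                               "p7")
  expect_false(v$valid); expect_equal(v$reason, "NO_HIT")
})

test_that("annotation windows are strand-aware, half-open, and gene-matched", {
  genes <- data.frame(gene_id = c("G1", "G2"),
                      chrom = "chr1", strand = c("+", "-"),
                      start = c(5000L, 20000L), end = c(7000L, 22000L),
                      tss = c(5000L, 21999L), stringsAsFactors = FALSE)
  mk <- function(start) {
    v <- apply_validity_criteria(data.frame(
      chrom = "chr1", start = start, strand = "+", mismatch_count = 0,
      identity = 1, three_prime_anchor_ok = TRUE, stringsAsFactors = FALSE),
      "p")
    v
  }
  # 100 bp upstream of a + gene TSS
  expect_true(map_to_annotation(mk(4850), genes, "G1")$valid)
  # overlapping the gene body
  expect_true(map_to_annotation(mk(6000), genes, "G1")$valid)
  # 1,501 bp upstream: window is [tss-1500, tss), half-open
  v <- map_to_annotation(mk(5000 - 1501 - 49), genes, "G1")
  expect_false(v$valid); expect_equal(v$reason, "ANNOTATION_FAIL")
  # last base still overlapping the window start passes
  expect_true(map_to_annotation(mk(5000 - 1500 - 49), genes, "G1")$valid)
  # minus-strand upstream window sits above the TSS
  expect_true(map_to_annotation(mk(22500), genes, "G2")$valid)
  expect_false(map_to_annotation(mk(24000), genes, "G2")$valid)
  # right position, wrong expected gene
  expect_false(map_to_annotation(mk(6000), genes, "G2")$valid)
  expect_error(map_to_annotation(mk(6000), genes[0, ], "G1"), "empty")
})

test_that("planted validity classes are recovered exactly across seeds", {
  for (s in c(31, 32, 33)) {
    cfg <- sim_config(seed = s)
    gs <- generate_genome_and_probes(cfg, seed = s)
    v <- validate_probes(gs$manifest, gs$genome)
    m <- merge(v, gs$truth$planted_validity, by = "probe_id")
    expect_identical(m$valid, m$expected_valid)
    expect_identical(m$reason, m$expected_reason)
    # chosen hits sit at the planted design loci
    ok <- m$reason %in% c("PASS", "ANNOTATION_FAIL")
    expect_identical(m$start[ok], m$expected_start[ok])
    expect_identical(m$strand[ok], m$expected_strand[ok])
  }
})

test_that("verdicts are invariant to reverse-complementing the genome", {
  cfg <- sim_config(seed = 41)
  gs <- generate_genome_and_probes(cfg, seed = 41, n_per_class = 1)
  g <- gs$genome
  L <- nchar(g$chromosomes[[1]])
  rc <- vapply(g$chromosomes, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1))
  genes_rc <- g$genes
  genes_rc$start <- L - g$genes$end
  genes_rc$end <- L - g$genes$start
  genes_rc$strand <- ifelse(g$genes$strand == "+", "-", "+")
  genes_rc$tss <- ifelse(genes_rc$strand == "+", genes_rc$start,
                         genes_rc$end - 1L)
  g_rc <- genome_bundle(rc, genes_rc)
  v1 <- validate_probes(gs$manifest, g)
  v2 <- validate_probes(gs$manifest, g_rc)
  expect_identical(v1$valid, v2$valid)
  expect_identical(v1$reason, v2$reason)
})
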