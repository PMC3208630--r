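# Shared fixtures and independent oracles. Everything is generated in code;
# expensive shared computations are cached for the duration of the test run.

light_settings <- bcsvd_settings(n_iter = 600L, burn_in = 150L)

make_small_dataset <- function(seed = 3, n_probes = 300, n_differential = 20,
                               effect_size = 0.3, within_group_sd = 0.05,
                               ...) {
  cfg <- sim_config(n_control = 5, n_case = 7, n_probes = n_probes,
                    n_differential = n_differential,
                    effect_size = effect_size,
                    within_group_sd = within_group_sd, seed = seed, ...)
  list(cfg = cfg, data = suppressWarnings(generate_dataset(cfg)))
}

# Brute-force sliding-window alignment oracle, independent of align_probe's
# Biostrings path: scans every placement on both strands and counts
# substitutions directly.
oracle_align <- function(probe, chromosomes, max_mm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  pc <- strsplit(probe, "")[[1]]
  out <- list()
  for (cn in names(chromosomes)) {
    gc <- strsplit(chromosomes[[cn]], "")[[1]]
    L <- length(gc)
    if (L < 50) next
    n_win <- L - 49L
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pc else rev(unname(comp[pc]))
      mm <- integer(n_win)
      for (k in 1:50) mm <- mm + (gc[k:(n_win + k - 1)] != pat[k])
      for (s0 in which(mm <= max_mm)) {
        s <- s0 - 1L
        seg <- gc[(s + 1):(s + 50)]
        oriented <- if (strand == "+") seg else rev(unname(comp[seg]))
        mism <- pc != oriented | pc == "N"
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = s, strand = strand,
          mismatch_count = sum(mism), identity = (50 - sum(mism)) / 50,
          three_prime_anchor_ok = !mism[49] && !mism[50],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatch_count = integer(0),
                      identity = numeric(0),
                      three_prime_anchor_ok = logical(0)))
  o <- do.call(rbind, out)
  o <- o[order(o$mismatch_count, o$chrom, o$start, o$strand), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# One shared run of the synthetic infant-design replica: 5 controls vs 7
# cases, 163 strongly differential loci among 2163 probes, full permutation
# test, probe selection, and LOOCV on the selected set.
.fixture_cache <- new.env(parent = emptyenv())

infant_replica <- function() {
  if (!exists("infant", .fixture_cache)) {
    cfg <- sim_config(n_control = 5, n_case = 7, n_probes = 2163,
                      n_differential = 163, effect_size = 0.3,
                      within_group_sd = 0.05, seed = 1)
    ds <- suppressWarnings(generate_dataset(cfg))
    design <- standardize(ds$beta, ds$phenotypes$group)
    results <- permutation_pvalues(design, B = 99L, seed = 1)
    sig <- select_significant(results, 0.05)
    keep <- match(sig$probe_id, ds$beta$probe_ids)
    beta_sig <- beta_matrix(ds$beta$values[keep, , drop = FALSE],
                            sig$probe_id, ds$beta$sample_ids)
    cv <- loocv(beta_sig, ds$phenotypes$group, seed = 1)
    assign("infant", list(cfg = cfg, data = ds, results = results,
                          significant = sig, beta_sig = beta_sig,
                          loocv = cv), .fixture_cache)
  }
  get("infant", .fixture_cache)
}
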