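#' Classify PCOS-like phenotypes from a sample sheet
#'
#' Applies the study's clinical rules: menstrual cycles longer than 34 days
#' are intermittent/anovulatory (92% of normal female rhesus cycles fall in
#' 24-34 days); hyperandrogenism is serum testosterone at or above a
#' threshold (0.32 ng/ml, the control mean plus one SD in the reference
#' colony, or derived from the supplied controls); polycystic ovaries (PCO)
#' are 10 or more ~1-3 mm follicles per greatest ovarian diameter. Missing
#' measurements give missing labels.
#'
#' @param pheno data.frame with `sample_id`, `group`, `testosterone`,
#'   `cycle_length`, `follicle_count`.
#' @param t_threshold Testosterone cutoff in ng/ml (default 0.32). Pass
#'   `NULL` to derive it as mean + 1 SD of control testosterone.
#' @param cycle_threshold,follicle_threshold Rule cutoffs (defaults 34 days,
#'   10 follicles).
#' @return data.frame: `sample_id`, `cycle_status`
#'   (`"intermittent"`/`"normal"`), `hyperandrogenic`, `pco`; the threshold
#'   used is attached as attribute `t_threshold`.
#' @export
classify_phenotypes <- function(pheno, t_threshold = 0.32,
                                cycle_threshold = 34,
                                follicle_threshold = 10) {
  if (is.null(t_threshold)) {
    ctrl_t <- pheno$testosterone[pheno$group == "control"]
    ctrl_t <- ctrl_t[!is.na(ctrl_t)]
    if (length(ctrl_t) < 2)
      stop("no controls available to derive the testosterone threshold")
    t_threshold <- mean(ctrl_t) + stats::sd(ctrl_t)
  }
  out <- data.frame(
    sample_id = pheno$sample_id,
    cycle_status = ifelse(is.na(pheno$cycle_length), NA_character_,
                          ifelse(pheno$cycle_length > cycle_threshold,
                                 "intermittent", "normal")),
    hyperandrogenic = pheno$testosterone >= t_threshold,
    pco = pheno$follicle_count >= follicle_threshold,
    stringsAsFactors = FALSE)
  attr(out, "t_threshold") <- t_threshold
  out
}

#' Probe-wise linear regression of methylation on a phenotype
#'
#' Within the given sample subset (e.g. the PA animals only), each probe's
#' beta values are regressed on the phenotype by ordinary least squares,
#' reporting the slope, Pearson correlation R and two-sided slope-test p,
#' with Bonferroni and Benjamini-Hochberg corrections over the probes
#' actually tested.
#'
#' @param beta A [beta_matrix] at the probes of interest.
#' @param phenotype Named numeric vector (names = sample IDs) of phenotype
#'   values.
#' @param subset Character vector of sample IDs to use (mandatory; the study
#'   design tests cases and controls separately).
#' @param min_n Minimum non-missing pairs per probe (default 3).
#' @return data.frame: `probe_id`, `n`, `slope`, `r`, `p`, `p_bonferroni`,
#'   `q_bh`, plus a `skipped` data.frame attribute with reasons.
#' @export
phenotype_regression <- function(beta, phenotype, subset, min_n = 3) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (is.null(names(phenotype))) stop("phenotype must be named by sample ID")
  subset <- intersect(subset, beta$sample_ids)
  x_all <- phenotype[subset]
  rows <- list(); skipped <- list()
  for (j in seq_along(beta$probe_ids)) {
    yv <- beta$values[j, subset]
    keep <- !is.na(yv) & !is.na(x_all)
    x <- x_all[keep]; yy <- yv[keep]
    pid <- beta$probe_ids[j]
    if (sum(keep) < min_n) {
      skipped[[length(skipped) + 1L]] <- data.frame(probe_id = pid,
                                                    reason = "too_few_pairs")
      next
    }
    if (stats::sd(x) == 0) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        probe_id = pid, reason = "constant_phenotype")
      next
    }
    if (stats::sd(yy) == 0) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        probe_id = pid, reason = "constant_methylation")
      next
    }
    fit <- stats::lm(yy ~ x)
    co <- summary(fit)$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = pid, n = sum(keep), slope = co[2, 1],
      r = stats::cor(x, yy), p = co[2, 4], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(probe_id = character(0), n = integer(0),
                      slope = numeric(0), r = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), q_bh = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$p_bonferroni <- bonferroni(out$p, m = nrow(out))
    out$q_bh <- bh_fdr(out$p)
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(probe_id = character(0), reason = character(0))
  out
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise, for `m` tests.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param m Number of tests (must be at least `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  if (m < length(pvals)) stop("m must be >= length(pvals)")
  pmin(1, m * pvals)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control with enforced monotonicity (the
#' standard `p.adjust` BH construction).
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-set over-representation against a custom reference list
#'
#' Right-tailed Fisher's exact (hypergeometric tail) test of each set:
#' with `N` reference genes, a set of size `n_set` (after intersection with
#' the reference), an input list of size `n_list` and `k` hits,
#' p = P(X >= k) for X hypergeometric. The ratio column is `k / n_set`, the
#' fraction of the set covered by the input list. Input genes outside the
#' reference are dropped (and counted in the `dropped` attribute).
#'
#' @param input_genes Character vector of significant genes.
#' @param gene_sets Named list of character vectors.
#' @param reference_genes Character vector, e.g. every gene on the array.
#' @return data.frame: `set`, `k`, `n_set`, `n_list`, `n_reference`,
#'   `ratio`, `p`.
#' @export
enrichment <- function(input_genes, gene_sets, reference_genes) {
  reference_genes <- unique(reference_genes)
  if (length(reference_genes) == 0) stop("empty reference gene list")
  input_genes <- unique(input_genes)
  dropped <- setdiff(input_genes, reference_genes)
  input_genes <- intersect(input_genes, reference_genes)
  N <- length(reference_genes); n_list <- length(input_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), reference_genes)
    n_set <- length(set)
    k <- length(intersect(input_genes, set))
    p <- if (n_set == 0) NA_real_ else
      stats::phyper(k - 1, n_set, N - n_set, n_list, lower.tail = FALSE)
    data.frame(set = nm, k = k, n_set = n_set, n_list = n_list,
               n_reference = N,
               ratio = if (n_set > 0) k / n_set else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}
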