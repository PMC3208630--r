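#' Leave-one-out cross-validation of the fitted classifier
#'
#' For each sample in turn, the remaining samples are standardized, reduced
#' by SVD and fit with the Gibbs-sampled probit model at the given probe set;
#' the held-out sample is standardized with the training means/SDs, projected
#' onto the training loadings, and classified at posterior predictive
#' probability 0.5 (ties broken toward control). The probe set is fixed once
#' before LOOCV (selection is not repeated inside folds) unless the caller
#' re-selects per fold themselves.
#'
#' @param beta A [beta_matrix] restricted (by the caller) to the selected
#'   probes.
#' @param labels 0/1 or character labels (1 = case).
#' @param settings A [bcsvd_settings()].
#' @param seed Integer seed (per-fold seeds are derived by counter).
#' @param case_label Case label for character input.
#' @return List of class `loocv_result`: `predictions` (data.frame:
#'   `sample_id`, `truth`, `prob_case`, `predicted`, `flagged`),
#'   `sensitivity`, `specificity`, `confusion` (TP/FN/TN/FP).
#' @export
loocv <- function(beta, labels, settings = bcsvd_settings(), seed = 1L,
                  case_label = "PA") {
  stopifnot(inherits(beta, "beta_matrix"))
  y <- coerce_labels(labels, case_label)
  n <- length(y)
  if (nrow(beta$values) == 0) stop("selected probe set is empty")
  if (min(table(factor(y, levels = 0:1))) < 2)
    stop("need at least 2 samples per class")
  preds <- data.frame(sample_id = beta$sample_ids, truth = y,
                      prob_case = NA_real_, predicted = NA_integer_,
                      flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (min(table(factor(y_tr, levels = 0:1))) < 1) {
      preds$flagged[i] <- TRUE
      warning(sprintf("fold %d leaves a class empty; excluded", i))
      next
    }
    tr_vals <- beta$values[, -i, drop = FALSE]
    mu <- rowMeans(tr_vals)
    sds <- apply(tr_vals, 1, stats::sd)
    keep <- sds > 0
    tr_beta <- beta_matrix(tr_vals[keep, , drop = FALSE],
                           beta$probe_ids[keep], beta$sample_ids[-i])
    design <- standardize(tr_beta, y_tr)
    kept_ids <- design$probe_ids
    decomp <- svd_reduce(design)
    flip <- y_tr[1] == 1L
    y_fit <- if (flip) 1L - y_tr else y_tr
    draws <- gibbs_fit(decomp$scores, y_fit, settings,
                       seed = perm_seed(seed, i))
    idx <- match(kept_ids, beta$probe_ids)
    z_new <- (beta$values[idx, i] - mu[idx]) / sds[idx]
    scores_new <- matrix(z_new, nrow = 1) %*% decomp$loadings
    p_case <- predict_probit(draws, scores_new)
    if (flip) p_case <- 1 - p_case
    preds$prob_case[i] <- p_case
    preds$predicted[i] <- as.integer(p_case > 0.5)  # tie -> control
  }
  ok <- !preds$flagged
  tp <- sum(ok & preds$truth == 1 & preds$predicted == 1)
  fn <- sum(ok & preds$truth == 1 & preds$predicted == 0)
  tn <- sum(ok & preds$truth == 0 & preds$predicted == 0)
  fp <- sum(ok & preds$truth == 0 & preds$predicted == 1)
  structure(list(predictions = preds,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 confusion = c(TP = tp, FN = fn, TN = tn, FP = fp)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result: sensitivity %.1f%%, specificity %.1f%% (n = %d)\n",
              100 * x$sensitivity, 100 * x$specificity,
              nrow(x$predictions)))
  invisible(x)
}

#' Generalized likelihood ratio power
#'
#' Given -ln(lambda), where lambda is the likelihood ratio of the
#' intercept-only null model to the alternative, the deviance -2 ln(lambda)
#' is referred to a chi-square distribution with one degree of freedom:
#' power = 1 - Pr(chi2(1) >= -2 ln lambda).
#'
#' @param neg_ln_lambda Non-negative -ln(lambda).
#' @return List of class `power_result`: `neg_ln_lambda`, `deviance`,
#'   `power`.
#' @export
glr_power <- function(neg_ln_lambda) {
  if (neg_ln_lambda < 0) stop("neg_ln_lambda must be >= 0")
  deviance <- 2 * neg_ln_lambda
  structure(list(neg_ln_lambda = neg_ln_lambda, deviance = deviance,
                 power = stats::pchisq(deviance, df = 1)),
            class = "power_result")
}

#' GLR power from fitted log-likelihoods
#'
#' -ln(lambda) = loglik_alt - loglik_null for the intercept-only null versus
#' the model with all selected probes.
#'
#' @param loglik_null,loglik_alt Log-likelihoods with
#'   `loglik_alt >= loglik_null`.
#' @return A `power_result`, as [glr_power()].
#' @export
glr_from_fits <- function(loglik_null, loglik_alt) {
  if (loglik_alt < loglik_null)
    stop("loglik_alt must be >= loglik_null (likelihoods reversed?)")
  glr_power(loglik_alt - loglik_null)
}

#' Hierarchical clustering of samples at selected loci
#'
#' Agglomerative clustering of samples on Euclidean distance between their
#' methylation profiles with average linkage (the classic expression-matrix
#' viewer defaults), plus a flat k-group cut. Deterministic given input
#' order; ties merge lowest index first (the `hclust` convention).
#'
#' @param beta A [beta_matrix] at the significant loci.
#' @param k Number of flat clusters (default 2).
#' @param method Linkage (default `"average"`).
#' @return List of class `cluster_result`: `hclust`, `labels` (named flat
#'   assignments), `newick` (dendrogram as Newick text).
#' @export
hierarchical_cluster <- function(beta, k = 2, method = "average") {
  stopifnot(inherits(beta, "beta_matrix"))
  n <- ncol(beta$values)
  if (n < 2) stop("need at least 2 samples")
  if (k > n) stop("fewer samples than clusters requested")
  d <- stats::dist(t(beta$values), method = "euclidean")
  hc <- stats::hclust(d, method = method)
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "cluster_result")
}
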