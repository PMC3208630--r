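#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset), the methylated fraction of total locus
#' intensity, ranging from 0 (fully unmethylated) to 1 (fully methylated).
#' Negative background-corrected intensities are clamped to 0 before the
#' ratio; a zero denominator yields `NA` rather than an error.
#'
#' @param M,U Numeric matrices or vectors of methylated / unmethylated
#'   intensities (conformable).
#' @param offset Optional denominator offset (default 0).
#' @return beta values with the shape of `M`, in `[0, 1]` or `NA`.
#' @export
compute_beta <- function(M, U, offset = 0) {
  stopifnot(offset >= 0)
  M <- pmax(M, 0); U <- pmax(U, 0)
  denom <- M + U + offset
  out <- ifelse(denom > 0, M / denom, NA_real_)
  if (is.matrix(M)) out <- matrix(out, nrow(M), ncol(M), dimnames = dimnames(M))
  out
}

#' Filter probes on detection p-values
#'
#' A probe is retained iff its detection p-value (probability that its signal
#' is indistinguishable from background) is below `p_threshold` in at least
#' `min_sample_fraction` of samples.
#'
#' @param detection_p Probes x samples matrix of detection p-values.
#' @param p_threshold Strict detection cutoff (default 0.01).
#' @param min_sample_fraction Fraction of samples that must pass (default 1,
#'   i.e. every sample).
#' @return List: `pass` (logical probe mask) and `report` (class `qc_report`
#'   with `probes_tested`, `probes_passed`, `pass_rate`).
#' @export
detection_filter <- function(detection_p, p_threshold = 0.01,
                             min_sample_fraction = 1.0) {
  detection_p <- as.matrix(detection_p)
  if (length(detection_p) == 0) stop("empty detection matrix")
  stopifnot(all(detection_p >= 0 & detection_p <= 1, na.rm = TRUE))
  frac_ok <- rowMeans(detection_p < p_threshold)
  pass <- frac_ok >= min_sample_fraction
  report <- structure(list(probes_tested = nrow(detection_p),
                           probes_passed = sum(pass),
                           pass_rate = mean(pass)), class = "qc_report")
  list(pass = pass, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d / %d probes passed (%.1f%%)\n",
              x$probes_passed, x$probes_tested, 100 * x$pass_rate))
  invisible(x)
}

#' Principal component screen of samples
#'
#' Samples-in-rows PCA of the beta matrix after per-probe mean imputation of
#' missing values. Used to spot outlying arrays and technical structure; by
#' default the top 5 components are retained.
#'
#' @param beta A [beta_matrix].
#' @param n_components Components to keep (truncated with a warning if it
#'   exceeds `n_samples - 1`).
#' @return List: `scores` (samples x k, centered), `eigenvalues`
#'   (non-increasing), `prop_var`.
#' @export
pca_screen <- function(beta, n_components = 5) {
  stopifnot(inherits(beta, "beta_matrix"))
  X <- t(beta$values)                      # samples x probes
  if (nrow(X) < 2) stop("need at least 2 samples")
  for (j in which(colSums(is.na(X)) > 0)) {
    mu <- mean(X[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    X[is.na(X[, j]), j] <- mu
  }
  kmax <- nrow(X) - 1L
  if (n_components > kmax) {
    warning(sprintf("n_components truncated to %d", kmax))
    n_components <- kmax
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       eigenvalues = ev[seq_len(k)],
       prop_var = ev[seq_len(k)] / sum(ev))
}

#' Flag outlying samples on PC scores
#'
#' A sample is flagged iff its absolute score exceeds `z_threshold` standard
#' deviations of that component's scores, on any retained component.
#' Zero-variance components are skipped.
#'
#' @param pc_scores Samples x components score matrix from [pca_screen()].
#' @param z_threshold SD multiple (default 3).
#' @return Named logical vector of per-sample flags.
#' @export
outlier_flag <- function(pc_scores, z_threshold = 3) {
  pc_scores <- as.matrix(pc_scores)
  if (nrow(pc_scores) < 3) stop("need at least 3 samples")
  flags <- rep(FALSE, nrow(pc_scores))
  for (j in seq_len(ncol(pc_scores))) {
    s <- stats::sd(pc_scores[, j])
    if (!is.finite(s) || s == 0) next
    flags <- flags | abs(pc_scores[, j]) > z_threshold * s
  }
  stats::setNames(flags, rownames(pc_scores))
}

#' Screen principal components against technical covariates
#'
#' For each (component, covariate) pair: continuous covariates are tested by
#' ordinary least squares of the PC score on the covariate (slope t-test);
#' nominal covariates by a likelihood-ratio test of a logistic (two levels)
#' or multinomial (more levels) regression of the covariate on the PC score.
#' Perfect separation is reported via the `separation` flag together with the
#' monotone-limit LRT p-value rather than an error. Constant covariates give
#' `NA`.
#'
#' @param pc_scores Samples x components matrix.
#' @param covariates data.frame of per-sample covariates (rows aligned with
#'   `pc_scores`); factors/characters are nominal, numerics continuous.
#' @return data.frame: `component`, `covariate`, `type`, `p`, `separation`.
#' @export
covariate_screen <- function(pc_scores, covariates) {
  pc_scores <- as.matrix(pc_scores)
  stopifnot(nrow(pc_scores) == nrow(covariates))
  comp_names <- colnames(pc_scores)
  if (is.null(comp_names)) comp_names <- sprintf("PC%d", seq_len(ncol(pc_scores)))
  out <- list()
  for (j in seq_len(ncol(pc_scores))) {
    pc <- pc_scores[, j]
    for (v in names(covariates)) {
      x <- covariates[[v]]
      nominal <- is.factor(x) || is.character(x) || is.logical(x)
      keep <- !is.na(x) & !is.na(pc)
      p <- NA_real_; sep <- FALSE
      if (sum(keep) >= 3 && length(unique(x[keep])) > 1) {
        if (!nominal) {
          fit <- stats::lm(pc[keep] ~ x[keep])
          p <- summary(fit)$coefficients[2, 4]
        } else {
          f <- factor(x[keep])
          if (nlevels(f) == 2) {
            y01 <- as.integer(f) - 1L
            fit <- suppressWarnings(
              stats::glm(y01 ~ pc[keep], family = stats::binomial()))
            p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                               lower.tail = FALSE)
            mu <- stats::fitted(fit)
            sep <- all(abs(mu - y01) < 1e-6)
          } else {
            null_fit <- nnet::multinom(f ~ 1, trace = FALSE)
            alt_fit <- suppressWarnings(
              nnet::multinom(f ~ pc[keep], trace = FALSE))
            dev <- null_fit$deviance - alt_fit$deviance
            p <- stats::pchisq(max(dev, 0), df = nlevels(f) - 1,
                               lower.tail = FALSE)
            pr <- stats::fitted(alt_fit)
            sep <- all(apply(pr, 1, max) > 1 - 1e-6)
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        component = comp_names[j], covariate = v,
        type = if (nominal) "nominal" else "continuous",
        p = p, separation = sep, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
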