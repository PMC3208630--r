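# Bayesian classification with SVD dimension reduction (BCSVD).
#
# The test treats the full standardized probe matrix as the design matrix of
# a binary classification model, reduces it to its SVD score space (rank <=
# n - 1 after centering), fits a Bayesian probit model by Gibbs sampling with
# latent-variable data augmentation, back-transforms the reduced coefficients
# to probe space through the SVD loadings, and assigns each probe a
# permutation empirical p-value. All probes are tested simultaneously in a
# single model rather than one at a time.

#' Sampler settings for the BCSVD model
#'
#' @param n_iter,burn_in Gibbs iterations / burn-in for the observed-label
#'   fit.
#' @param perm_n_iter,perm_burn_in Settings used inside each permutation
#'   refit. These default to the observed-fit settings: the permutation test
#'   compares the observed statistic with statistics computed by the
#'   identical procedure under permuted labels, so unequal chain lengths
#'   would break the exchangeability the empirical p-value relies on (the
#'   Monte Carlo dispersion of the statistic depends on the chain length).
#' @param prior_variance Prior variance tau^2 of the reduced-space
#'   coefficients, gamma ~ N(0, tau^2 I).
#' @param intercept_prior_variance Prior variance of the intercept.
#' @return A list of class `bcsvd_settings`.
#' @export
bcsvd_settings <- function(n_iter = 2000L, burn_in = 500L,
                           perm_n_iter = n_iter, perm_burn_in = burn_in,
                           prior_variance = 100, intercept_prior_variance = 100) {
  stopifnot(n_iter > burn_in, perm_n_iter > perm_burn_in,
            prior_variance > 0, intercept_prior_variance > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 perm_n_iter = as.integer(perm_n_iter),
                 perm_burn_in = as.integer(perm_burn_in),
                 prior_variance = prior_variance,
                 intercept_prior_variance = intercept_prior_variance),
            class = "bcsvd_settings")
}

coerce_labels <- function(labels, case_label = "PA") {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == case_label)
}

#' Standardize a beta matrix into a design matrix
#'
#' Transposes to samples x probes and centers/scales each probe to mean 0,
#' variance 1. Zero-variance probes cannot be standardized; they are dropped
#' and reported.
#'
#' @param beta A [beta_matrix] (no missing values; impute upstream).
#' @param labels Class labels: 0/1 numeric (1 = case) or character/factor
#'   matched against `case_label`.
#' @param case_label Label treated as the case class (default `"PA"`).
#' @return List of class `bcsvd_design`: `Z` (samples x probes, standardized),
#'   `y`, `probe_ids`, `dropped_probes`, `sample_ids`.
#' @export
standardize <- function(beta, labels, case_label = "PA") {
  stopifnot(inherits(beta, "beta_matrix"))
  y <- coerce_labels(labels, case_label)
  if (length(y) != length(beta$sample_ids))
    stop("labels must align with samples")
  if (min(table(factor(y, levels = 0:1))) < 2)
    stop("need at least 2 samples in each class")
  X <- t(beta$values)
  if (anyNA(X)) stop("missing beta values; impute before standardizing")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  dropped <- beta$probe_ids[!keep]
  Z <- scale(X[, keep, drop = FALSE])
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  structure(list(Z = Z, y = y, probe_ids = beta$probe_ids[keep],
                 dropped_probes = dropped, sample_ids = beta$sample_ids),
            class = "bcsvd_design")
}

#' SVD reduction of a standardized design matrix
#'
#' Retains every singular value above `tol`; after per-probe centering the
#' rank is at most `n_samples - 1`.
#'
#' @param design A `bcsvd_design` from [standardize()].
#' @param tol Singular-value retention threshold (default 1e-10).
#' @return List of class `svd_decomposition`: `scores` (samples x r, = U D),
#'   `loadings` (probes x r, = V), `singular_values`, `r`.
#' @export
svd_reduce <- function(design, tol = 1e-10) {
  stopifnot(inherits(design, "bcsvd_design"))
  Z <- design$Z
  if (all(Z == 0)) stop("all-zero design matrix")
  s <- svd(Z)
  r <- sum(s$d > tol)
  if (r == 0) stop("no singular values above tolerance")
  idx <- seq_len(r)
  structure(list(scores = s$u[, idx, drop = FALSE] %*% diag(s$d[idx], r, r),
                 loadings = s$v[, idx, drop = FALSE],
                 singular_values = s$d[idx], r = r,
                 probe_ids = design$probe_ids),
            class = "svd_decomposition")
}

# Core Gibbs sweep for the augmented probit model:
#   u_i ~ N(x_i' theta, 1), y_i = 1[u_i > 0], theta ~ N(0, diag(1/prec)).
# The conditional for theta is Gaussian with fixed precision A = X'X + P, so
# its Cholesky factor is computed once.
gibbs_probit <- function(X, y, prior_prec, n_iter, burn_in) {
  n <- nrow(X); k <- ncol(X)
  A <- crossprod(X) + diag(prior_prec, k, k)
  R <- chol(A)
  theta <- numeric(k)
  keep <- n_iter - burn_in
  draws <- matrix(NA_real_, keep, k)
  eps <- 1e-12
  is_case <- y == 1
  for (t in seq_len(n_iter)) {
    eta <- drop(X %*% theta)
    p0 <- stats::pnorm(-eta)            # mass below the truncation point
    v <- stats::runif(n)
    q <- ifelse(is_case, p0 + v * (1 - p0), v * p0)
    u <- eta + stats::qnorm(pmin(1 - eps, pmax(eps, q)))
    b <- crossprod(X, u)
    m <- backsolve(R, backsolve(R, b, transpose = TRUE))
    theta <- drop(m + backsolve(R, stats::rnorm(k)))
    if (t > burn_in) draws[t - burn_in, ] <- theta
  }
  draws
}

#' Fit the Bayesian probit model on SVD scores by Gibbs sampling
#'
#' Latent-variable data augmentation: u_i ~ N(mu + s_i' gamma, 1) with
#' y_i = 1 iff u_i > 0, gamma ~ N(0, tau^2 I), mu ~ N(0, 100). All
#' conditionals are conjugate. A fixed seed gives identical draws.
#'
#' @param scores Samples x r score matrix from [svd_reduce()].
#' @param y Binary 0/1 labels.
#' @param settings A [bcsvd_settings()].
#' @param seed Integer seed.
#' @param permutation_mode Use the cheaper permutation iteration counts.
#' @return List of class `posterior_draws`: `gamma` (draws x r), `intercept`,
#'   `settings`, `seed`.
#' @export
gibbs_fit <- function(scores, y, settings = bcsvd_settings(), seed = 1L,
                      permutation_mode = FALSE) {
  scores <- as.matrix(scores)
  y <- coerce_labels(y)
  if (nrow(scores) != length(y)) stop("scores/labels mismatch")
  if (any(!is.finite(scores))) stop("degenerate scores")
  n_iter <- if (permutation_mode) settings$perm_n_iter else settings$n_iter
  burn_in <- if (permutation_mode) settings$perm_burn_in else settings$burn_in
  X <- cbind(1, scores)
  prior_prec <- c(1 / settings$intercept_prior_variance,
                  rep(1 / settings$prior_variance, ncol(scores)))
  draws <- withr::with_seed(as.integer(seed),
                            gibbs_probit(X, y, prior_prec, n_iter, burn_in))
  structure(list(gamma = draws[, -1, drop = FALSE], intercept = draws[, 1],
                 settings = settings, seed = as.integer(seed),
                 n_iter = n_iter, burn_in = burn_in),
            class = "posterior_draws")
}

#' Probe-space statistics from posterior draws
#'
#' Back-transforms the reduced coefficients to probe space: the statistic of
#' probe j is the posterior mean of b = V gamma at coordinate j. Because the
#' design matrix is standardized, these effects are already on a common
#' scale across probes. A positive statistic means higher methylation
#' predicts the case class (hypermethylation in cases).
#'
#' With `standardized = TRUE` the posterior mean is divided by the per-probe
#' posterior SD of b instead. This variant is deliberately not the default:
#' when the classes are strongly separated the probit posterior along the
#' discriminant direction is limited by the prior rather than the
#' likelihood, so mean and SD grow together and the ratio discards the very
#' magnitude signal that distinguishes the observed labels from
#' permutations.
#'
#' @param draws A `posterior_draws` from [gibbs_fit()].
#' @param decomp An `svd_decomposition` from [svd_reduce()].
#' @param standardized Divide by the per-probe posterior SD.
#' @return Named numeric vector of per-probe statistics.
#' @export
probe_statistics <- function(draws, decomp, standardized = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(decomp, "svd_decomposition"))
  if (ncol(draws$gamma) != decomp$r) stop("dimension mismatch")
  B <- decomp$loadings %*% t(draws$gamma)   # probes x draws
  nd <- ncol(B)
  m <- rowMeans(B)
  if (standardized) {
    s <- sqrt(pmax(0, (rowSums(B^2) - nd * m^2) / (nd - 1)))
    m <- ifelse(s > 0, m / s, 0)
  }
  stats::setNames(m, decomp$probe_ids)
}

# Canonicalized statistic: the probit augmentation model is exactly symmetric
# under label complement (theta -> -theta), so labels are recoded to make
# sample 1 a control before fitting and the statistic sign restored after.
# This makes |stat|, and hence permutation p-values, exactly invariant to
# 0<->1 relabeling.
canonical_stat <- function(decomp, y, settings, seed, permutation_mode) {
  flip <- y[1] == 1L
  yc <- if (flip) 1L - y else y
  draws <- gibbs_fit(decomp$scores, yc, settings, seed, permutation_mode)
  st <- probe_statistics(draws, decomp)
  list(stat = if (flip) -st else st, draws = draws, flipped = flip)
}

perm_seed <- function(master, b) {
  as.integer((as.double(master) %% 1e6 * 1000003 + b) %% 2147483629) + 1L
}

#' Permutation empirical p-values for all probes
#'
#' Computes the observed probe statistics, then refits the Gibbs sampler
#' under `B` label permutations (the standardization and SVD are label-free
#' and reused). Each probe's empirical p is per-probe with the add-one
#' correction: p_j = (1 + #\{b : |stat_bj| >= |stat_j|\}) / (B + 1). With the
#' `pooled = TRUE` flag the permutation statistics of all probes form one
#' shared reference distribution instead. If `B` reaches the number of
#' distinct label assignments, those are enumerated exhaustively.
#'
#' @param design A `bcsvd_design` from [standardize()].
#' @param B Number of permutations (>= 19).
#' @param seed Master seed; per-permutation seeds are derived by a counter
#'   scheme so earlier permutations are unchanged when `B` grows.
#' @param settings A [bcsvd_settings()].
#' @param pooled Use a pooled reference distribution instead of per-probe.
#' @return data.frame of class `probe_test_result`: `probe_id`, `statistic`,
#'   `direction` (`"hyper"`/`"hypo"` in cases vs controls), `empirical_p`;
#'   attributes `B`, `exhaustive`, `rank`.
#' @export
permutation_pvalues <- function(design, B = 99L, seed = 1L,
                                settings = bcsvd_settings(), pooled = FALSE) {
  stopifnot(inherits(design, "bcsvd_design"))
  B <- as.integer(B)
  if (B < 19L) stop("B must be at least 19")
  y <- design$y; n <- length(y); n1 <- sum(y)
  decomp <- svd_reduce(design)
  obs <- canonical_stat(decomp, y, settings, seed = perm_seed(seed, 0L),
                        permutation_mode = FALSE)$stat

  n_assign <- choose(n, n1)
  exhaustive <- B >= n_assign - 1
  if (exhaustive) {
    # Enumerate subsets of the minority-class size; the observed assignment
    # is identified by a label-swap-invariant representative (for an equal
    # split, the side containing sample 1) so that relabeling 0<->1 gives
    # bit-identical p-values.
    m <- min(n1, n - n1)
    combos <- utils::combn(n, m)
    obs_rep <- if (n1 < n - n1) which(y == 1L)
      else if (n1 > n - n1) which(y == 0L)
      else { side <- which(y == y[1]); sort(side) }
    perm_cols <- Filter(function(ci) !identical(combos[, ci], obs_rep),
                        seq_len(ncol(combos)))
    B_eff <- length(perm_cols)
    perm_stats <- matrix(NA_real_, length(obs), B_eff)
    for (b in seq_len(B_eff)) {
      ci <- perm_cols[[b]]
      yb <- integer(n)
      if (n1 <= n - n1) yb[combos[, ci]] <- 1L
      else yb[-combos[, ci]] <- 1L
      perm_stats[, b] <- withr::with_seed(perm_seed(seed, ci), {
        canonical_stat(decomp, yb, settings,
                       seed = sample.int(2147483647L, 1),
                       permutation_mode = TRUE)$stat
      })
    }
  } else {
    B_eff <- B
    perm_stats <- matrix(NA_real_, length(obs), B_eff)
    for (b in seq_len(B_eff)) {
      perm_stats[, b] <- withr::with_seed(perm_seed(seed, b), {
        yb <- sample(y)
        canonical_stat(decomp, yb, settings,
                       seed = sample.int(2147483647L, 1),
                       permutation_mode = TRUE)$stat
      })
    }
  }

  abs_obs <- abs(obs)
  if (pooled) {
    pool <- sort(abs(as.vector(perm_stats)))
    exceed <- length(pool) - findInterval(abs_obs - 1e-15, pool)
    emp_p <- (1 + exceed) / (length(pool) + 1)
  } else {
    exceed <- rowSums(abs(perm_stats) >= abs_obs)
    emp_p <- (1 + exceed) / (B_eff + 1)
  }

  res <- data.frame(probe_id = names(obs), statistic = unname(obs),
                    direction = ifelse(obs >= 0, "hyper", "hypo"),
                    empirical_p = emp_p, stringsAsFactors = FALSE)
  class(res) <- c("probe_test_result", "data.frame")
  attr(res, "B") <- B_eff
  attr(res, "exhaustive") <- exhaustive
  attr(res, "rank") <- decomp$r
  attr(res, "dropped_probes") <- design$dropped_probes
  res
}

#' Select significantly differentially methylated probes
#'
#' Probes with empirical p strictly below `alpha`, keeping the statistic sign
#' as the hyper/hypomethylation direction in cases versus controls.
#'
#' @param results A `probe_test_result` from [permutation_pvalues()].
#' @param alpha Significance level (default 0.05).
#' @return Subset of `results` rows.
#' @export
select_significant <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), "empirical_p" %in% names(results))
  results[results$empirical_p < alpha, , drop = FALSE]
}

#' Probit log-likelihood
#'
#' @param X Design matrix (with intercept column).
#' @param y Binary 0/1 labels.
#' @param theta Coefficient vector.
#' @return Scalar log-likelihood.
#' @export
probit_loglik <- function(X, y, theta) {
  eta <- drop(as.matrix(X) %*% theta)
  sum(stats::pnorm((2 * y - 1) * eta, log.p = TRUE))
}

#' Posterior predictive case probability
#'
#' Averages the probit link over posterior draws at new score rows.
#'
#' @param draws A `posterior_draws`.
#' @param scores_new Matrix (rows = new samples) of reduced-space scores.
#' @return Vector of predictive probabilities of the case class.
#' @export
predict_probit <- function(draws, scores_new) {
  scores_new <- matrix(scores_new, ncol = ncol(draws$gamma))
  eta <- outer(rep(1, nrow(scores_new)), draws$intercept) +
    scores_new %*% t(draws$gamma)
  rowMeans(stats::pnorm(eta))
}
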