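make_design <- function(seed = 1, n = 12, p = 40, n_case = 7) {
  set.seed(seed)
  vals <- matrix(runif(p * n, 0.2, 0.8), p, n,
                 dimnames = list(sprintf("p%03d", 1:p), sprintf("s%02d", 1:n)))
  labels <- rep(c(0, 1), c(n - n_case, n_case))
  list(beta = beta_matrix(vals), labels = labels)
}

test_that("standardize centers, scales, and drops constant probes", {
  d <- make_design()
  d$beta$values[3, ] <- 0.5              # constant probe
  design <- standardize(d$beta, d$labels)
  expect_equal(design$dropped_probes, "p003")
  expect_equal(ncol(design$Z), 39)
  expect_lt(max(abs(colMeans(design$Z))), 1e-8)
  expect_lt(max(abs(apply(design$Z, 2, sd) - 1)), 1e-6)
  expect_error(standardize(d$beta, rep(c(0, 1), c(1, 11))), "2 samples")
})

test_that("svd_reduce bounds the rank and reconstructs the design exactly", {
  d <- make_design(n = 12, p = 200)
  design <- standardize(d$beta, d$labels)
  dec <- svd_reduce(design)
  expect_lte(dec$r, 11)                   # centering rank bound
  recon <- dec$scores %*% t(dec$loadings)
  expect_lt(max(abs(design$Z - recon)), 1e-8)
  expect_true(all(diff(dec$singular_values) <= 1e-12))
  expect_lt(max(abs(crossprod(dec$loadings) - diag(dec$r))), 1e-8)
  # singular values match the eigendecomposition of Z Z^T
  ev <- eigen(tcrossprod(design$Z), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(dec$singular_values, sqrt(pmax(0, ev[seq_len(dec$r)])),
               tolerance = 1e-8)
  # rank-1 planted matrix
  u <- rnorm(12); v <- rnorm(5)
  z1 <- scale(u %*% t(v))
  d1 <- structure(list(Z = z1, y = d$labels, probe_ids = paste0("q", 1:5),
                       dropped_probes = character(0)),
                  class = "bcsvd_design")
  expect_equal(svd_reduce(d1)$r, 1)
})

test_that("gibbs_fit is seed-deterministic with null posteriors centered at zero", {
  d <- make_design(seed = 2)
  design <- standardize(d$beta, d$labels)
  dec <- svd_reduce(design)
  a <- gibbs_fit(dec$scores, design$y, light_settings, seed = 5)
  b <- gibbs_fit(dec$scores, design$y, light_settings, seed = 5)
  expect_identical(a$gamma, b$gamma)
  expect_identical(a$intercept, b$intercept)
  expect_equal(nrow(a$gamma), 450)        # n_iter - burn_in
  # null check: with labels independent of the scores, posterior means
  # average to zero over repeated label draws (label-complement symmetry)
  long <- bcsvd_settings(n_iter = 700, burn_in = 200, prior_variance = 1)
  pm <- vapply(1:40, function(i) {
    y <- withr::with_seed(100 + i, sample(design$y))
    dr <- gibbs_fit(dec$scores[, 1:3, drop = FALSE], y, long, seed = 200 + i)
    colMeans(dr$gamma)
  }, numeric(3))
  for (k in 1:3) {
    se <- sd(pm[k, ]) / sqrt(ncol(pm))
    expect_lt(abs(mean(pm[k, ])), 3 * se + 0.01)
  }
})

test_that("a perfectly separating 1-D score yields an almost surely one-signed posterior", {
  scores <- matrix(c(-3, -2.5, -2, -1.5, 2, 2.5, 3, 3.5), ncol = 1)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  dr <- gibbs_fit(scores, y, bcsvd_settings(n_iter = 3000, burn_in = 500),
                  seed = 3)
  expect_gt(mean(dr$gamma[, 1] > 0), 0.99)
})

test_that("probe statistics have the contract shape and find a planted probe", {
  d <- make_design(seed = 4, n = 12, p = 200)
  # plant one strongly differential probe (tight within-group spread)
  set.seed(40)
  d$beta$values[7, ] <- pmin(1, pmax(0, ifelse(d$labels == 1, 0.85, 0.15) +
                                       rnorm(12, sd = 0.03)))
  design <- standardize(d$beta, d$labels)
  dec <- svd_reduce(design)
  dr <- gibbs_fit(dec$scores, design$y, light_settings, seed = 2)
  st <- probe_statistics(dr, dec)
  expect_length(st, 200)
  expect_identical(names(st), design$probe_ids)
  expect_equal(names(which.max(abs(st))), "p007")
  expect_gt(st[["p007"]], 0)              # hypermethylated in cases
  # degenerate draws give all-zero statistics
  dr0 <- dr; dr0$gamma[] <- 0
  expect_true(all(probe_statistics(dr0, dec) == 0))
  st_std <- probe_statistics(dr, dec, standardized = TRUE)
  expect_identical(sign(st_std[abs(st) > 1e-8]), sign(st[abs(st) > 1e-8]))
})

test_that("reduced-rank fit preserves the probit likelihood of the full model", {
  d <- make_design(seed = 6, n = 12, p = 8)   # p < n, full column rank
  design <- standardize(d$beta, d$labels)
  dec <- svd_reduce(design)
  set.seed(1)
  for (rep in 1:5) {
    gamma <- rnorm(dec$r); mu <- rnorm(1)
    beta_probe <- dec$loadings %*% gamma
    ll_scores <- probit_loglik(cbind(1, dec$scores), design$y, c(mu, gamma))
    ll_probes <- probit_loglik(cbind(1, design$Z), design$y,
                               c(mu, beta_probe))
    expect_equal(ll_scores, ll_probes, tolerance = 1e-6)
  }
})

test_that("permutation p-values respect the add-one floor and significance contract", {
  set.seed(3)
  n <- 12; p <- 80
  vals <- matrix(runif(p * n, 0.3, 0.7), p, n,
                 dimnames = list(sprintf("cg%05d", 1:p), sprintf("s%02d", 1:n)))
  y <- rep(c(0, 1), c(5, 7))
  # one perfectly separating probe
  vals[1, ] <- ifelse(y == 1, 0.9, 0.1) + rnorm(n, sd = 0.005)
  design <- standardize(beta_matrix(vals), y)
  res <- permutation_pvalues(design, B = 49, seed = 7,
                             settings = light_settings)
  expect_s3_class(res, "probe_test_result")
  expect_true(all(res$empirical_p >= 1 / 50))
  expect_true(all(res$empirical_p <= 1))
  expect_identical(res$direction, ifelse(res$statistic >= 0, "hyper", "hypo"))
  # the separating probe sits on the add-one floor and is selected
  expect_equal(res$empirical_p[res$probe_id == "cg00001"], 1 / 50)
  sig <- select_significant(res, alpha = 0.05)
  expect_true("cg00001" %in% sig$probe_id)
  expect_identical(nrow(select_significant(res, alpha = 0)), 0L)
  all1 <- res; all1$empirical_p <- 1
  expect_identical(nrow(select_significant(all1)), 0L)
  expect_error(permutation_pvalues(design, B = 10), "at least 19")
})

test_that("permutation p-values are invariant to 0/1 relabeling", {
  fx <- make_small_dataset(seed = 12, n_probes = 60, n_differential = 4)
  g <- fx$data$phenotypes$group
  d1 <- standardize(fx$data$beta, g)
  d2 <- standardize(fx$data$beta, ifelse(g == "PA", "control", "PA"))
  r1 <- permutation_pvalues(d1, B = 29, seed = 5, settings = light_settings)
  r2 <- permutation_pvalues(d2, B = 29, seed = 5, settings = light_settings)
  expect_identical(r1$empirical_p, r2$empirical_p)
  expect_equal(r1$statistic, -r2$statistic)
})

test_that("small designs enumerate all distinct label assignments exhaustively", {
  set.seed(8)
  vals <- matrix(runif(6 * 30, 0.2, 0.8), 30, 6,
                 dimnames = list(sprintf("p%02d", 1:30), sprintf("s%d", 1:6)))
  vals[1, 4:6] <- pmin(1, vals[1, 4:6] + 0.5)   # separating probe
  y <- c(0, 0, 0, 1, 1, 1)
  design <- standardize(beta_matrix(vals), y)
  res <- permutation_pvalues(design, B = 99, seed = 2,
                             settings = light_settings)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "B"), choose(6, 3) - 1)   # 19 of 20 assignments
  expect_true(all(abs(res$empirical_p * 20 - round(res$empirical_p * 20)) <
                    1e-12))
  expect_equal(res$empirical_p[res$probe_id == "p01"], 1 / 20)
  res_again <- permutation_pvalues(design, B = 99, seed = 2,
                                   settings = light_settings)
  expect_identical(res$empirical_p, res_again$empirical_p)
})

test_that("growing B keeps earlier permutations fixed (counter seed scheme)", {
  fx <- make_small_dataset(seed = 14, n_probes = 40, n_differential = 2)
  design <- standardize(fx$data$beta, fx$data$phenotypes$group)
  r1 <- permutation_pvalues(design, B = 19, seed = 3, settings = light_settings)
  r2 <- permutation_pvalues(design, B = 29, seed = 3, settings = light_settings)
  # counts at the shared 19 permutations agree: p2*(30) - p1*(20) counts only
  # the 10 new permutations, so it must lie in [0, 10]
  extra <- r2$empirical_p * 30 - r1$empirical_p * 20
  expect_true(all(extra >= -1e-9 & extra <= 10 + 1e-9))
})
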