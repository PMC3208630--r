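test_that("phenotype rules apply the published cutoffs at their boundaries", {
  ph <- data.frame(sample_id = sprintf("s%d", 1:6),
                   group = c("control", "control", "PA", "PA", "PA", "PA"),
                   testosterone = c(0.10, 0.20, 0.32, 0.31, NA, 0.48),
                   cycle_length = c(26, 28, 43, 34, 35, NA),
                   follicle_count = c(3, 4, 10, 9, NA, 12))
  lab <- classify_phenotypes(ph)
  expect_equal(lab$cycle_status,
               c("normal", "normal", "intermittent", "normal",
                 "intermittent", NA))
  expect_equal(lab$hyperandrogenic, c(FALSE, FALSE, TRUE, FALSE, NA, TRUE))
  expect_equal(lab$pco, c(FALSE, FALSE, TRUE, FALSE, NA, TRUE))
  expect_equal(attr(lab, "t_threshold"), 0.32)
  # derived threshold: control mean + 1 SD
  lab2 <- classify_phenotypes(ph, t_threshold = NULL)
  expect_equal(attr(lab2, "t_threshold"), 0.15 + sd(c(0.1, 0.2)))
  expect_error(classify_phenotypes(ph[ph$group == "PA", ],
                                   t_threshold = NULL), "no controls")
})

test_that("probe-wise regression recovers exact and planted relationships", {
  testo <- c(s1 = 0.1, s2 = 0.2, s3 = 0.3, s4 = 0.4, s5 = 0.5, s6 = 0.6,
             s7 = 0.7)
  vals <- rbind(p_exact = 0.1 + 0.8 * testo,
                p_flat = rep(0.5, 7))
  beta <- beta_matrix(vals, sample_ids = names(testo))
  res <- suppressWarnings(phenotype_regression(beta, testo, names(testo)))
  row <- res[res$probe_id == "p_exact", ]
  expect_equal(row$r, 1.0)
  expect_lt(row$p, 1e-10)
  expect_equal(row$slope, 0.8)
  expect_false("p_flat" %in% res$probe_id)      # constant probe skipped
  expect_equal(attr(res, "skipped")$reason, "constant_methylation")
  # antisymmetry: negating the phenotype flips R and the slope sign
  res_neg <- suppressWarnings(phenotype_regression(beta, -testo, names(testo)))
  expect_equal(res_neg[res_neg$probe_id == "p_exact", "r"], -1.0)
  # corrections: bonferroni = m*p capped, q >= p
  expect_equal(res$p_bonferroni, pmin(1, nrow(res) * res$p))
  expect_true(all(res$q_bh >= res$p - 1e-15))
})

test_that("planted regression slopes are recovered within 3 standard errors", {
  hits <- 0
  for (s in 1:100) {
    set.seed(700 + s)
    x <- runif(7, 0, 0.6)
    yv <- pmin(1, pmax(0, 0.2 + 0.5 * x + rnorm(7, sd = 0.02)))
    fit <- summary(lm(yv ~ x))$coefficients
    if (abs(fit[2, 1] - 0.5) < 3 * fit[2, 2]) hits <- hits + 1
  }
  b <- beta_matrix(matrix(pmin(1, pmax(0, 0.2 + 0.5 * seq(0, 0.6, 0.1) +
                                         c(.01, -.01, .02, 0, -.02, .01, 0))),
                          1, 7, dimnames = list("p1", paste0("s", 1:7))))
  x <- setNames(seq(0, 0.6, 0.1), paste0("s", 1:7))
  res <- phenotype_regression(b, x, names(x))
  expect_lt(abs(res$slope - 0.5), 0.1)
  expect_gte(hits, 97)
})

test_that("null methylation-phenotype regressions are calibrated", {
  set.seed(81)
  pvals <- replicate(200, {
    x <- setNames(runif(7), paste0("s", 1:7))
    b <- beta_matrix(matrix(runif(7), 1, 7,
                            dimnames = list("p1", paste0("s", 1:7))))
    phenotype_regression(b, x, names(x))$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.045)
})

test_that("bonferroni follows min(1, m p) exactly", {
  expect_equal(bonferroni(0.01, m = 10), 0.1)
  expect_equal(bonferroni(0.5, m = 10), 1.0)
  expect_equal(bonferroni(c(0.2, 0.7)), c(0.4, 1.0))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})

test_that("BH q-values reproduce the step-up construction", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  expect_error(bh_fdr(numeric(0)), "empty")
  # order invariance: sort-and-restore correctness
  set.seed(5)
  p <- runif(40)
  ord <- sample(40)
  expect_equal(bh_fdr(p)[ord], bh_fdr(p[ord]))
})

test_that("enrichment reproduces the hypergeometric tail and the ratio convention", {
  ref <- paste0("g", 1:100)
  sets <- list(S26 = paste0("g", 1:26), S5 = paste0("g", 30:34))
  # 3 hits in a 26-gene set: ratio prints as 0.12
  input26 <- c(paste0("g", 1:3), paste0("g", 90:96))
  e <- enrichment(input26, sets["S26"], ref)
  expect_equal(round(e$ratio, 2), 0.12)
  expect_equal(e$k, 3)
  # exhaustive tail-sum oracle: reference 100, set 5, list 10, hits 3
  input <- c(paste0("g", 30:32), paste0("g", 50:56))
  e5 <- enrichment(input, sets["S5"], ref)
  oracle <- sum(sapply(3:5, function(j)
    choose(5, j) * choose(95, 10 - j))) / choose(100, 10)
  expect_equal(e5$p, oracle, tolerance = 1e-12)
  # p is non-increasing in the number of hits
  ps <- sapply(0:5, function(k) {
    inp <- c(if (k > 0) paste0("g", 30:(29 + k)),
             if (k < 10) paste0("g", 50:(59 - k)))
    enrichment(inp, sets["S5"], ref)$p
  })
  expect_true(all(diff(ps) <= 1e-12))
  # input equal to the reference makes every contained set a certain event
  efull <- enrichment(ref, sets, ref)
  expect_true(all(efull$p == 1))
  expect_true(all(efull$ratio == 1))
  # genes outside the reference are dropped and reported
  ed <- enrichment(c("g1", "not_on_array"), sets["S26"], ref)
  expect_equal(attr(ed, "dropped"), "not_on_array")
  expect_equal(ed$n_list, 1)
  expect_error(enrichment("g1", sets, character(0)), "empty reference")
})
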