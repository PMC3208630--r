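#!/usr/bin/env Rscript
# Quality control: simulate two-channel intensities (with a planted fraction
# of failed probes), recompute beta = M/(M+U), filter on detection
# p-values, and screen samples by PCA for outliers and technical
# confounders.

source("analysis/00_config.R")

for (arm in names(arm_configs)) {
  cfg <- arm_configs[[arm]]
  paths <- arm_paths(arm)
  beta <- read_beta_matrix(paths$beta)
  pheno <- read.csv(paths$pheno)

  intens <- simulate_intensities(beta, cfg, fail_fraction = 0.3)
  beta_rt <- beta_matrix(compute_beta(intens$M, intens$U),
                         beta$probe_ids, beta$sample_ids)
  filt <- detection_filter(intens$detection_p)
  message(sprintf("[%s] detection filter: %d / %d probes pass (%.0f%%)",
                  arm, filt$report$probes_passed, filt$report$probes_tested,
                  100 * filt$report$pass_rate))

  beta_qc <- beta_matrix(beta_rt$values[filt$pass, , drop = FALSE],
                         beta$probe_ids[filt$pass], beta$sample_ids)
  pca <- pca_screen(beta_qc, n_components = 5)
  flags <- outlier_flag(pca$scores)
  message(sprintf("[%s] PCA outliers: %s", arm,
                  if (any(flags)) paste(names(flags)[flags], collapse = ", ")
                  else "none"))

  covs <- pheno[, c("dna_amount", "od_260_280", "batch")]
  covs$batch <- factor(covs$batch)
  screen <- covariate_screen(pca$scores, covs)
  n_assoc <- sum(screen$p < 0.05, na.rm = TRUE)
  message(sprintf("[%s] covariate screen: %d of %d (PC, covariate) pairs at p < 0.05",
                  arm, n_assoc, sum(!is.na(screen$p))))

  write_beta_matrix(beta_qc, file.path(data_dir,
                                       sprintf("%s_beta_qc.tsv", arm)))
  write.table(screen, file.path(results_dir,
                                sprintf("%s_covariate_screen.tsv", arm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest_json(list(seed = cfg$seed,
                           probes_tested = filt$report$probes_tested,
                           probes_passed = filt$report$probes_passed,
                           pass_rate = filt$report$pass_rate,
                           outliers = names(flags)[flags]),
                      file.path(results_dir, sprintf("%s_qc.json", arm)))
}
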