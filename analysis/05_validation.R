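#!/usr/bin/env Rscript
# Internal validation of each arm's fitted model: leave-one-out
# cross-validation on the selected probe set, generalized-likelihood-ratio
# power against the intercept-only null, and hierarchical clustering of
# samples at the significant loci.

source("analysis/00_config.R")

for (arm in names(arm_configs)) {
  cfg <- arm_configs[[arm]]
  paths <- arm_paths(arm)
  beta <- read_beta_matrix(file.path(data_dir,
                                     sprintf("%s_beta_qc.tsv", arm)))
  pheno <- read.csv(paths$pheno)
  sig <- read.delim(paths$sig)

  keep <- match(sig$probe_id, beta$probe_ids)
  beta_sig <- beta_matrix(beta$values[keep, , drop = FALSE],
                          sig$probe_id, beta$sample_ids)

  cv <- loocv(beta_sig, pheno$group, seed = cfg$seed)
  pw <- bcsvd_glr(beta_sig, pheno$group, seed = cfg$seed)
  cl <- hierarchical_cluster(beta_sig, k = 2)
  pure <- all(rowSums(table(cl$labels, pheno$group) > 0) == 1)

  message(sprintf(
    "[%s] LOOCV sensitivity %.0f%%, specificity %.0f%%; -ln(lambda) = %.2f, deviance %.2f, power %.4f; k=2 cut %s the groups",
    arm, 100 * cv$sensitivity, 100 * cv$specificity, pw$neg_ln_lambda,
    pw$deviance, pw$power, if (pure) "reproduces" else "mixes"))

  writeLines(cl$newick, file.path(results_dir,
                                  sprintf("%s_dendrogram.nwk", arm)))
  write.table(data.frame(sample_id = names(cl$labels), cluster = cl$labels),
              file.path(results_dir, sprintf("%s_clusters.tsv", arm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest_json(list(seed = cfg$seed,
                           n_selected = nrow(sig),
                           sensitivity = cv$sensitivity,
                           specificity = cv$specificity,
                           confusion = as.list(cv$confusion),
                           neg_ln_lambda = pw$neg_ln_lambda,
                           deviance = pw$deviance, power = pw$power),
                      file.path(results_dir,
                                sprintf("%s_validation.json", arm)))
}
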