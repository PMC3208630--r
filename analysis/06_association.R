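#!/usr/bin/env Rscript
# Phenotype work: classify PCOS-like phenotypes from the sample sheets
# (cycle length > 34 d, testosterone >= 0.32 ng/ml, >= 10 follicles), regress
# methylation at significant probes on serum testosterone within the PA
# group (with the control group run alongside as a negative control), and
# test gene-set over-representation against the array's own gene list.

source("analysis/00_config.R")

for (arm in names(arm_configs)) {
  paths <- arm_paths(arm)
  beta <- read_beta_matrix(file.path(data_dir,
                                     sprintf("%s_beta_qc.tsv", arm)))
  pheno <- read.csv(paths$pheno)
  sig <- read.delim(paths$sig)

  labels <- classify_phenotypes(pheno)
  write.csv(labels, file.path(results_dir,
                              sprintf("%s_phenotype_labels.csv", arm)),
            row.names = FALSE)
  if (arm == "adult") {
    n_int <- sum(labels$cycle_status == "intermittent", na.rm = TRUE)
    message(sprintf("[adult] %d intermittent/anovulatory, %d hyperandrogenic, %d PCO",
                    n_int, sum(labels$hyperandrogenic, na.rm = TRUE),
                    sum(labels$pco, na.rm = TRUE)))
  }

  keep <- match(sig$probe_id, beta$probe_ids)
  beta_sig <- beta_matrix(beta$values[keep, , drop = FALSE],
                          sig$probe_id, beta$sample_ids)
  testo <- setNames(pheno$testosterone, pheno$sample_id)
  for (grp in c("PA", "control")) {
    assoc <- phenotype_regression(beta_sig, testo,
                                  pheno$sample_id[pheno$group == grp])
    write.table(assoc,
                file.path(results_dir,
                          sprintf("%s_association_%s.tsv", arm, grp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[%s/%s] %d probes tested; %d at raw p < 0.05; min q = %.3f",
                    arm, grp, nrow(assoc), sum(assoc$p < 0.05),
                    if (nrow(assoc)) min(assoc$q_bh) else NA))
  }
}

# over-representation on the probe-validity gene calls, with the full array
# gene list as the reference set
verdicts <- read.delim(file.path(results_dir, "probe_validity.tsv"))
genes <- read_genes(file.path(data_dir, "genes.bed"))
reference <- genes$gene_id
sets <- split(reference, rep(seq_len(max(1, length(reference) %/% 5)),
                             each = 5, length.out = length(reference)))
names(sets) <- sprintf("SET%02d", seq_along(sets))
write_gmt(sets, file.path(data_dir, "gene_sets.gmt"))
input <- unique(na.omit(verdicts$mapped_gene[verdicts$valid]))
enr <- enrichment(input, read_gmt(file.path(data_dir, "gene_sets.gmt")),
                  reference)
write.table(enr, file.path(results_dir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- enr[order(enr$p), ][1, ]
message(sprintf("enrichment: top set %s, %d/%d (%.2f), p = %.3g",
                top$set, top$k, top$n_set, top$ratio, top$p))
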