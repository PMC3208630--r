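#!/usr/bin/env Rscript
# Generate the synthetic study inputs: beta matrices with known differential
# structure and phenotype sheets for both arms, plus a toy genome with
# planted probe classes for the cross-species validity stage.

source("analysis/00_config.R")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

for (arm in names(arm_configs)) {
  cfg <- arm_configs[[arm]]
  ds <- suppressWarnings(generate_dataset(cfg))
  paths <- arm_paths(arm)
  write_beta_matrix(ds$beta, paths$beta)
  write.csv(ds$phenotypes, paths$pheno, row.names = FALSE)
  jsonlite::write_json(list(
    differential_probe_ids = ds$truth$differential_probe_ids,
    true_delta = as.list(ds$truth$true_delta)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  message(sprintf("[%s] %d probes x %d samples, %d planted differential",
                  arm, nrow(ds$beta$values), ncol(ds$beta$values),
                  length(ds$truth$differential_probe_ids)))
}

gs <- generate_genome_and_probes(arm_configs$infant, seed = 303,
                                 n_per_class = 3)
write_genome_fasta(gs$genome, file.path(data_dir, "genome.fa"))
write_genes(gs$genome$genes, file.path(data_dir, "genes.bed"), "bed")
write_genes(gs$genome$genes, file.path(data_dir, "genes.gff3"), "gff3")
write.csv(gs$manifest, file.path(data_dir, "probe_manifest.csv"),
          row.names = FALSE)
write.csv(gs$truth$planted_validity,
          file.path(data_dir, "probe_truth.csv"), row.names = FALSE)
message(sprintf("toy genome: %d chromosomes, %d genes, %d planted probes",
                length(gs$genome$chromosomes), nrow(gs$genome$genes),
                nrow(gs$manifest)))
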