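#!/usr/bin/env Rscript
# Cross-species probe validity: align each 50-nt probe of the manifest to
# the toy genome, apply the 3'-anchor / mismatch / uniqueness criteria, and
# confirm gene annotations through the 1.5 kb promoter or gene-body windows.
# Verdicts are compared with the planted truth.

source("analysis/00_config.R")

genome <- genome_bundle(read_genome_fasta(file.path(data_dir, "genome.fa")),
                        read_genes(file.path(data_dir, "genes.bed")))
manifest <- read.csv(file.path(data_dir, "probe_manifest.csv"))
truth <- read.csv(file.path(data_dir, "probe_truth.csv"))

verdicts <- validate_probes(manifest, genome)
write.table(verdicts, file.path(results_dir, "probe_validity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

m <- merge(verdicts, truth, by = "probe_id")
agree <- mean(m$valid == m$expected_valid & m$reason == m$expected_reason)
message(sprintf("%d probes aligned; %d valid; agreement with planted truth %.0f%%",
                nrow(verdicts), sum(verdicts$valid), 100 * agree))
print(table(verdicts$reason))
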