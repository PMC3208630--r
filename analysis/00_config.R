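# Shared configuration for the analysis scripts. Two synthetic cohorts
# emulate the study design: an infant arm (5 controls vs 7 prenatally
# androgenized) and an adult arm (5 vs 8), each on a down-sampled 2,163-probe
# array with planted differential methylation (163 and 325 loci).

library(bcsvdmeth)

results_dir <- "results"
data_dir <- file.path(results_dir, "data")

arm_configs <- list(
  infant = sim_config(n_control = 5, n_case = 7, n_probes = 2163,
                      n_differential = 163, effect_size = 0.3,
                      within_group_sd = 0.05, seed = 101,
                      age_class = "infant"),
  adult = sim_config(n_control = 5, n_case = 8, n_probes = 2163,
                     n_differential = 325, effect_size = 0.3,
                     within_group_sd = 0.05, seed = 202,
                     age_class = "adult")
)

n_permutations <- 99L
alpha <- 0.05

arm_paths <- function(arm) {
  list(beta = file.path(data_dir, sprintf("%s_beta.tsv", arm)),
       pheno = file.path(data_dir, sprintf("%s_phenotypes.csv", arm)),
       truth = file.path(data_dir, sprintf("%s_truth.json", arm)),
       bcsvd = file.path(results_dir, sprintf("%s_bcsvd.tsv", arm)),
       sig = file.path(results_dir, sprintf("%s_significant.tsv", arm)))
}
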