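#' Pipeline configuration
#'
#' One structured object holding every stage toggle and module default, so a
#' run is reproducible from the config and seed alone. Unknown keys are
#' rejected.
#'
#' @param sim A [sim_config()].
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "qc", "bcsvd", "validate_probes", "validation",
#'   "association", "enrichment")`.
#' @param out_dir Output directory for run artifacts.
#' @param detection_p_threshold,min_sample_fraction Detection-filter
#'   defaults.
#' @param fail_fraction Planted detection-failure fraction for the intensity
#'   simulation.
#' @param n_components,z_threshold PCA screen defaults.
#' @param settings A [bcsvd_settings()].
#' @param B,alpha Permutation count and significance level.
#' @param max_mismatches Probe-alignment mismatch cap.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "qc", "bcsvd",
                                       "validate_probes", "validation",
                                       "association", "enrichment"),
                            out_dir = tempfile("bcsvd_run_"),
                            detection_p_threshold = 0.01,
                            min_sample_fraction = 1.0,
                            fail_fraction = 0,
                            n_components = 5, z_threshold = 3,
                            settings = bcsvd_settings(),
                            B = 99L, alpha = 0.05, max_mismatches = 5L) {
  all_stages <- c("simulate", "qc", "bcsvd", "validate_probes", "validation",
                  "association", "enrichment")
  if (!all(stages %in% all_stages))
    stop("unknown stage: ", paste(setdiff(stages, all_stages), collapse = ", "))
  structure(list(sim = sim, stages = stages, out_dir = out_dir,
                 detection_p_threshold = detection_p_threshold,
                 min_sample_fraction = min_sample_fraction,
                 fail_fraction = fail_fraction,
                 n_components = n_components, z_threshold = z_threshold,
                 settings = settings, B = as.integer(B), alpha = alpha,
                 max_mismatches = as.integer(max_mismatches)),
            class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the toggled stages in order — simulate, QC, BCSVD, probe
#' validity, model validation, phenotype association, enrichment — writing
#' every artifact (with the seed and settings that produced it) into the run
#' directory. Reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of in-memory stage results; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  p <- function(...) file.path(config$out_dir, ...)
  on <- function(s) s %in% config$stages

  if (on("simulate")) stage_try("simulate", {
    res$dataset <- generate_dataset(config$sim)
    res$genome_sim <- generate_genome_and_probes(config$sim)
    write_beta_matrix(res$dataset$beta, p("beta.tsv"))
    utils::write.csv(res$dataset$phenotypes, p("phenotypes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      differential_probe_ids = res$dataset$truth$differential_probe_ids,
      true_delta = as.list(res$dataset$truth$true_delta),
      planted_validity = res$genome_sim$truth$planted_validity),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
    write_genome_fasta(res$genome_sim$genome, p("genome.fa"))
    write_genes(res$genome_sim$genome$genes, p("genes.bed"), "bed")
    utils::write.csv(res$genome_sim$manifest, p("probe_manifest.csv"),
                     row.names = FALSE)
  })

  beta <- res$dataset$beta
  labels <- res$dataset$phenotypes$group

  if (on("qc")) stage_try("qc", {
    intens <- simulate_intensities(beta, config$sim, config$fail_fraction)
    beta_rt <- beta_matrix(compute_beta(intens$M, intens$U),
                           beta$probe_ids, beta$sample_ids)
    filt <- detection_filter(intens$detection_p, config$detection_p_threshold,
                             config$min_sample_fraction)
    beta_qc <- beta_matrix(beta_rt$values[filt$pass, , drop = FALSE],
                           beta$probe_ids[filt$pass], beta$sample_ids)
    pca <- pca_screen(beta_qc, config$n_components)
    flags <- outlier_flag(pca$scores, config$z_threshold)
    covs <- res$dataset$phenotypes[, c("dna_amount", "od_260_280", "batch")]
    covs$batch <- factor(covs$batch)
    screen <- covariate_screen(pca$scores, covs)
    utils::write.table(screen, p("covariate_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest_json(list(seed = config$sim$seed,
                             probes_tested = filt$report$probes_tested,
                             probes_passed = filt$report$probes_passed,
                             pass_rate = filt$report$pass_rate,
                             outliers = names(flags)[flags]),
                        p("qc_report.json"))
    res$qc <- list(beta_qc = beta_qc, report = filt$report, pca = pca,
                   outlier_flags = flags, covariate_screen = screen)
  })

  beta_work <- if (!is.null(res$qc)) res$qc$beta_qc else beta

  if (on("bcsvd")) stage_try("bcsvd", {
    design <- standardize(beta_work, labels)
    results <- permutation_pvalues(design, B = config$B,
                                   seed = config$sim$seed,
                                   settings = config$settings)
    sig <- select_significant(results, config$alpha)
    out <- results
    out$significant <- out$empirical_p < config$alpha
    utils::write.table(out, p("bcsvd_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest_json(list(seed = config$sim$seed, B = attr(results, "B"),
                             exhaustive = attr(results, "exhaustive"),
                             rank = attr(results, "rank"),
                             dropped_probes = attr(results, "dropped_probes"),
                             alpha = config$alpha,
                             settings = unclass(config$settings)),
                        p("bcsvd_manifest.json"))
    res$bcsvd <- list(results = results, significant = sig)
  })

  if (on("validate_probes")) stage_try("validate_probes", {
    verdicts <- validate_probes(res$genome_sim$manifest,
                                res$genome_sim$genome,
                                config$max_mismatches)
    utils::write.table(verdicts, p("probe_validity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$validity <- verdicts
  })

  if (on("validation")) stage_try("validation", {
    sig_ids <- res$bcsvd$significant$probe_id
    if (length(sig_ids) >= 1) {
      keep <- match(sig_ids, beta_work$probe_ids)
      beta_sig <- beta_matrix(beta_work$values[keep, , drop = FALSE],
                              sig_ids, beta_work$sample_ids)
      cv <- loocv(beta_sig, labels, config$settings, seed = config$sim$seed)
      pw <- bcsvd_glr(beta_sig, labels, config$settings,
                      seed = config$sim$seed)
      cl <- hierarchical_cluster(beta_sig)
      writeLines(cl$newick, p("dendrogram.nwk"))
      utils::write.table(data.frame(sample_id = names(cl$labels),
                                    cluster = cl$labels),
                         p("clusters.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_manifest_json(list(sensitivity = cv$sensitivity,
                               specificity = cv$specificity,
                               confusion = as.list(cv$confusion),
                               neg_ln_lambda = pw$neg_ln_lambda,
                               deviance = pw$deviance, power = pw$power),
                          p("validation.json"))
      res$validation <- list(loocv = cv, power = pw, cluster = cl)
    }
  })

  if (on("association")) stage_try("association", {
    ph <- res$dataset$phenotypes
    labels_df <- classify_phenotypes(ph)
    utils::write.csv(labels_df, p("phenotype_labels.csv"), row.names = FALSE)
    sig_ids <- res$bcsvd$significant$probe_id
    if (length(sig_ids) >= 1) {
      keep <- match(sig_ids, beta_work$probe_ids)
      beta_sig <- beta_matrix(beta_work$values[keep, , drop = FALSE],
                              sig_ids, beta_work$sample_ids)
      testo <- stats::setNames(ph$testosterone, ph$sample_id)
      assoc_pa <- phenotype_regression(beta_sig, testo,
                                       ph$sample_id[ph$group == "PA"])
      assoc_ctrl <- phenotype_regression(beta_sig, testo,
                                         ph$sample_id[ph$group == "control"])
      utils::write.table(assoc_pa, p("association_PA.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(assoc_ctrl, p("association_control.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$association <- list(PA = assoc_pa, control = assoc_ctrl,
                              labels = labels_df)
    }
  })

  if (on("enrichment")) stage_try("enrichment", {
    reference <- res$genome_sim$genome$genes$gene_id
    sets <- split(reference,
                  rep(seq_len(max(1, length(reference) %/% 5)),
                      each = 5, length.out = length(reference)))
    names(sets) <- sprintf("SET%02d", seq_along(sets))
    input <- unique(res$validity$mapped_gene[res$validity$valid])
    input <- input[!is.na(input)]
    enr <- enrichment(input, sets, reference)
    utils::write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$enrichment <- enr
  })

  invisible(res)
}

#' GLR power of a fitted BCSVD model
#'
#' Fits the probit model on the SVD scores of the given probe set, evaluates
#' its log-likelihood at the posterior mean, compares it with the
#' intercept-only null (binomial MLE), and converts the resulting
#' -ln(lambda) to power via the one-degree chi-square reference.
#'
#' @param beta A [beta_matrix] at the selected probes.
#' @param labels 0/1 or character labels.
#' @param settings A [bcsvd_settings()].
#' @param seed Integer seed.
#' @param case_label Case label for character input.
#' @return A `power_result` with extra fields `loglik_null`, `loglik_alt`.
#' @export
bcsvd_glr <- function(beta, labels, settings = bcsvd_settings(), seed = 1L,
                      case_label = "PA") {
  y <- coerce_labels(labels, case_label)
  design <- standardize(beta, y)
  decomp <- svd_reduce(design)
  flip <- y[1] == 1L
  yc <- if (flip) 1L - y else y
  draws <- gibbs_fit(decomp$scores, yc, settings, seed)
  theta <- c(mean(draws$intercept), colMeans(draws$gamma))
  X <- cbind(1, decomp$scores)
  ll_alt <- probit_loglik(X, yc, theta)
  phat <- mean(y)
  ll_null <- sum(y) * log(phat) + sum(1 - y) * log(1 - phat)
  pw <- glr_power(max(0, ll_alt - ll_null))
  pw$loglik_null <- ll_null
  pw$loglik_alt <- ll_alt
  pw
}
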