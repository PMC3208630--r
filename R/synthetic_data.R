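#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. The defaults emulate
#' the infant arm of the study design this package targets: 5 control and 7
#' prenatally androgenized (PA) samples, a down-sampled array, and a set of
#' planted differentially methylated probes.
#'
#' @param n_control Number of control samples.
#' @param n_case Number of case (PA) samples.
#' @param n_probes Total number of CpG probes on the simulated array.
#' @param n_differential Number of probes with a planted group difference.
#' @param effect_size Absolute planted group difference in mean beta
#'   (methylation fraction, 0-1 scale).
#' @param within_group_sd Within-group beta-scale noise SD (truncated normal).
#' @param n_batches Number of technical batches; samples are assigned
#'   round-robin.
#' @param batch_effect_sd SD of the additive per-batch beta-scale offset.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param intensity_scale Mean total fluorescence counts per probe used by
#'   [simulate_intensities()].
#' @param age_class `"infant"` or `"adult"`; controls which clinical phenotypes
#'   (menstrual cycle length, ovarian follicle counts) are generated.
#' @param genome_n_chrom,genome_chrom_length,genome_n_genes Shape of the toy
#'   genome built by [generate_genome_and_probes()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_control = 5L, n_case = 7L,
                       n_probes = 2000L, n_differential = 163L,
                       effect_size = 0.3, within_group_sd = 0.05,
                       n_batches = 2L, batch_effect_sd = 0,
                       seed = 1L, intensity_scale = 1000,
                       age_class = c("infant", "adult"),
                       genome_n_chrom = 2L, genome_chrom_length = 50000L,
                       genome_n_genes = 20L) {
  age_class <- match.arg(age_class)
  cfg <- list(n_control = as.integer(n_control), n_case = as.integer(n_case),
              n_probes = as.integer(n_probes),
              n_differential = as.integer(n_differential),
              effect_size = effect_size, within_group_sd = within_group_sd,
              n_batches = as.integer(n_batches),
              batch_effect_sd = batch_effect_sd,
              seed = as.integer(seed), intensity_scale = intensity_scale,
              age_class = age_class,
              genome_n_chrom = as.integer(genome_n_chrom),
              genome_chrom_length = as.integer(genome_chrom_length),
              genome_n_genes = as.integer(genome_n_genes))
  if (cfg$n_control <= 0L || cfg$n_case <= 0L || cfg$n_probes <= 0L)
    stop("sample and probe counts must be positive")
  if (cfg$n_differential < 0L || cfg$n_differential > cfg$n_probes)
    stop("n_differential must lie in [0, n_probes]")
  if (cfg$effect_size < 0 || cfg$within_group_sd < 0 || cfg$batch_effect_sd < 0)
    stop("effect_size, within_group_sd and batch_effect_sd must be >= 0")
  if (cfg$n_batches <= 0L) stop("n_batches must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Beta matrix container
#'
#' Methylation fractions in `[0, 1]` stored probes-in-rows (the usual
#' features-by-samples array convention). `NA` encodes missing values.
#'
#' @param values Numeric matrix, probes x samples, entries in `[0,1]` or `NA`.
#' @param probe_ids,sample_ids Unique identifiers for rows / columns.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe_ids and sample_ids are required")
  probe_ids <- as.character(probe_ids); sample_ids <- as.character(sample_ids)
  if (anyDuplicated(probe_ids)) stop("duplicate probe IDs")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids))
    stop("dimension mismatch between values and IDs")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at (%s, %s): %g",
                 probe_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 values[bad[1, 1], bad[1, 2]]))
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 sample_ids = sample_ids),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

# Truncated-normal draws on [0, 1] via inverse CDF; sd = 0 degenerates to the
# clamped mean.
rtrunc01 <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- pmin(1, pmax(0, mean))
  pos <- sd > 0
  if (any(pos)) {
    fa <- stats::pnorm(0, mean[pos], sd[pos])
    fb <- stats::pnorm(1, mean[pos], sd[pos])
    u <- stats::runif(sum(pos))
    out[pos] <- stats::qnorm(fa + u * (fb - fa), mean[pos], sd[pos])
    out[pos] <- pmin(1, pmax(0, out[pos]))  # guard numerical spill
  }
  out
}

#' Generate a synthetic case-control methylation dataset
#'
#' Draws a beta matrix with a known set of differentially methylated probes,
#' a phenotype table shaped like the study's clinical tables, and a truth set
#' recording the planted signal. Case samples have their per-probe mean beta
#' shifted by a signed effect at the differential probes only; noise is
#' truncated normal on `[0, 1]`; batch offsets are additive on the beta scale
#' before truncation, with batch labels assigned round-robin.
#'
#' @param config A [sim_config()].
#' @return A list with elements `beta` ([beta_matrix]), `phenotypes`
#'   (data.frame), and `truth` (class `truth_set`: `differential_probe_ids`,
#'   named `true_delta` over all probes, `clamped` flag vector).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_control + config$n_case
    probe_ids <- sprintf("cg%05d", seq_len(config$n_probes))
    sample_ids <- c(sprintf("ctrl_%02d", seq_len(config$n_control)),
                    sprintf("case_%02d", seq_len(config$n_case)))
    group <- rep(c("control", "PA"), c(config$n_control, config$n_case))

    base_mean <- stats::runif(config$n_probes, 0.05, 0.95)
    diff_idx <- sort(sample.int(config$n_probes, config$n_differential))
    sign_j <- sample(c(-1, 1), config$n_differential, replace = TRUE)
    case_mean <- base_mean
    case_mean[diff_idx] <- base_mean[diff_idx] + sign_j * config$effect_size
    clamped <- case_mean < 0 | case_mean > 1
    if (any(clamped))
      warning(sprintf("%d planted case means clamped to [0,1]", sum(clamped)))
    case_mean <- pmin(1, pmax(0, case_mean))
    true_delta <- case_mean - base_mean
    names(true_delta) <- probe_ids

    batch <- ((seq_len(n) - 1L) %% config$n_batches) + 1L
    batch_off <- stats::rnorm(config$n_batches, 0, config$batch_effect_sd)

    vals <- matrix(NA_real_, config$n_probes, n)
    for (i in seq_len(n)) {
      mu <- if (group[i] == "PA") case_mean else base_mean
      vals[, i] <- rtrunc01(config$n_probes, mu + batch_off[batch[i]],
                            config$within_group_sd)
    }
    beta <- beta_matrix(vals, probe_ids, sample_ids)

    pheno <- simulate_phenotypes(sample_ids, group, batch, config)

    truth <- structure(list(
      differential_probe_ids = probe_ids[diff_idx],
      true_delta = true_delta,
      clamped = stats::setNames(clamped, probe_ids)), class = "truth_set")
    list(beta = beta, phenotypes = pheno, truth = truth)
  })
}

# Clinical + technical covariates shaped like the study's sample tables:
# serum testosterone / androstenedione (ng/ml) elevated in PA animals, adult
# cycle lengths and follicle counts crossing the published phenotype cutoffs,
# plus DNA amount, OD 260/280 and batch as technical covariates.
simulate_phenotypes <- function(sample_ids, group, batch, config) {
  n <- length(sample_ids)
  is_pa <- group == "PA"
  testo <- ifelse(is_pa,
                  pmax(0.01, stats::rnorm(n, 0.37, 0.10)),
                  pmax(0.01, stats::rnorm(n, 0.17, 0.07)))
  andro <- ifelse(is_pa,
                  pmax(0.05, stats::rnorm(n, 1.8, 1.0)),
                  pmax(0.05, stats::rnorm(n, 0.85, 0.20)))
  if (config$age_class == "adult") {
    cycle <- ifelse(is_pa,
                    pmax(24, round(stats::rnorm(n, 60, 25))),
                    pmax(24, round(stats::rnorm(n, 27, 2))))
    follicles <- ifelse(is_pa, stats::rpois(n, 12), stats::rpois(n, 4))
  } else {
    cycle <- rep(NA_real_, n)
    follicles <- rep(NA_integer_, n)
  }
  data.frame(sample_id = sample_ids, group = group,
             age_class = config$age_class,
             testosterone = round(testo, 2),
             androstenedione = round(andro, 2),
             cycle_length = cycle, follicle_count = follicles,
             dna_amount = round(stats::rnorm(n, 500, 50), 1),
             od_260_280 = round(stats::rnorm(n, 1.85, 0.05), 2),
             batch = batch, stringsAsFactors = FALSE)
}

#' Simulate two-channel probe intensities from a beta matrix
#'
#' Inverts the beta definition beta = M/(M+U): per probe and sample the total
#' count is Poisson with mean `intensity_scale` and the methylated count M is
#' binomial with probability beta, so the expected recomputed beta equals the
#' input. A configurable fraction of probes is planted as "failed" with high
#' detection p-values in every sample, to exercise detection filtering.
#'
#' @param beta A [beta_matrix].
#' @param config A [sim_config()] (supplies `intensity_scale` and `seed`).
#' @param fail_fraction Fraction of probes planted as detection failures.
#' @return List with matrices `M`, `U`, `detection_p` (probes x samples) and
#'   `failed_probe_ids`.
#' @export
simulate_intensities <- function(beta, config, fail_fraction = 0) {
  stopifnot(inherits(beta, "beta_matrix"), inherits(config, "sim_config"),
            fail_fraction >= 0, fail_fraction <= 1)
  withr::with_seed(config$seed + 1L, {
    v <- beta$values
    np <- nrow(v); ns <- ncol(v)
    total <- matrix(pmax(1, stats::rpois(np * ns, config$intensity_scale)),
                    np, ns)
    vv <- v; vv[is.na(vv)] <- 0.5  # missing betas still get counts
    M <- matrix(stats::rbinom(np * ns, as.vector(total), as.vector(vv)),
                np, ns)
    U <- total - M
    n_fail <- round(fail_fraction * np)
    fail_idx <- if (n_fail > 0) sort(sample.int(np, n_fail)) else integer(0)
    det <- matrix(stats::runif(np * ns, 0, 1e-4), np, ns)
    if (n_fail > 0)
      det[fail_idx, ] <- matrix(stats::runif(n_fail * ns, 0.05, 0.9),
                                n_fail, ns)
    dimnames(M) <- dimnames(U) <- dimnames(det) <- dimnames(v)
    list(M = M, U = U, detection_p = det,
         failed_probe_ids = beta$probe_ids[fail_idx])
  })
}
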