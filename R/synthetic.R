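#' Configuration for synthetic two-arm cohort generation
#'
#' Describes the statistical world the downstream analysis assumes: a
#' two-arm (control vs marker-positive) bulk RNA-seq experiment with
#' negative-binomial counts, a planted upregulated gene signature in the
#' positive arm, clinical covariates independent of arm, and survival times
#' linked to the signature through a log-hazard coefficient.
#'
#' Defaults state that world once: 1000 genes with 29 planted signature
#' genes (the size of the derived signature the pipeline is built around),
#' 10 samples per arm, negative-binomial counts with median baseline mean
#' 100 and size 10 (bulk-like overdispersion ~0.1), a planted fold-change
#' of 4, gene lengths uniform on 500-5000 bp, a protective survival link of
#' -0.5 per standard-deviation of score (high score, longer survival), and
#' 30% censoring.
#'
#' @param n_genes total number of genes
#' @param n_signature_genes number of planted upregulated genes
#' @param samples_per_group samples per arm (>= 2)
#' @param baseline_mean median negative-binomial mean count per gene;
#'   per-gene baselines are drawn log-normally (sdlog 1) around it
#' @param dispersion negative-binomial size parameter (constant across
#'   genes); variance = mu + mu^2 / size
#' @param signature_fold multiplicative mean shift of planted genes in the
#'   positive arm (>= 1; 1 = null cohort)
#' @param gene_length_range length-2 integer vector, uniform sampling range
#'   for gene lengths in bp
#' @param survival_link log-hazard per standard deviation of the latent
#'   signature score; negative values make high-score samples live longer
#' @param censor_rate fraction of samples independently censored, in [0,1]
#' @param seed master seed; per-stage sub-seeds are derived from it so
#'   identical configs give bitwise-identical cohorts
#' @return validated list of class `synthetic_config`
#' @export
synthetic_config <- function(n_genes = 1000, n_signature_genes = 29,
                             samples_per_group = 10, baseline_mean = 100,
                             dispersion = 10, signature_fold = 4,
                             gene_length_range = c(500L, 5000L),
                             survival_link = -0.5, censor_rate = 0.3,
                             seed = 1) {
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_number(n_signature_genes, "n_signature_genes", lower = 1, integer = TRUE)
  if (n_signature_genes > n_genes)
    abort_config("invalid 'n_signature_genes': exceeds 'n_genes'")
  check_number(samples_per_group, "samples_per_group", lower = 2, integer = TRUE)
  check_number(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_number(signature_fold, "signature_fold", lower = 1)
  if (!is.numeric(gene_length_range) || length(gene_length_range) != 2L ||
      any(gene_length_range <= 0) || gene_length_range[1] > gene_length_range[2])
    abort_config("invalid 'gene_length_range': need positive c(min, max)")
  check_number(survival_link, "survival_link")
  check_number(censor_rate, "censor_rate", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)

  structure(list(
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    samples_per_group = as.integer(samples_per_group),
    baseline_mean = baseline_mean, dispersion = dispersion,
    signature_fold = signature_fold,
    gene_length_range = as.integer(gene_length_range),
    survival_link = survival_link, censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic two-arm cohort with a planted signature
#'
#' Draws negative-binomial counts for `n_genes` genes over two arms
#' ("control" and "positive", `samples_per_group` each). Per-gene baseline
#' means are log-normal around `baseline_mean`; the first
#' `n_signature_genes` genes (ids recorded in `truth`) have their mean
#' multiplied by `signature_fold` in the positive arm only. Gene lengths
#' are uniform over `gene_length_range`, covariates (age, stage, location)
#' are drawn independently of arm, and survival times follow
#' [generate_survival()] applied to a latent per-sample signature score
#' (standardized mean log2 count over planted genes).
#'
#' @param config a `synthetic_config`
#' @return list of class `synthetic_cohort`: `counts` (integer matrix with
#'   gene/sample dimnames), `gene_lengths` (named integer vector),
#'   `metadata` (data.frame: `sample`, `group`, `age`, `stage`, `location`,
#'   `time`, `event`), `truth` (list: `signature` gene ids, `fold`),
#'   `config`
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ng <- config$n_genes; ns <- 2L * config$samples_per_group
  genes <- sprintf("gene_%04d", seq_len(ng))
  samples <- c(sprintf("ctrl_%02d", seq_len(config$samples_per_group)),
               sprintf("pos_%02d", seq_len(config$samples_per_group)))
  group <- rep(c("control", "positive"), each = config$samples_per_group)
  planted <- genes[seq_len(config$n_signature_genes)]

  counts <- with_seed(stage_seed(config$seed, "counts"), {
    base_mu <- stats::rlnorm(ng, meanlog = log(config$baseline_mean), sdlog = 1)
    mu <- matrix(base_mu, nrow = ng, ncol = ns)
    mu[seq_len(config$n_signature_genes), group == "positive"] <-
      mu[seq_len(config$n_signature_genes), group == "positive"] *
      config$signature_fold
    cnt <- matrix(stats::rnbinom(ng * ns, mu = mu, size = config$dispersion),
                  nrow = ng, dimnames = list(genes, samples))
    storage.mode(cnt) <- "integer"
    cnt
  })

  gene_lengths <- with_seed(stage_seed(config$seed, "lengths"), {
    stats::setNames(sample(seq(config$gene_length_range[1],
                               config$gene_length_range[2]), ng,
                           replace = TRUE), genes)
  })

  covariates <- with_seed(stage_seed(config$seed, "covariates"), {
    data.frame(
      sample = samples, group = group,
      age = round(stats::rnorm(ns, mean = 62, sd = 10), 1),
      stage = sample(1:4, ns, replace = TRUE,
                     prob = c(0.25, 0.35, 0.25, 0.15)),
      location = sample(c("left", "right"), ns, replace = TRUE)
    )
  })

  # latent per-sample signature activity drives survival
  latent <- colMeans(log2(counts[planted, , drop = FALSE] + 1))
  surv <- generate_survival(latent, config)
  metadata <- cbind(covariates, surv)

  structure(list(counts = counts, gene_lengths = gene_lengths,
                 metadata = metadata,
                 truth = list(signature = planted,
                              fold = config$signature_fold),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic two-arm cohort: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples (", x$config$samples_per_group,
      "/arm), ", length(x$truth$signature), " planted genes at fold ",
      x$truth$fold, "\n", sep = "")
  invisible(x)
}

#' Generate a bimodal expression vector for threshold-recovery tests
#'
#' A two-component Gaussian mixture: `n_low` values around `mu_low` and
#' `n_high` around `mu_high`, common standard deviation `sigma`. The true
#' component membership is recorded in the `"membership"` attribute so
#' tests can check that the recovered StepMiner threshold separates the
#' modes.
#'
#' @param n_low,n_high component sizes (>= 1)
#' @param mu_low,mu_high component means, `mu_low < mu_high`
#' @param sigma common standard deviation (> 0)
#' @param seed RNG seed
#' @return numeric vector of length `n_low + n_high` with attribute
#'   `membership` (`"low"`/`"high"` per element)
#' @export
generate_bimodal_vector <- function(n_low, n_high, mu_low, mu_high, sigma,
                                    seed = 1) {
  check_number(n_low, "n_low", lower = 1, integer = TRUE)
  check_number(n_high, "n_high", lower = 1, integer = TRUE)
  check_number(mu_low, "mu_low")
  check_number(mu_high, "mu_high")
  if (mu_low >= mu_high)
    abort_config("invalid means: 'mu_low' must be below 'mu_high'")
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed", integer = TRUE)
  values <- with_seed(stage_seed(seed, "bimodal"), {
    c(stats::rnorm(n_low, mu_low, sigma), stats::rnorm(n_high, mu_high, sigma))
  })
  attr(values, "membership") <- rep(c("low", "high"), c(n_low, n_high))
  values
}

#' Generate survival times linked to a per-sample score
#'
#' Exponential survival with hazard proportional to
#' `exp(survival_link * z)`, where `z` is the standardized score, so
#' `survival_link` is a log-hazard ratio per standard deviation of score
#' (negative = high score protective). Independent censoring: each sample
#' is censored with probability `censor_rate`, at a uniform time before its
#' event.
#'
#' @param scores finite numeric vector of per-sample scores
#' @param config a `synthetic_config` providing `survival_link`,
#'   `censor_rate`, and the seed for the survival RNG stream
#' @return data.frame: `time` (positive), `event` (1 = event observed,
#'   0 = censored)
#' @export
generate_survival <- function(scores, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(!is.finite(scores))) abort_input("'scores' must be finite")
  z <- if (stats::sd(scores) > 0) {
    (scores - mean(scores)) / stats::sd(scores)
  } else {
    rep(0, length(scores))
  }
  with_seed(stage_seed(config$seed, "survival"), {
    hazard <- 0.02 * exp(config$survival_link * z) # baseline median ~35 units
    t_event <- stats::rexp(length(z), rate = hazard)
    censored <- stats::runif(length(z)) < config$censor_rate
    time <- ifelse(censored, stats::runif(length(z), 0, 1) * t_event, t_event)
    time <- pmax(time, .Machine$double.eps) # strictly positive
    data.frame(time = time, event = as.integer(!censored))
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `counts.tsv` (genes as rows, sample-id header),
#' `gene_lengths.tsv` (gene, length), `metadata.tsv`, and
#' `truth_signature.txt` (one planted gene id per line) into `dir`.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             gene_lengths = file.path(dir, "gene_lengths.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth_signature.txt"))
  write_expression_matrix(cohort$counts, paths[["counts"]])
  utils::write.table(
    data.frame(gene = names(cohort$gene_lengths),
               length = unname(cohort$gene_lengths)),
    paths[["gene_lengths"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$truth$signature, paths[["truth"]])
  invisible(paths)
}
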