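#' Assemble and validate a pipeline configuration
#'
#' The end-to-end flow mirrors a two-step analysis: derive an upregulated
#' signature from a two-arm experiment (unless a signature file is
#' supplied, which skips the differential-expression stage), then fit
#' per-gene StepMiner thresholds, normalize, score, and classify - with an
#' optional survival stage when the metadata carries `time`/`event`
#' columns.
#'
#' Exactly one of `counts` (with `lengths`) or `expression` must be given:
#' counts are summarized to TPM and log2(TPM+1); an `expression` matrix is
#' taken to be log2(TPM+1) already.
#'
#' @param out_dir output directory for result tables and the manifest
#' @param counts path to a count matrix TSV/CSV (genes x samples)
#' @param lengths path to a two-column gene-length TSV (`gene`, `length`)
#' @param expression path to a log2(TPM+1) matrix TSV/CSV
#' @param metadata path to a sample metadata TSV; needs `sample` and
#'   `group` columns, plus `time` and `event` for the survival stage
#' @param signature optional path to a signature gene list; supplying it
#'   skips the differential-expression stage
#' @param gene_sets optional path to a GMT collection; enables the
#'   enrichment stage on the derived signature
#' @param test,control arm labels; default: control = first sorted label
#' @param p_cut,fc_cut differential-expression thresholds (see
#'   [differential_expression()])
#' @param dof degrees of freedom for the step-fit statistic
#' @param gap intermediate band half-width for [binarize()]
#' @param run_survival run the survival stage (requires `time`/`event`)
#' @param seed seed recorded in the manifest; the analysis itself is
#'   deterministic
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, counts = NULL, lengths = NULL,
                            expression = NULL, metadata = NULL,
                            signature = NULL, gene_sets = NULL,
                            test = NULL, control = NULL,
                            p_cut = 0.05, fc_cut = 2, dof = 3, gap = 0,
                            run_survival = FALSE, seed = 1) {
  if (is.null(counts) == is.null(expression))
    abort_config("exactly one of 'counts' or 'expression' must be set")
  if (!is.null(counts) && is.null(lengths))
    abort_config("'lengths' is required with 'counts'")
  if (is.null(metadata)) abort_config("'metadata' path is required")
  for (p in c(counts, lengths, expression, metadata, signature, gene_sets))
    if (!file.exists(p)) abort_config("path does not exist: ", p)
  check_number(p_cut, "p_cut", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(fc_cut, "fc_cut", lower = 1)
  check_number(dof, "dof", lower = 2, integer = TRUE)
  check_number(gap, "gap", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(list(out_dir = out_dir, counts = counts, lengths = lengths,
                 expression = expression, metadata = metadata,
                 signature = signature, gene_sets = gene_sets,
                 test = test, control = control, p_cut = p_cut,
                 fc_cut = fc_cut, dof = dof, gap = gap,
                 run_survival = isTRUE(run_survival),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of [pipeline_config()]. Values given on top
#' (e.g. from CLI flags) override the file's.
#'
#' @param path JSON file
#' @param overrides named list of overriding values
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort_config("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

#' Run the in-memory analysis core
#'
#' deg (unless a signature is supplied) -> threshold -> normalize ->
#' score -> classify, plus optional survival stratification. This is the
#' computational heart of [run_pipeline()], usable directly on matrices.
#'
#' @param expr log2(TPM+1) matrix (genes x samples)
#' @param groups arm label per sample column
#' @param signature optional character vector of gene ids; if `NULL` the
#'   upregulated signature is derived from `expr` by
#'   [differential_expression()]
#' @param survival_df optional data.frame with `time` and `event` per
#'   sample (same order as columns)
#' @inheritParams pipeline_config
#' @return list: `deg` (NULL when the stage was skipped), `signature`,
#'   `fits`, `normalized`, `scores`, `auc`, `compare`, `survival`
#' @export
run_analysis <- function(expr, groups, signature = NULL, test = NULL,
                         control = NULL, p_cut = 0.05, fc_cut = 2,
                         dof = 3, survival_df = NULL) {
  expr <- as_gene_matrix(expr)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (is.null(control)) control <- lev[1L]
  if (is.null(test)) test <- setdiff(lev, control)[1L]

  deg <- NULL
  if (is.null(signature)) {
    deg <- differential_expression(expr, groups, test = test,
                                   control = control, p_cut = p_cut,
                                   fc_cut = fc_cut)
    signature <- signature_genes(deg, "up")
    if (length(signature) == 0L)
      abort_input("derived signature is empty: no gene passes p <= ", p_cut,
                  " and fold-change >= ", fc_cut)
  }

  fits <- fit_step_matrix(expr, dof = dof)
  normalized <- normalize_expression(expr, fits)
  scores <- composite_score(normalized, signature)
  auc <- roc_auc(scores$score, groups, positive = test)
  compare <- group_compare(scores, groups)

  surv <- NULL
  if (!is.null(survival_df)) {
    stratum <- stratify_by_metagene(expr, signature)
    surv <- km_logrank(survival_df$time, survival_df$event, stratum)
    surv$stratum <- stratum
  }

  list(deg = deg, signature = signature, fits = fits,
       normalized = normalized, scores = scores, auc = auc,
       compare = compare, survival = surv,
       arms = c(test = test, control = control))
}

#' Run the full file-to-file pipeline
#'
#' Reads the configured inputs, executes [run_analysis()], and writes into
#' `out_dir`: `deg.tsv` (when derived), `signature.txt`, `stepfits.tsv`,
#' `scores.tsv`, `classification.json` (AUC + Welch tests),
#' `enrichment.tsv` (when gene sets are configured), `survival.json`
#' (when run), and `manifest.json` recording package version, seed,
#' thresholds and the full configuration - enough to regenerate every
#' output. Given the same inputs and seed, outputs are byte-identical.
#'
#' @param config a `pipeline_config`
#' @return invisibly, the [run_analysis()] result list with `$paths`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wrap <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort_input("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
  }

  expr <- wrap("ingest", {
    if (!is.null(config$counts)) {
      cnt <- read_expression_matrix(config$counts, counts = TRUE)
      len_df <- utils::read.table(config$lengths, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
      log_transform(tpm(cnt, stats::setNames(len_df$length, len_df$gene)))
    } else {
      read_expression_matrix(config$expression)
    }
  })
  meta <- wrap("ingest", {
    m <- utils::read.table(config$metadata, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(m)))
      abort_input("metadata needs 'sample' and 'group' columns")
    missing <- setdiff(colnames(expr), m$sample)
    if (length(missing))
      abort_input("metadata missing sample(s): ",
                  paste(missing, collapse = ", "))
    m[match(colnames(expr), m$sample), , drop = FALSE]
  })
  sig <- if (!is.null(config$signature))
    wrap("signature", read_signature(config$signature)) else NULL
  surv_df <- NULL
  if (config$run_survival) {
    if (!all(c("time", "event") %in% names(meta)))
      abort_input("pipeline stage 'survival' failed: metadata lacks ",
                  "'time'/'event' columns")
    surv_df <- meta[, c("time", "event")]
  }

  res <- run_analysis(expr, meta$group, signature = sig,
                      test = config$test, control = config$control,
                      p_cut = config$p_cut, fc_cut = config$fc_cut,
                      dof = config$dof, survival_df = surv_df)

  paths <- c(signature = file.path(config$out_dir, "signature.txt"),
             stepfits = file.path(config$out_dir, "stepfits.tsv"),
             scores = file.path(config$out_dir, "scores.tsv"),
             classification = file.path(config$out_dir, "classification.json"),
             manifest = file.path(config$out_dir, "manifest.json"))
  writeLines(res$signature, paths[["signature"]])
  utils::write.table(res$fits, paths[["stepfits"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scores_out <- cbind(res$scores, group = meta$group)
  utils::write.table(scores_out, paths[["scores"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(auc = res$auc, positive_class = unname(res$arms[["test"]]),
         welch = res$compare$tests, group_summary = res$compare$summary),
    paths[["classification"]], auto_unbox = TRUE, digits = NA)

  if (!is.null(res$deg)) {
    paths[["deg"]] <- file.path(config$out_dir, "deg.tsv")
    utils::write.table(res$deg, paths[["deg"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(config$gene_sets)) {
    paths[["enrichment"]] <- file.path(config$out_dir, "enrichment.tsv")
    enr <- wrap("enrich", gene_set_enrichment(res$signature, rownames(expr),
                                              read_gmt(config$gene_sets)))
    utils::write.table(enr, paths[["enrichment"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$survival)) {
    paths[["survival"]] <- file.path(config$out_dir, "survival.json")
    jsonlite::write_json(
      list(chisq = res$survival$chisq, df = res$survival$df,
           p = res$survival$p,
           strata = as.list(table(res$survival$stratum)),
           curves = res$survival$curves),
      paths[["survival"]], auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "stepsig",
    version = as.character(utils::packageVersion("stepsig")),
    seed = config$seed,
    thresholds = list(p_cut = config$p_cut, fc_cut = config$fc_cut,
                      dof = config$dof, gap = config$gap),
    config = unclass(config),
    outputs = as.list(paths)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       null = "null", digits = NA)

  res$paths <- paths
  invisible(res)
}
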