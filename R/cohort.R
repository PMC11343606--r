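#' Multivariate ordinary least squares of a marker on covariates
#'
#' Models a per-sample response (e.g. marker expression or positivity) as a
#' linear combination of all other columns of the table. Character/factor
#' covariates are dummy-coded against their alphabetically first level;
#' per-coefficient two-sided t-based p-values test the null of no effect,
#' and 95% confidence intervals are `estimate +/- t_{0.975, n-p} * SE`.
#'
#' @param table data.frame with the response and covariate columns; no
#'   missing cells
#' @param response name of the response column
#' @param conf_level confidence level for the intervals, default 0.95
#' @return data.frame, one row per model term (intercept included):
#'   `term`, `estimate`, `std_error`, `conf_low`, `conf_high`, `t`, `p`
#' @export
multivariate_ols <- function(table, response, conf_level = 0.95) {
  if (!is.data.frame(table)) abort_input("'table' must be a data.frame")
  if (!response %in% names(table))
    abort_input("response column '", response, "' not found")
  if (anyNA(table)) abort_input("missing cells in the covariate table")
  check_number(conf_level, "conf_level", lower = 0, upper = 1,
               strict_lower = TRUE)
  table <- as.data.frame(lapply(table, function(col) {
    if (is.character(col)) factor(col, levels = sort(unique(col))) else col
  }), check.names = FALSE)

  fml <- stats::reformulate(".", response = as.name(response))
  mm <- stats::model.matrix(fml, data = table)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[-qr_mm$pivot[seq_len(qr_mm$rank)]]
    abort_input("rank-deficient design; collinear term(s): ",
                paste(dropped, collapse = ", "))
  }
  if (nrow(mm) <= ncol(mm))
    abort_input("need more samples (", nrow(mm), ") than coefficients (",
                ncol(mm), ")")

  fit <- stats::lm(fml, data = table)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  data.frame(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
             conf_low = ci[, 1], conf_high = ci[, 2], t = sm[, 3],
             p = sm[, 4], row.names = NULL)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per stratum (with Greenwood standard
#' errors, reported but not tested numerically) and the two-group log-rank
#' chi-square (1 df) with its p-value. With no events anywhere the curves
#' are still returned but the test is undefined: statistic and p are `NA`
#' with a warning.
#'
#' @param time positive event/censoring times
#' @param event event indicator (1/TRUE = event, 0/FALSE = censored)
#' @param stratum two-level stratum label per sample (e.g. `"high"`/`"low"`
#'   from [stratify_by_metagene()])
#' @return list of class `km_logrank`: `curves` (data.frame: `stratum`,
#'   `time`, `n_risk`, `n_event`, `survival`, `std_err`), `chisq`, `df`,
#'   `p`, `n` (per-stratum sizes)
#' @export
km_logrank <- function(time, event, stratum) {
  if (any(!is.finite(time)) || any(time <= 0))
    abort_input("'time' must be strictly positive")
  event <- as.integer(as.logical(event))
  stratum <- as.character(stratum)
  if (length(unique(stratum)) != 2L)
    abort_input("exactly two non-empty strata required; got: ",
                paste(unique(stratum), collapse = ", "))
  if (length(time) != length(event) || length(time) != length(stratum))
    abort_input("'time', 'event' and 'stratum' must have equal lengths")

  sf <- survival::survfit(survival::Surv(time, event) ~ stratum)
  labels <- sub("^stratum=", "", names(sf$strata))
  curves <- data.frame(
    stratum = rep(labels, sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv, std_err = sf$surv * sf$std.err
  )

  if (sum(event) == 0L) {
    warning("no events in either stratum; log-rank test undefined")
    chisq <- NA_real_; p <- NA_real_
  } else {
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ stratum)
    chisq <- unname(sd_fit$chisq)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, chisq = chisq, df = 1L, p = p,
                 n = table(stratum)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Kaplan-Meier / log-rank, strata:",
      paste(sprintf("%s (n=%d)", names(x$n), as.integer(x$n)),
            collapse = ", "), "\n")
  if (is.na(x$chisq)) cat("  log-rank undefined (no events)\n")
  else cat(sprintf("  log-rank chi-square = %.4g (1 df), p = %.4g\n",
                   x$chisq, x$p))
  invisible(x)
}

#' Dichotomize samples by signature metagene
#'
#' The metagene is the per-sample mean expression over the signature genes;
#' samples above the cohort median metagene are labelled `"high"`, the rest
#' (including exact ties with the median) `"low"`.
#'
#' @param mat expression matrix (genes x samples, log2(TPM+1) units)
#' @param signature character vector of gene ids; genes absent from the
#'   matrix are reported with a warning and excluded
#' @return named character vector of `"high"`/`"low"` per sample, with the
#'   metagene values in attribute `"metagene"`
#' @export
stratify_by_metagene <- function(mat, signature) {
  mat <- as_gene_matrix(mat)
  if (!is.character(signature) || length(signature) == 0L)
    abort_input("'signature' must be a non-empty character vector")
  present <- intersect(unique(signature), rownames(mat))
  absent <- setdiff(unique(signature), present)
  if (length(absent))
    warning("signature gene(s) not in matrix, excluded: ",
            paste(absent, collapse = ", "))
  if (length(present) == 0L)
    abort_input("no signature gene present in the matrix")
  metagene <- colMeans(mat[present, , drop = FALSE])
  stratum <- ifelse(metagene > stats::median(metagene), "high", "low")
  names(stratum) <- colnames(mat)
  attr(stratum, "metagene") <- metagene
  stratum
}
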