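#' One-step adaptive regression (StepMiner) on an expression vector
#'
#' Fits a single step function to a gene's expression values: the values are
#' sorted ascending, every step position `k` in `1..n-1` is evaluated, and the
#' position minimizing the residual sum of squares is returned. The fitted
#' value is the mean of the low segment (`values[1:k]`) below the step and the
#' mean of the high segment above it. The midpoint of the two segment means is
#' the StepMiner threshold used for all downstream normalization.
#'
#' Sorting first means a single "up" step captures both up- and down-shaped
#' genes; the step sits at the sharpest change between expression levels.
#' Ties in the residual sum of squares are broken by the smallest `k`, so a
#' constant vector yields `k = 1` and a threshold equal to the constant.
#'
#' @param values numeric vector of expression values (typically
#'   log2(TPM+1)), length >= 2, all finite. Order is irrelevant; the fit is
#'   on the sorted values.
#' @param dof degrees of freedom consumed by the adaptive fit (low mean,
#'   high mean, step position); used by the regression statistic. Default 3.
#' @return an object of class `step_fit`: a list with elements
#'   `k` (step position over the sorted values), `mu_low`, `mu_high`,
#'   `fitted` (per sorted position), `sse_step`, `sse_null`
#'   (residual SS around the grand mean), `statistic` (see
#'   [step_statistic()]), `dof`, `threshold` (SThr, the midpoint of the
#'   segment means), `n`, and `sorted` (the sorted input).
#' @seealso [step_statistic()], [step_threshold()], [binarize()],
#'   [fit_step_matrix()]
#' @examples
#' fit <- fit_step(c(1, 1, 1, 5, 5, 5))
#' fit$k          # 3
#' fit$threshold  # 3
#' @export
fit_step <- function(values, dof = 3) {
  if (!is.numeric(values) || length(values) < 2L)
    abort_input("fit_step() needs a numeric vector of length >= 2")
  if (any(!is.finite(values)))
    abort_input("fit_step() input contains non-finite values")
  check_number(dof, "dof", lower = 2, integer = TRUE)

  x <- sort(values)
  n <- length(x)
  xbar <- mean(x)
  sse_null <- sum((x - xbar)^2)

  # Direct per-k evaluation. O(n^2) but exact: segment means and residual
  # sums are computed the obvious way so results match a brute-force oracle
  # bit-for-bit, including tie cases on gridded data.
  sse_k <- vapply(seq_len(n - 1L), function(k) {
    lo <- x[seq_len(k)]
    hi <- x[seq.int(k + 1L, n)]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(sse_k) # first minimum: smallest k on ties

  mu_low <- mean(x[seq_len(k)])
  mu_high <- mean(x[seq.int(k + 1L, n)])
  fitted <- c(rep(mu_low, k), rep(mu_high, n - k))
  sse_step <- sse_k[k]

  fit <- structure(list(
    k = k, mu_low = mu_low, mu_high = mu_high, fitted = fitted,
    sse_step = sse_step, sse_null = sse_null, dof = dof, n = n,
    threshold = (mu_low + mu_high) / 2, sorted = x
  ), class = "step_fit")
  # the statistic needs residual df; for n <= dof the fit itself is still
  # valid (threshold, means) but the statistic is undefined
  fit$statistic <- if (n > dof) step_statistic(fit) else NA_real_
  fit
}

#' Regression test statistic of a step fit
#'
#' F-like ratio of variance explained by the step to residual variance:
#' `((sse_null - sse_step) / (M - 1)) / (sse_step / (n - M))`, with `M` the
#' degrees of freedom of the adaptive fit (default 3: two segment means plus
#' the step position). A zero-residual (perfect) step returns `Inf` so exact
#' comparisons downstream stay exact; a step explaining nothing
#' (`sse_step == sse_null`, e.g. a constant vector) returns 0.
#'
#' @param fit a `step_fit` from [fit_step()]
#' @return a single number in `[0, Inf]`
#' @export
step_statistic <- function(fit) {
  stopifnot(inherits(fit, "step_fit"))
  m <- fit$dof
  if (fit$n <= m)
    abort_input("degenerate fit: n (", fit$n, ") must exceed dof (", m, ")")
  if (fit$sse_null - fit$sse_step <= 0) return(0)
  if (fit$sse_step == 0) return(Inf)
  ((fit$sse_null - fit$sse_step) / (m - 1)) / (fit$sse_step / (fit$n - m))
}

#' StepMiner threshold of a fit
#'
#' The expression level separating the fitted low and high segments:
#' the midpoint `(mu_low + mu_high) / 2`. Always lies within the range of
#' the input values.
#'
#' @param fit a `step_fit` from [fit_step()]
#' @return a single number (same units as the fitted values)
#' @export
step_threshold <- function(fit) {
  stopifnot(inherits(fit, "step_fit"))
  (fit$mu_low + fit$mu_high) / 2
}

#' Binarize expression values against a StepMiner threshold
#'
#' Labels each value `"high"` if above `threshold + gap`, `"low"` if below
#' `threshold - gap`, and `"intermediate"` otherwise. With the default
#' `gap = 0` every value gets a binary label and a value exactly at the
#' threshold is labelled `"low"`.
#'
#' @param values numeric vector
#' @param threshold the per-gene StepMiner threshold (SThr)
#' @param gap non-negative half-width of the intermediate band; default 0
#' @return character vector of labels in `c("low", "intermediate", "high")`
#' @export
binarize <- function(values, threshold, gap = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    abort_input("'threshold' must be a single finite number")
  check_number(gap, "gap", lower = 0)
  out <- rep("intermediate", length(values))
  out[values > threshold + gap] <- "high"
  out[values < threshold - gap] <- "low"
  out[values == threshold & gap == 0] <- "low" # tie rule at gap = 0
  out
}

#' Fit step functions to every gene of an expression matrix
#'
#' Applies [fit_step()] to each row, pooling all samples of the matrix:
#' per-gene thresholds are a per-dataset quantity and are always recomputed
#' within the cohort being analyzed.
#'
#' @param mat numeric matrix, genes as rows (rownames = gene ids), samples
#'   as columns
#' @param dof degrees of freedom passed to [fit_step()]
#' @return data.frame with one row per gene: `gene`, `k`, `mu_low`,
#'   `mu_high`, `SThr`, `statistic`
#' @export
fit_step_matrix <- function(mat, dof = 3) {
  mat <- as_gene_matrix(mat)
  fits <- apply(mat, 1L, fit_step, dof = dof, simplify = FALSE)
  data.frame(
    gene = rownames(mat),
    k = vapply(fits, `[[`, integer(1), "k"),
    mu_low = vapply(fits, `[[`, numeric(1), "mu_low"),
    mu_high = vapply(fits, `[[`, numeric(1), "mu_high"),
    SThr = vapply(fits, `[[`, numeric(1), "threshold"),
    statistic = vapply(fits, `[[`, numeric(1), "statistic"),
    row.names = NULL
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat("StepMiner one-step fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  k = %d, mu_low = %.4g, mu_high = %.4g, SThr = %.4g\n",
              x$k, x$mu_low, x$mu_high, x$threshold))
  cat(sprintf("  SSE(step) = %.4g, SSE(null) = %.4g, statistic = %.4g\n",
              x$sse_step, x$sse_null, x$statistic))
  invisible(x)
}

# Coerce to a numeric matrix with gene rownames; shared input guard.
as_gene_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat))
    abort_input("expected a numeric genes x samples matrix")
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("gene_", seq_len(nrow(mat)))
  if (anyDuplicated(rownames(mat)))
    abort_input("duplicated gene ids: ",
                paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                      collapse = ", "))
  if (any(!is.finite(mat)))
    abort_input("matrix contains non-finite values")
  mat
}
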