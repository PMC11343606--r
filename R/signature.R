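#' Threshold-centered modified Z-score
#'
#' The scalar transform behind [normalize_expression()]:
#' `(expr - SThr) / (3 * stddev)`. Exposed separately so the formula's
#' anchor points are testable directly: a value at the threshold maps to 0
#' and a value three standard deviations above it maps to 1.
#'
#' @param expr numeric values
#' @param SThr the StepMiner threshold
#' @param stddev positive standard deviation used for scaling
#' @return normalized values, same shape as `expr`
#' @export
threshold_normalize <- function(expr, SThr, stddev) {
  if (any(stddev <= 0)) abort_input("'stddev' must be positive")
  (expr - SThr) / (3 * stddev)
}

#' Threshold-centered normalization of an expression matrix
#'
#' Rescales each gene relative to its StepMiner threshold with a modified
#' Z-score: `(expr - SThr) / (3 * stddev)`, where `stddev` is the per-gene
#' sample standard deviation (n-1 denominator) across all samples of the
#' matrix. A value at its gene's threshold maps to exactly 0 and a value
#' three standard deviations above it to exactly 1, so normalized units are
#' "3-sigma steps above threshold" and are comparable across genes.
#'
#' Genes with zero variance cannot be scaled; they are flagged as degenerate,
#' assigned 0 everywhere, and listed in the result rather than dropped, so
#' signatures stay comparable across datasets with censored genes.
#'
#' @param mat numeric matrix of expression values (genes x samples,
#'   typically log2(TPM+1))
#' @param fits per-gene thresholds: either the data.frame returned by
#'   [fit_step_matrix()] (columns `gene`, `SThr`) or a named numeric vector
#'   of thresholds. Every gene of `mat` must have one.
#' @return an object of class `normalized_matrix`: list with `entries`
#'   (same shape as `mat`), `SThr` and `stddev` (named per-gene vectors),
#'   and `degenerate` (character vector of zero-variance gene ids).
#' @export
normalize_expression <- function(mat, fits) {
  mat <- as_gene_matrix(mat)
  thr <- if (is.data.frame(fits)) {
    stats::setNames(fits$SThr, fits$gene)
  } else if (is.numeric(fits) && !is.null(names(fits))) {
    fits
  } else {
    abort_input("'fits' must be a fit_step_matrix() data.frame or a named numeric vector")
  }
  missing <- setdiff(rownames(mat), names(thr))
  if (length(missing))
    abort_input("no step fit for gene(s): ", paste(missing, collapse = ", "))
  thr <- thr[rownames(mat)]

  sds <- apply(mat, 1L, stats::sd)
  degenerate <- rownames(mat)[sds == 0]
  entries <- threshold_normalize(mat, thr, pmax(sds, .Machine$double.xmin))
  entries[sds == 0, ] <- 0

  structure(list(entries = entries, SThr = thr, stddev = sds,
                 degenerate = degenerate),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Threshold-centered normalized matrix: ", nrow(x$entries), " genes x ",
      ncol(x$entries), " samples\n", sep = "")
  if (length(x$degenerate))
    cat("  degenerate (zero-variance) genes: ",
        paste(x$degenerate, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Composite signature score per sample
#'
#' Sums the threshold-centered normalized values of the signature genes in
#' each sample; samples are then rank-ordered by the score (ascending, ties
#' broken by sample id for stability). The sum - not the mean - is the
#' score, so it scales with signature size; set `average = TRUE` only when
#' comparing signatures of different sizes.
#'
#' @param normalized a `normalized_matrix` from [normalize_expression()]
#' @param signature character vector of signature gene ids. Genes absent
#'   from the matrix are reported with a warning and excluded; an empty
#'   effective signature is an error.
#' @param average if TRUE, use the mean over signature genes instead of the
#'   sum. Default FALSE.
#' @return data.frame of class `signature_scores`, one row per sample in
#'   input column order: `sample`, `score`, `rank`. Attribute `signature`
#'   records the gene ids actually used.
#' @export
composite_score <- function(normalized, signature, average = FALSE) {
  stopifnot(inherits(normalized, "normalized_matrix"))
  if (!is.character(signature) || length(signature) == 0L)
    abort_input("'signature' must be a non-empty character vector of gene ids")
  signature <- unique(signature)
  present <- intersect(signature, rownames(normalized$entries))
  absent <- setdiff(signature, present)
  if (length(absent))
    warning("signature gene(s) not in matrix, excluded: ",
            paste(absent, collapse = ", "))
  if (length(present) == 0L)
    abort_input("no signature gene present in the matrix")

  sub <- normalized$entries[present, , drop = FALSE]
  score <- if (average) colMeans(sub) else colSums(sub)
  samples <- colnames(normalized$entries)
  if (is.null(samples)) samples <- paste0("sample_", seq_along(score))
  ord <- order(score, samples) # ascending score, stable ties by sample id
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)

  out <- data.frame(sample = samples, score = unname(score), rank = rank,
                    row.names = NULL)
  attr(out, "signature") <- present
  class(out) <- c("signature_scores", "data.frame")
  out
}

#' ROC area under the curve of a score against binary labels
#'
#' Mann-Whitney formulation: the probability that a uniformly random
#' positive sample outscores a uniformly random negative one, with ties
#' counted 0.5. The positive class is named explicitly by the caller; there
#' is no automatic orientation.
#'
#' @param scores numeric vector
#' @param labels vector of class labels, same length as `scores`; exactly
#'   two distinct values must be present
#' @param positive the label value to treat as positive
#' @return AUC in `[0, 1]`
#' @examples
#' roc_auc(c(1, 2, 2, 3), c("n", "n", "p", "p"), positive = "p") # 0.875
#' @export
roc_auc <- function(scores, labels, positive) {
  if (length(scores) != length(labels))
    abort_input("'scores' and 'labels' differ in length")
  if (any(!is.finite(scores))) abort_input("'scores' must be finite")
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    abort_input("both classes must be present (positive = '", positive, "')")
  if (length(unique(labels)) != 2L)
    abort_input("'labels' must contain exactly two distinct values")
  r <- rank(scores) # midranks: ties contribute 0.5 per pair
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Welch t-tests of a signature score between sample groups
#'
#' Two-sided Welch (unequal-variance) two-sample t-test for every pair of
#' groups, plus per-group summaries suitable for violin-style plotting.
#'
#' @param scores a `signature_scores` data.frame from [composite_score()],
#'   or a numeric vector of per-sample scores
#' @param groups group label per sample (same order as `scores`)
#' @return list with `tests` (data.frame: `group1`, `group2`, `t`, `df`,
#'   `p`) and `summary` (data.frame: `group`, `n`, `mean`, `sd`, `median`)
#' @export
group_compare <- function(scores, groups) {
  x <- if (inherits(scores, "signature_scores")) scores$score else scores
  if (!is.numeric(x)) abort_input("'scores' must be numeric")
  if (length(x) != length(groups))
    abort_input("'groups' must have one label per sample")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  n_by <- table(groups)
  if (any(n_by < 2L))
    abort_input("every group needs >= 2 samples; too small: ",
                paste(names(n_by)[n_by < 2L], collapse = ", "))

  pairs <- utils::combn(lev, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- x[groups == pairs[1L, j]]
    b <- x[groups == pairs[2L, j]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      # identical constant groups: no evidence of difference
      data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
                 t = 0, df = length(a) + length(b) - 2, p = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  }))
  summary <- do.call(rbind, lapply(lev, function(g) {
    v <- x[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v))
  }))
  list(tests = tests, summary = summary)
}
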