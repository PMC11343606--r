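#' Transcripts-per-million summarization of a count matrix
#'
#' Length-normalizes counts to per-kilobase-free rates
#' (`count / gene_length`) and rescales each sample so its rates sum to
#' 10^6. Every column of the result sums to 10^6 exactly (up to floating
#' point); doubling all counts of a sample leaves its TPM unchanged.
#'
#' @param counts non-negative integer matrix, genes x samples
#' @param gene_lengths positive gene lengths in bp; named vector matched to
#'   rownames of `counts`, or unnamed in row order
#' @return numeric matrix of TPM values, same dimnames as `counts`
#' @export
tpm <- function(counts, gene_lengths) {
  counts <- as_gene_matrix(counts)
  if (any(counts < 0)) abort_input("counts must be non-negative")
  len <- gene_lengths
  if (!is.null(names(len))) {
    missing <- setdiff(rownames(counts), names(len))
    if (length(missing))
      abort_input("no gene length for: ", paste(missing, collapse = ", "))
    len <- len[rownames(counts)]
  }
  if (length(len) != nrow(counts))
    abort_input("'gene_lengths' must have one entry per gene")
  if (any(!is.finite(len)) || any(len <= 0))
    abort_input("gene lengths must be strictly positive")

  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero))
    abort_input("all-zero sample column(s): ",
                paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2L, tot, `/`) * 1e6
}

#' log2(x + 1) transform
#'
#' The final expression unit of the pipeline: `log2(TPM + 1)`. Zero maps to
#' zero and the transform is monotone, so within-sample gene ordering is
#' preserved.
#'
#' @param x non-negative numeric matrix or vector (TPM units)
#' @return same shape, entrywise `log2(x + 1)`
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort_input("negative values in input")
  log2(x + 1)
}

# Vectorized Welch two-sample t on matrix rows; returns t, df, p.
welch_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # zero-variance rows: identical constant arms carry no evidence (t = 0,
  # p = 1); constant arms at different levels separate perfectly
  flat <- se2 == 0
  t[flat] <- sign(m1 - m2)[flat] * Inf
  t[flat & m1 == m2] <- 0
  df[flat] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean1 = m1, mean2 = m2)
}

#' Differential expression between two arms with the signature filters
#'
#' A deliberately simple two-group engine: per-gene Welch two-sided t-test
#' on log2(TPM+1) values, with fold-change computed on linear TPM means
#' with a pseudocount of 1 (so all-zero genes are defined:
#' `FC = (mean_test + 1) / (mean_control + 1)`). This is a stand-in for a
#' negative-binomial GLM engine; the downstream contract - the list of
#' genes passing `P <= p_cut` and `fold-change >= fc_cut` in a direction -
#' is preserved. Benjamini-Hochberg adjusted p-values are reported
#' alongside raw p; the default selection rule uses raw p (set
#' `use_adjusted = TRUE` to select on adjusted p instead).
#'
#' @param mat expression matrix in log2(TPM+1) units, genes x samples
#' @param groups arm label per sample (exactly two distinct values)
#' @param test,control the labels of the test and control arms; by default
#'   the second and first sorted distinct labels
#' @param p_cut raw-p threshold, default 0.05
#' @param fc_cut linear fold-change threshold, default 2
#' @param use_adjusted select on BH-adjusted p instead of raw p
#' @return data.frame of class `deg_table`, one row per gene: `gene`,
#'   `mean_test`, `mean_control` (linear TPM), `fold_change` (linear,
#'   test / control with pseudocount 1), `t`, `p`, `p_adj`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `passes`. Attributes record thresholds and
#'   arm labels.
#' @export
differential_expression <- function(mat, groups, test = NULL, control = NULL,
                                    p_cut = 0.05, fc_cut = 2,
                                    use_adjusted = FALSE) {
  mat <- as_gene_matrix(mat)
  if (length(groups) != ncol(mat))
    abort_input("'groups' must have one label per sample column")
  check_number(p_cut, "p_cut", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(fc_cut, "fc_cut", lower = 1)
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L)
    abort_input("exactly two arms required; got: ", paste(lev, collapse = ", "))
  if (is.null(control)) control <- lev[1L]
  if (is.null(test)) test <- setdiff(lev, control)
  if (!all(c(test, control) %in% lev))
    abort_input("'test'/'control' must match the group labels")
  idx_t <- which(groups == test)
  idx_c <- which(groups == control)
  if (length(idx_t) < 2L || length(idx_c) < 2L)
    abort_input("each arm needs >= 2 samples (test: ", length(idx_t),
                ", control: ", length(idx_c), ")")

  w <- welch_rows(mat, idx_t, idx_c)
  lin <- 2^mat - 1 # back to linear TPM
  mt <- rowMeans(lin[, idx_t, drop = FALSE])
  mc <- rowMeans(lin[, idx_c, drop = FALSE])
  fc <- (mt + 1) / (mc + 1)
  p_adj <- bh_adjust(w$p)
  p_sel <- if (use_adjusted) p_adj else w$p
  direction <- ifelse(fc >= fc_cut, "up",
                      ifelse(fc <= 1 / fc_cut, "down", "none"))
  passes <- p_sel <= p_cut & direction != "none"

  out <- data.frame(gene = rownames(mat), mean_test = mt, mean_control = mc,
                    fold_change = fc, t = w$t, p = w$p, p_adj = p_adj,
                    direction = direction, passes = passes, row.names = NULL)
  attr(out, "thresholds") <- list(p_cut = p_cut, fc_cut = fc_cut,
                                  use_adjusted = use_adjusted)
  attr(out, "arms") <- c(test = test, control = control)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Extract the passing gene list from a DEG table
#'
#' @param deg a `deg_table` from [differential_expression()]
#' @param direction `"up"` (default: up in the test arm), `"down"`, or
#'   `"both"`
#' @return character vector of gene ids
#' @export
signature_genes <- function(deg, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(inherits(deg, "deg_table"))
  keep <- deg$passes & (direction == "both" | deg$direction == direction)
  deg$gene[keep]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: sort p ascending, multiply by `n / rank`, enforce
#' monotonicity from the largest down, cap at 1; output in input order.
#' Adjusted values are never below the raw ones.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same length and order
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0) || any(pvals > 1))
    abort_input("p-values must be finite and within [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric gene-set enrichment of a hit list
#'
#' For each set, tests over-representation of `hits` among the set's
#' members restricted to `universe`, by the hypergeometric upper tail
#' (probability of an overlap at least as large under uniform sampling of
#' `|hits|` genes from the universe). Fold enrichment is the observed hit
#' fraction in the set over the expected fraction:
#' `(overlap / |hits|) / (|set n universe| / |universe|)`.
#'
#' @param hits character vector of hit gene ids; must be a subset of
#'   `universe`
#' @param universe character vector of all assayed gene ids
#' @param sets named list of character vectors (e.g. from [read_gmt()])
#' @return data.frame, one row per set: `set`, `set_size` (within
#'   universe), `overlap`, `fold_enrichment`, `p`, `p_adj` (BH across
#'   sets), sorted by `p`
#' @export
gene_set_enrichment <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  if (length(sets) == 0L) abort_input("'sets' is empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort_input("'sets' must be a named list")
  out_of_universe <- setdiff(hits, universe)
  if (length(out_of_universe))
    abort_input("hit gene(s) absent from universe: ",
                paste(out_of_universe, collapse = ", "))
  n_u <- length(universe); n_h <- length(hits)
  if (n_h == 0L) abort_input("'hits' is empty")

  rows <- lapply(names(sets), function(nm) {
    in_u <- intersect(sets[[nm]], universe)
    k <- length(intersect(hits, in_u))
    K <- length(in_u)
    fold <- if (K == 0L) 0 else (k / n_h) / (K / n_u)
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, n_u - K, n_h, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               fold_enrichment = fold, p = p)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res[order(res$p, res$set), , drop = FALSE]
}
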