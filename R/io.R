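#' Read a genes x samples expression or count matrix
#'
#' First column: gene ids; header row: sample ids. Delimiter is sniffed
#' from the extension (`.csv` = comma, anything else = tab). Duplicate gene
#' ids and missing cells are errors (missing cells are reported with their
#' gene/sample coordinates). With `counts = TRUE` the matrix is validated
#' as non-negative integers and returned in integer storage.
#'
#' @param path file path (TSV or CSV)
#' @param counts validate/ingest as a count matrix
#' @return numeric matrix with gene rownames and sample colnames
#' @export
read_expression_matrix <- function(path, counts = FALSE) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    abort_input("duplicated gene id(s) in ", path, ": ",
                paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) abort_input("non-numeric cells in ", path)
  rownames(mat) <- genes
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    abort_input("missing cell(s) in ", path, " at: ",
                paste(sprintf("(%s, %s)", genes[idx[, 1]],
                              colnames(mat)[idx[, 2]]), collapse = ", "))
  }
  if (counts) {
    if (any(mat < 0) || any(mat != round(mat)))
      abort_input("count matrix must contain non-negative integers: ", path)
    storage.mode(mat) <- "integer"
  }
  mat
}

#' Write a genes x samples matrix as TSV/CSV
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (header `gene`), sample ids in the header row.
#'
#' @param mat matrix with gene rownames and sample colnames
#' @param path output path; `.csv` writes comma-separated, else tabs
#' @return invisibly, `path`
#' @export
write_expression_matrix <- function(mat, path) {
  mat <- as_gene_matrix(mat)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature gene list
#'
#' One gene id per line; blank lines and `#` comments (whole-line or
#' trailing) are ignored.
#'
#' @param path file path
#' @return character vector of gene ids
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- lines[nzchar(lines)]
  if (length(genes) == 0L) abort_input("empty signature file: ", path)
  genes
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path
#' @return named list of character vectors; set descriptions in attribute
#'   `"descriptions"`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_input("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    abort_input("malformed GMT line(s) (need name, description, >=1 gene): ",
                paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    abort_input("duplicated set name(s) in ", path)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional per-set descriptions (recycled `"na"`)
#' @return invisibly, `path`
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) abort_input("'sets' must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample survival table
#'
#' TSV with columns `sample`, `time`, `event` (0/1).
#'
#' @param path file path
#' @return data.frame with validated columns
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_input("survival table missing column(s): ",
                paste(miss, collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    abort_input("survival times must be strictly positive")
  if (!all(df$event %in% c(0, 1)))
    abort_input("'event' must be 0/1")
  df
}
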