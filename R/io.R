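## Delimited-text readers and writers. Matrices are genes-in-rows with a
## header row of sample identifiers and gene identifiers in the first
## column; tab is the default delimiter, comma is auto-detected.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file is empty: ", path)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a normalized expression matrix
#'
#' Expects rectangular delimited text with sample identifiers in the header
#' and gene identifiers in the first column. Continuous and integer values
#' are both accepted; negative, missing or non-numeric cells are rejected
#' with their gene/sample location.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return genes x samples numeric matrix with unique dimnames.
#' @export
readExpression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"")
  if (ncol(df) < 2L) stop("expected gene ids plus at least one sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate sample identifiers in header")
  m <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1L]))
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "invalid (negative or non-numeric) value at gene '%s', sample '%s'",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  m
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]: tab-delimited, gene ids in a first column
#' named `gene_id`.
#'
#' @param m genes x samples matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' One row per sample: sample identifiers in the first column, a group
#' column, and optional numeric covariate columns.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` auto-detects.
#' @param group name of the group column (default `"group"`).
#' @param covariates names of covariate columns; `NULL` (default) takes
#'   every numeric column other than the group column.
#' @return `data.frame` with rownames = sample ids, a factor `group` column
#'   (levels in order of first appearance) and numeric covariates, plus
#'   attribute `"covariates"` naming them.
#' @export
readDesign <- function(path, sep = NULL, group = "group",
                       covariates = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected sample ids plus a group column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in design")
  if (!(group %in% colnames(df)))
    stop(sprintf("design lacks group column '%s'", group))
  out <- df[-1L]
  rownames(out) <- ids
  out[[group]] <- factor(out[[group]],
                         levels = unique(as.character(out[[group]])))
  if (is.null(covariates))
    covariates <- setdiff(colnames(out)[vapply(out, is.numeric, logical(1))],
                          group)
  for (v in covariates)
    if (!is.numeric(out[[v]]))
      stop(sprintf("covariate column '%s' is not numeric", v))
  attr(out, "covariates") <- covariates
  out
}

#' Read expression and design into a ZIExpDataSet
#'
#' @param exprPath expression matrix file (see [readExpression()]).
#' @param designPath design table file (see [readDesign()]).
#' @param sep delimiter for both files; `NULL` auto-detects.
#' @param group,covariates passed to [readDesign()].
#' @return A [ZIExpDataSet-class]; design rows are matched to expression
#'   columns by sample identifier, and a mismatch is an error.
#' @export
readZIExpDataSet <- function(exprPath, designPath, sep = NULL,
                             group = "group", covariates = NULL) {
  m <- readExpression(exprPath, sep)
  d <- readDesign(designPath, sep, group, covariates)
  missing <- setdiff(rownames(d), colnames(m))
  extra <- setdiff(colnames(m), rownames(d))
  if (length(missing) || length(extra))
    stop("design/expression sample mismatch: ",
         paste(c(missing, extra), collapse = ", "))
  d <- d[colnames(m), , drop = FALSE]
  ZIExpDataSet(m, colData = d, group = group,
               covariates = attr(d, "covariates"))
}

#' Write a differential expression results table
#'
#' Tab-delimited, one row per gene: gene id, natural-scale group means,
#' `log2FoldChange`, `pi`, `stat`, `df`, `pvalue`, `padj`, optional
#' `empiricalP`/`empiricalPadj`, `status`. Missing values are written as
#' literal `NA`. Warns (and writes a header-only file) when `results` is
#' empty.
#'
#' @param results a [ZIExpResults-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  df <- as.data.frame(results)
  df <- data.frame(gene_id = rownames(df), df, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) warning("writing an empty results table")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table
#'
#' @param path file written by [writeResults()].
#' @return `data.frame` with `gene_id` as rownames.
#' @export
readResults <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  rownames(df) <- df$gene_id
  df
}
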