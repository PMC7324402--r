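#' Gene-by-position expression matrix
#'
#' Non-negative FPKM-like values; rows are genes (unique IDs), columns are
#' ordered positions along the axis (anterior to posterior). The column
#' order is explicit metadata and is never inferred from label sorting.
#'
#' @param values numeric matrix with rownames = gene IDs and colnames =
#'   position labels.
#' @param batch batch label (single string).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, batch = "A") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stopf("expression matrix needs gene IDs as rownames")
  if (anyDuplicated(rownames(values))) stopf("duplicate gene IDs")
  if (is.null(colnames(values))) stopf("expression matrix needs position labels as colnames")
  if (ncol(values) < 2L) stopf("need at least 2 positions")
  if (any(values < 0)) stopf("expression values must be non-negative")
  storage.mode(values) <- "double"
  structure(list(values = values, batch = as.character(batch)[1]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d positions (batch %s)\n",
              nrow(x$values), ncol(x$values), x$batch))
  cat("  positions:", paste(colnames(x$values), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Row 1 = position labels, column 1 = gene IDs.
#'
#' @param path file path.
#' @param batch batch label to attach.
#' @return An `expr_matrix`.
#' @export
read_expr_tsv <- function(path, batch = "A") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  expr_matrix(as.matrix(df), batch = batch)
}

#' Write an expression matrix as TSV
#'
#' @param expr an `expr_matrix`.
#' @param path destination file.
#' @export
write_expr_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
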