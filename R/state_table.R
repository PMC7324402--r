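#' Binary module state table
#'
#' An m x P matrix of module activity (rows `M1..Mm`, columns = ordered
#' positions along the axis). When `terminal_duplicated` is `TRUE` the last
#' column is a duplicate of the preceding one, encoding the assumption that
#' the pattern stays constant beyond the last sampled position (inside the
#' morphogen-producing compartment).
#'
#' @param states 0/1 matrix, modules in rows, positions in columns.
#' @param terminal_duplicated logical; whether the last column duplicates the
#'   previous one.
#' @return An object of class `state_table`.
#' @export
state_table <- function(states, terminal_duplicated = FALSE) {
  states <- as.matrix(states)
  if (!all(states %in% c(0L, 1L))) stopf("state table entries must be 0 or 1")
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) rownames(states) <- paste0("M", seq_len(nrow(states)))
  if (is.null(colnames(states))) colnames(states) <- paste0("P", seq_len(ncol(states)))
  if (terminal_duplicated) {
    p <- ncol(states)
    if (p < 2L) stopf("a terminal-duplicated table needs at least 2 columns")
    if (!identical(states[, p], states[, p - 1L]))
      stopf("terminal_duplicated is set but the last two columns differ")
  }
  structure(list(states = states, terminal_duplicated = isTRUE(terminal_duplicated)),
            class = "state_table")
}

#' Append a duplicated terminal column to a state table
#'
#' @param tab a `state_table` without duplicated terminal.
#' @param label column label for the duplicate; default appends `"*"`.
#' @return A `state_table` with one extra column.
#' @export
duplicate_terminal <- function(tab, label = NULL) {
  stopifnot(inherits(tab, "state_table"))
  if (tab$terminal_duplicated) return(tab)
  s <- tab$states
  p <- ncol(s)
  if (is.null(label)) label <- paste0(colnames(s)[p], "*")
  s2 <- cbind(s, s[, p])
  colnames(s2) <- c(colnames(s), label)
  state_table(s2, terminal_duplicated = TRUE)
}

# columns that were actually observed (drops the duplicated terminal column)
observed_states <- function(tab) {
  stopifnot(inherits(tab, "state_table"))
  s <- tab$states
  if (tab$terminal_duplicated) s[, -ncol(s), drop = FALSE] else s
}

#' @export
print.state_table <- function(x, ...) {
  s <- x$states
  cat(sprintf("Binary module state table: %d modules x %d positions%s\n",
              nrow(s), ncol(s),
              if (x$terminal_duplicated) " (terminal duplicated)" else ""))
  for (j in seq_len(ncol(s)))
    cat(sprintf("  %-6s %s\n", colnames(s)[j], paste(s[, j], collapse = "")))
  invisible(x)
}

#' @export
dim.state_table <- function(x) dim(x$states)

#' Read a binary state table from a 0/1 TSV
#'
#' Expects module rows and position columns, first column = module labels,
#' first row = position labels.
#'
#' @param path file path.
#' @param terminal_duplicated whether the last column is the duplicated
#'   terminal column.
#' @return A `state_table`.
#' @export
read_state_table <- function(path, terminal_duplicated = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  state_table(as.matrix(df), terminal_duplicated = terminal_duplicated)
}

#' Write a binary state table as a 0/1 TSV
#'
#' @param tab a `state_table`.
#' @param path file path.
#' @export
write_state_table <- function(tab, path) {
  stopifnot(inherits(tab, "state_table"))
  df <- data.frame(module = rownames(tab$states), tab$states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
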