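#' Gene-to-module assignment
#'
#' @param module_of named integer vector mapping gene ID to module index
#'   `1..m`.
#' @param m module count.
#' @return A `module_assignment`.
#' @export
module_assignment <- function(module_of, m = max(module_of)) {
  module_of <- stats::setNames(as.integer(module_of), names(module_of))
  if (is.null(names(module_of))) stopf("module_of must be named by gene ID")
  if (any(module_of < 1L | module_of > m)) stopf("module indices must lie in 1..m")
  if (length(setdiff(seq_len(m), unique(module_of))))
    stopf("every module must be non-empty; missing: %s",
          paste0("M", setdiff(seq_len(m), unique(module_of)), collapse = ", "))
  structure(list(module_of = module_of, m = as.integer(m)), class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("Module assignment: %d genes in %d modules\n",
              length(x$module_of), x$m))
  print(table(factor(paste0("M", x$module_of), levels = paste0("M", seq_len(x$m)))))
  invisible(x)
}

#' Cluster genes into positional modules
#'
#' Hierarchical clustering of per-gene z-scored profiles (default distance
#' 1 - Pearson correlation, Ward linkage), cut into `m` groups. Ward linkage
#' is the default because single-linkage-like chaining under average linkage
#' lets noisy outlier genes claim whole clusters at realistic panel sizes;
#' `linkage = "average"` remains available. Modules
#' are renumbered by where their mean profile first rises above its own
#' average (earliest activation = M1), so labels are reproducible.
#'
#' @param expr an `expr_matrix`.
#' @param m number of modules (default 12).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust].
#' @return A `module_assignment`.
#' @export
cluster_genes <- function(expr, m = 12L, distance = c("pearson", "euclidean"),
                          linkage = "ward.D2") {
  stopifnot(inherits(expr, "expr_matrix"))
  distance <- match.arg(distance)
  v <- expr$values
  if (m > nrow(v)) stopf("m (%d) exceeds the gene count (%d)", m, nrow(v))
  sds <- apply(v, 1, stats::sd)
  z <- (v - rowMeans(v)) / ifelse(sds > 0, sds, 1)
  d <- if (distance == "pearson") {
    cc <- suppressWarnings(stats::cor(t(z)))
    cc[!is.finite(cc)] <- 0      # zero-variance profiles: maximal uncertainty
    stats::as.dist(1 - cc)
  } else {
    stats::dist(z)
  }
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = m)
  # renumber by the onset of above-average activation of the mean profile
  # (earliest = M1), with the centre of the active region and the argmax as
  # tie-breaks; onset/centre are robust to small ripples that move the argmax
  keys <- vapply(seq_len(m), function(g) {
    prof <- colMeans(z[cl == g, , drop = FALSE])
    act <- which(prof > mean(prof))
    if (!length(act)) act <- which.max(prof)
    c(act[1], mean(act), which.max(prof))
  }, numeric(3))
  relabel <- integer(m)
  relabel[order(keys[1L, ], keys[2L, ], keys[3L, ], seq_len(m))] <- seq_len(m)
  module_assignment(stats::setNames(relabel[cl], rownames(v)), m = m)
}

#' Binarize genes against their across-position mean
#'
#' An entry is 1 iff the value strictly exceeds that gene's mean across
#' positions (so a constant gene is all 0). The result is invariant under
#' any strictly increasing affine transform applied per gene row.
#'
#' @param expr an `expr_matrix`.
#' @return 0/1 integer matrix with the input's dimnames.
#' @export
binarize_genes <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  bin <- (v > rowMeans(v)) * 1L
  storage.mode(bin) <- "integer"
  bin
}

#' Module states by strict majority vote
#'
#' Module i is ON at position j iff strictly more than half of its member
#' genes are 1 there (ties are OFF). Optionally appends a duplicate of the
#' terminal column, encoding pattern constancy beyond the last position.
#'
#' @param bin gene-level 0/1 matrix (genes x positions).
#' @param assignment a `module_assignment` covering every gene in `bin`.
#' @param duplicate_terminal append the duplicated terminal column
#'   (default TRUE).
#' @return A `state_table`.
#' @export
module_states <- function(bin, assignment, duplicate_terminal = TRUE) {
  stopifnot(inherits(assignment, "module_assignment"))
  bin <- as.matrix(bin)
  miss <- setdiff(rownames(bin), names(assignment$module_of))
  if (length(miss))
    stopf("genes without module assignment: %s", paste(utils::head(miss, 5), collapse = ", "))
  m <- assignment$m
  states <- matrix(0L, nrow = m, ncol = ncol(bin),
                   dimnames = list(paste0("M", seq_len(m)), colnames(bin)))
  for (i in seq_len(m)) {
    genes <- names(assignment$module_of)[assignment$module_of == i]
    genes <- intersect(genes, rownames(bin))
    if (!length(genes)) stopf("module M%d has no genes in the binary matrix", i)
    sub <- bin[genes, , drop = FALSE]
    states[i, ] <- as.integer(colSums(sub) > nrow(sub) / 2)
  }
  tab <- state_table(states, terminal_duplicated = FALSE)
  if (duplicate_terminal) duplicate_terminal(tab) else tab
}
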