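#' Screen morphogen-responsive genes by monotone fold-change runs
#'
#' A gene passes when some run of `window_intervals` consecutive
#' position-to-position intervals is direction-consistent, every interval in
#' the run changing by at least `fold` (larger value over smaller, computed
#' on `value + eps`). With `fold = 1` the criterion degrades to plain
#' monotonicity (flat intervals count for either direction).
#'
#' @param expr an `expr_matrix`.
#' @param window_intervals number of consecutive intervals that must agree
#'   (default 4, spanning 5 positions).
#' @param fold minimum per-interval fold change (default 2).
#' @param eps pseudo-count guarding zero values; defaults to `1e-6` of the
#'   smallest positive value in the matrix.
#' @return Character vector of passing gene IDs, in input row order.
#' @export
screen_mrgs <- function(expr, window_intervals = 4L, fold = 2, eps = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (window_intervals < 1L) stopf("window_intervals must be >= 1")
  if (fold < 1) stopf("fold must be >= 1")
  v <- expr$values
  ni <- ncol(v) - 1L
  if (window_intervals > ni)
    stopf("window_intervals (%d) exceeds the %d intervals available", window_intervals, ni)
  if (is.null(eps)) {
    pos <- v[v > 0]
    eps <- if (length(pos)) 1e-6 * min(pos) else 1e-6
  }
  if (eps <= 0) stopf("eps must be > 0")
  num <- v[, -1L, drop = FALSE] + eps
  den <- v[, -ncol(v), drop = FALSE] + eps
  # small relative tolerance so an exact `fold`-change is not rejected by the
  # pseudo-count's pull of the ratio toward 1
  tol <- 2e-6
  up <- num >= fold * den * (1 - tol)
  down <- num * fold <= den * (1 + tol)
  run_hit <- function(mat) {
    hit <- mat[, seq_len(ni - window_intervals + 1L), drop = FALSE]
    if (window_intervals > 1L)
      for (o in seq_len(window_intervals - 1L))
        hit <- hit & mat[, o + seq_len(ni - window_intervals + 1L), drop = FALSE]
    rowSums(hit) > 0
  }
  pass <- run_hit(up) | run_hit(down)
  rownames(v)[pass]
}

#' Intersect two screened gene sets and report coverage
#'
#' @param setA,setB character vectors of gene IDs passing the screen in each
#'   sample set.
#' @return A `screen_result`: list with `passing` (both input sets),
#'   `common` (the intersection) and `coverage`, the percentage of each
#'   input set contained in the intersection, rounded to two decimals
#'   (`NA` with a warning for an empty input set).
#' @export
common_mrgs <- function(setA, setB) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  common <- intersect(setA, setB)
  cov <- function(s, name) {
    if (!length(s)) { warnf("%s is empty; coverage undefined", name); return(NA_real_) }
    round(100 * length(common) / length(s), 2)
  }
  structure(list(passing = list(A = setA, B = setB), common = common,
                 coverage = c(A = cov(setA, "setA"), B = cov(setB, "setB"))),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("MRG screen: |A| = %d, |B| = %d, common = %d (%.2f%% of A, %.2f%% of B)\n",
              length(x$passing$A), length(x$passing$B), length(x$common),
              x$coverage[["A"]], x$coverage[["B"]]))
  invisible(x)
}

#' Integrate two staggered sample sets into one ordered matrix
#'
#' Restricts both batches to `genes`, removes the batch effect per gene on
#' the log2 scale (a pseudo-count of 1e-6 of the smallest positive value
#' guards zero entries) with [limma::removeBatchEffect], so each gene's
#' per-batch mean on the log scale is equalized — a pure multiplicative
#' batch offset is removed exactly. Values are back-transformed and the
#' columns assembled in the user-supplied anterior-to-posterior
#' interleaving.
#'
#' The interleaving is subjective in the source protocol (guided by marker
#' genes), so it is config here; optional marker IDs are validated with
#' warnings: an `hh`-like marker should peak exclusively at the terminal
#' (posterior) position and a `dpp`-like marker in the interior.
#'
#' @param exprA,exprB `expr_matrix` objects (distinct batch labels assumed).
#' @param order data frame with columns `batch` (matching the two batch
#'   labels) and `position` (a column label of that batch), in the desired
#'   anterior-to-posterior order.
#' @param genes gene IDs to keep; must be present in both batches.
#' @param hh_like,dpp_like optional marker gene IDs for sanity warnings.
#' @return An `expr_matrix` with batch label `"integrated"`.
#' @export
integrate_samples <- function(exprA, exprB, order, genes,
                              hh_like = NULL, dpp_like = NULL) {
  stopifnot(inherits(exprA, "expr_matrix"), inherits(exprB, "expr_matrix"))
  order <- as.data.frame(order)
  if (!all(c("batch", "position") %in% names(order)))
    stopf("`order` needs columns 'batch' and 'position'")
  genes <- unique(as.character(genes))
  missA <- setdiff(genes, rownames(exprA$values))
  missB <- setdiff(genes, rownames(exprB$values))
  if (length(missA) || length(missB))
    stopf("genes missing from batch %s: %s%sbatch %s: %s",
          exprA$batch, paste(utils::head(missA, 5), collapse = ", "),
          if (length(missA) && length(missB)) "; " else "",
          exprB$batch, paste(utils::head(missB, 5), collapse = ", "))
  batches <- c(exprA$batch, exprB$batch)
  bad <- !(order$batch %in% batches)
  if (any(bad)) stopf("unknown batch label(s) in `order`: %s",
                      paste(unique(order$batch[bad]), collapse = ", "))
  for (i in seq_len(nrow(order))) {
    e <- if (order$batch[i] == exprA$batch) exprA else exprB
    if (!(order$position[i] %in% colnames(e$values)))
      stopf("position '%s' not found in batch %s", order$position[i], order$batch[i])
  }
  A <- exprA$values[genes, , drop = FALSE]
  B <- exprB$values[genes, , drop = FALSE]
  comb <- cbind(A, B)
  pos <- comb[comb > 0]
  lg_eps <- if (length(pos)) 1e-6 * min(pos) else 1e-6
  logmat <- log2(comb + lg_eps)
  batch <- rep(batches, c(ncol(A), ncol(B)))
  adj <- if (batches[1] == batches[2]) logmat
         else limma::removeBatchEffect(logmat, batch = batch)
  back <- pmax(2^adj - lg_eps, 0)
  pick <- vapply(seq_len(nrow(order)), function(i) {
    off <- if (order$batch[i] == exprA$batch) 0L else ncol(A)
    e <- if (order$batch[i] == exprA$batch) A else B
    off + match(order$position[i], colnames(e))
  }, integer(1))
  out <- back[, pick, drop = FALSE]
  colnames(out) <- order$position
  res <- expr_matrix(out, batch = "integrated")
  check_marker <- function(id, what, terminal) {
    if (is.null(id) || !(id %in% rownames(out))) return(invisible())
    peak <- which.max(out[id, ])
    if (terminal && peak != ncol(out))
      warnf("%s marker '%s' does not peak at the terminal position", what, id)
    if (!terminal && (peak == 1L || peak == ncol(out)))
      warnf("%s marker '%s' does not peak in the interior", what, id)
  }
  check_marker(hh_like, "hh-like", terminal = TRUE)
  check_marker(dpp_like, "dpp-like", terminal = FALSE)
  res
}
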