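#' Infer a Boolean network from a spatial state sequence
#'
#' Treats consecutive columns of the module state table as synchronous
#' transitions \eqn{S(j) \to S(j+1)} and, for each module, searches regulator
#' subsets in order of increasing size (lexicographic within a size).
#'
#' With `method = "consistent"` the first subset on which the observed
#' transitions are consistent is returned — no two transitions with the same
#' regulator pattern may disagree on the module's next state — and an
#' unsatisfiable-inference error is raised when no subset within
#' `max_indegree` is consistent. With `method = "bestfit"` (the best-fit
#' extension familiar from Boolean-network reconstruction tools) the first
#' subset achieving the minimal number of violated transitions is returned,
#' with the majority output per regulator pattern; it never fails, and
#' coincides with `"consistent"` whenever a consistent subset exists.
#'
#' Truth-table rows never observed are filled by the `completion` policy.
#' Under `"consistent"` the returned network exactly reproduces every
#' observed transition.
#'
#' @param table a `state_table` with at least 2 columns (the duplicated
#'   terminal column, if present, contributes the fixed-point transition).
#' @param max_indegree largest regulator subset size searched (default 4).
#' @param completion value for unseen truth-table rows: `"zero"` (inactive,
#'   default) or `"majority"` (most frequent observed output for the module,
#'   ties to 0).
#' @param method `"consistent"` (default) or `"bestfit"`; see Details.
#' @return A `boolean_network`.
#' @export
infer_network <- function(table, max_indegree = 4L,
                          completion = c("zero", "majority"),
                          method = c("consistent", "bestfit")) {
  stopifnot(inherits(table, "state_table"))
  completion <- match.arg(completion)
  method <- match.arg(method)
  s <- table$states
  m <- nrow(s)
  if (ncol(s) < 2L) stopf("need at least 2 columns to observe a transition")
  if (max_indegree > m) stopf("max_indegree (%d) cannot exceed module count (%d)", max_indegree, m)
  X <- s[, -ncol(s), drop = FALSE]           # states at j
  Y <- s[, -1L, drop = FALSE]                # states at j+1
  nt <- ncol(X)
  combos <- lapply(0:max_indegree, function(k) {
    if (k == 0L) matrix(integer(0), nrow = 0L, ncol = 1L) else utils::combn(m, k)
  })
  fns <- vector("list", m)
  for (i in seq_len(m)) {
    y <- Y[i, ]
    best <- NULL
    for (k in 0:max_indegree) {
      cs <- combos[[k + 1L]]
      for (ci in seq_len(ncol(cs))) {
        regs <- cs[, ci]
        idx <- if (k == 0L) rep(1L, nt)
               else 1L + as.integer(crossprod(X[regs, , drop = FALSE], 2^(seq_len(k) - 1L)))
        n1 <- tabulate(idx[y == 1L], nbins = 2^k)
        n0 <- tabulate(idx[y == 0L], nbins = 2^k)
        err <- sum(pmin(n0, n1))
        if (is.null(best) || err < best$err)
          best <- list(err = err, regs = regs, idx = idx, n0 = n0, n1 = n1)
        if (best$err == 0L) break
      }
      if (best$err == 0L) break
    }
    if (method == "consistent" && best$err > 0L) {
      dup <- which(duplicated(t(X)) | duplicated(t(X), fromLast = TRUE))
      conflict <- dup[vapply(dup, function(j) {
        any(vapply(dup, function(l) all(X[, j] == X[, l]) && Y[i, j] != Y[i, l], logical(1)))
      }, logical(1))]
      if (length(conflict))
        stopf(paste0("no consistent rule for M%d: transitions from identical states ",
                     "disagree at columns %s"), i, paste(conflict, collapse = ", "))
      stopf("no consistent rule for M%d within max_indegree = %d", i, max_indegree)
    }
    k <- length(best$regs)
    tt <- integer(2^k)
    seen <- best$n0 + best$n1 > 0L
    tt[seen] <- as.integer(best$n1[seen] > best$n0[seen])  # majority, ties -> 0
    if (any(!seen)) {
      fill <- if (completion == "zero") 0L
              else as.integer(sum(y == 1L) > sum(y == 0L))
      tt[!seen] <- fill
    }
    fns[[i]] <- boolean_function(i, best$regs, tt)
  }
  boolean_network(fns)
}
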