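#' Generate a random Boolean module network
#'
#' Each module gets at most `max_indegree` regulators (uniform 0..max) drawn
#' without replacement and a uniform random truth table; the AND/OR/NOT
#' expression text is synthesized from the truth table. All randomness flows
#' through the supplied seed; the global RNG state is untouched.
#'
#' @param m module count (>= 1).
#' @param max_indegree maximum regulators per module (0..m).
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @return A `boolean_network`.
#' @export
make_random_network <- function(m, max_indegree, seed) {
  if (m < 1L) stopf("m must be >= 1")
  if (max_indegree < 0L || max_indegree > m)
    stopf("max_indegree must lie in 0..m (got %d with m = %d)", max_indegree, m)
  withr::with_seed(as.integer(seed), {
    fns <- lapply(seq_len(m), function(i) {
      k <- sample(0:max_indegree, 1L)
      regs <- if (k == 0L) integer(0) else sort(sample.int(m, k))
      tt <- sample(0:1, 2^k, replace = TRUE)
      boolean_function(i, regs, tt)
    })
    boolean_network(fns)
  })
}

#' Simulate a synchronous state sequence
#'
#' @param net a `boolean_network`.
#' @param s0 initial state (0/1 vector or bit-string) of length `net$m`.
#' @param steps number of synchronous updates.
#' @param position_labels optional labels for the `steps + 1` columns.
#' @return A `state_table` with `steps + 1` columns (no duplicated terminal).
#' @export
simulate_state_sequence <- function(net, s0, steps, position_labels = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.character(s0)) s0 <- string_to_state(s0)
  s0 <- check_bits(s0)
  if (length(s0) != net$m) stopf("s0 has %d modules, network has %d", length(s0), net$m)
  out <- matrix(0L, nrow = net$m, ncol = steps + 1L)
  out[, 1L] <- s0
  for (j in seq_len(steps)) out[, j + 1L] <- bn_step(net, out[, j])
  rownames(out) <- paste0("M", seq_len(net$m))
  colnames(out) <- if (is.null(position_labels)) paste0("P", seq_len(steps + 1L)) else position_labels
  state_table(out)
}

#' Noisy modular expression matrices from a binary state table
#'
#' Per batch, every module contributes `genes_per_module` genes whose value
#' at an observed position is drawn log-normally around `mu_on` where the
#' module is ON and `mu_off` where it is OFF, multiplied by the batch's
#' offset. Deterministic marker genes with fixed shapes are appended
#' (`hh_like`: exclusive to the terminal position; `ci_like`: ON everywhere
#' but the terminal; `dpp_like`: geometric peak at the interior midpoint),
#' plus oscillating non-monotone background genes flagged as non-MRG. The
#' duplicated terminal column, if present, is not an observed position and
#' gets no expression column.
#'
#' @param table a `state_table` (module ON regions define the gene patterns).
#' @param genes_per_module genes per module (default 350, the scale of the
#'   wing-disc screen's ~4200 genes over 12 modules).
#' @param mu_on,mu_off FPKM-like location of ON / OFF genes
#'   (`mu_on > mu_off > 0`).
#' @param sigma log-scale noise SD (>= 0; 0 gives exact levels).
#' @param batch_offsets named numeric vector of multiplicative batch
#'   offsets; one matrix is returned per entry.
#' @param n_background count of non-monotone background genes (default 20).
#' @param seed integer seed.
#' @return Named list of `expr_matrix`, one per batch, each carrying
#'   attributes `markers` (named IDs) and `flagged_non_mrg` (background
#'   gene IDs).
#' @export
expression_from_states <- function(table, genes_per_module = 350L,
                                   mu_on = 100, mu_off = 10, sigma = 0.3,
                                   batch_offsets = c(A = 1, B = 1.5),
                                   n_background = 20L, seed = 1L) {
  stopifnot(inherits(table, "state_table"))
  if (!(mu_on > mu_off && mu_off > 0)) stopf("need mu_on > mu_off > 0")
  if (sigma < 0) stopf("sigma must be >= 0")
  s <- observed_states(table)
  m <- nrow(s); p <- ncol(s)
  if (is.null(names(batch_offsets)))
    names(batch_offsets) <- LETTERS[seq_along(batch_offsets)]
  gene_ids <- unlist(lapply(seq_len(m), function(i)
    sprintf("M%02d_g%03d", i, seq_len(genes_per_module))))
  mid <- ceiling(p / 2)
  markers <- rbind(
    hh_like  = c(rep(mu_off, p - 1L), mu_on),
    ci_like  = c(rep(mu_on, p - 1L), mu_off),
    dpp_like = pmax(mu_on / 2^abs(seq_len(p) - mid), mu_off)
  )
  bg_ids <- if (n_background > 0L) sprintf("bg_%03d", seq_len(n_background)) else character(0)
  background <- if (n_background > 0L) {
    # period-4 sign pattern ++-- : strictly alternates within the odd and the
    # even position subsets, so these genes stay non-monotone after staggered
    # batch subsampling as well as in the full matrix; genes differ by
    # amplitude, not phase
    e <- ifelse(((seq_len(p) - 1L) %% 4) < 2, 1, -1)
    t(vapply(seq_len(n_background), function(b) {
      base <- sqrt(mu_on * mu_off)
      base * (1.3 + 0.05 * b)^e
    }, numeric(p)))
  }
  mu_gene <- matrix(ifelse(s[rep(seq_len(m), each = genes_per_module), ] == 1L,
                           mu_on, mu_off),
                    nrow = m * genes_per_module)
  withr::with_seed(as.integer(seed), {
    out <- lapply(names(batch_offsets), function(b) {
      noise <- if (sigma > 0)
        matrix(exp(stats::rnorm(length(mu_gene), 0, sigma)), nrow = nrow(mu_gene))
      else 1
      vals <- rbind(mu_gene * noise,
                    markers,
                    if (n_background > 0L) background) * batch_offsets[[b]]
      rownames(vals) <- c(gene_ids, rownames(markers), bg_ids)
      colnames(vals) <- colnames(s)
      e <- expr_matrix(vals, batch = b)
      attr(e, "markers") <- stats::setNames(rownames(markers), rownames(markers))
      attr(e, "flagged_non_mrg") <- bg_ids
      e
    })
    stats::setNames(out, names(batch_offsets))
  })
}

#' Ground-truth bundle for end-to-end testing
#'
#' Builds a staggered-band module state table (each module ON over one
#' contiguous position interval marching from anterior to posterior, the
#' last modules ON at the terminal position, emulating the wing-disc
#' pattern), appends the duplicated terminal column, infers the generating
#' Boolean network from the table (so simulating the network from the first
#' column reproduces the table exactly), and simulates a two-batch staggered
#' expression pair.
#'
#' With the default 13 positions the integrated labels are the wing-disc
#' ordering `A1, B1, A2, B2, B3, A3, B4, A4, B5, A5, B6, A6, B7`, batch A
#' holding the `A*` columns and batch B the `B*` columns.
#'
#' @param m module count (default 12).
#' @param n_positions observed positions (default 13).
#' @param genes_per_module,mu_on,mu_off,sigma,batch_offsets,n_background
#'   passed to [expression_from_states].
#' @param max_indegree inference bound for the ground-truth network.
#' @param seed integer seed.
#' @return A `gmn_ground_truth`: list with `network`, `state_table`
#'   (terminal duplicated), `assignment`, `expression` (list of batches),
#'   `order` (integration interleaving), `s0`, and `seed`.
#' @export
make_ground_truth <- function(m = 12L, n_positions = 13L, genes_per_module = 350L,
                              mu_on = 100, mu_off = 10, sigma = 0.3,
                              batch_offsets = c(A = 1, B = 1.5),
                              n_background = 20L, max_indegree = 4L, seed = 1L) {
  if (n_positions < 4L) stopf("need at least 4 positions")
  labels <- integrated_labels(n_positions)
  tab <- NULL
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(200L)) {
      cand <- staggered_band_table(m, n_positions)
      colnames(cand) <- labels
      ct <- duplicate_terminal(state_table(cand))
      obs <- observed_states(ct)
      first_on <- apply(obs, 1, function(r) which(r == 1L)[1])
      centre <- apply(obs, 1, function(r) mean(which(r == 1L)))
      ok <- !any(duplicated(t(obs))) &&               # distinct position states
            !any(duplicated(obs)) &&                  # distinct module patterns
            !any(apply(obs, 1, function(r) length(unique(r)) == 1L)) &&
            !any(duplicated(cbind(first_on, centre))) # unambiguous module labels
      if (!ok) next
      net <- tryCatch(infer_network(ct, max_indegree = max_indegree),
                      error = function(e) NULL)
      if (is.null(net)) next
      tab <- ct
      break
    }
  })
  if (is.null(tab)) stopf("failed to generate a consistent staggered state table")
  net <- infer_network(tab, max_indegree = max_indegree)
  expr_full <- expression_from_states(tab, genes_per_module = genes_per_module,
                                      mu_on = mu_on, mu_off = mu_off, sigma = sigma,
                                      batch_offsets = batch_offsets,
                                      n_background = n_background,
                                      seed = derive_seed(seed, 1L))
  bnames <- names(batch_offsets)
  if (is.null(bnames)) bnames <- LETTERS[seq_along(batch_offsets)]
  ord <- data.frame(batch = if (length(bnames) == 1L) bnames
                            else ifelse(startsWith(labels, "A"), bnames[1], bnames[2]),
                    position = labels, stringsAsFactors = FALSE)
  expr_pair <- lapply(seq_along(expr_full), function(bi) {
    e <- expr_full[[bi]]
    keep <- ord$position[ord$batch == names(expr_full)[bi]]
    out <- expr_matrix(e$values[, keep, drop = FALSE], batch = e$batch)
    attr(out, "markers") <- attr(e, "markers")
    attr(out, "flagged_non_mrg") <- attr(e, "flagged_non_mrg")
    out
  })
  names(expr_pair) <- names(expr_full)
  module_genes <- grep("^M[0-9]+_g", rownames(expr_full[[1]]$values), value = TRUE)
  assignment <- module_assignment(
    stats::setNames(as.integer(sub("^M([0-9]+)_.*$", "\\1", module_genes)), module_genes),
    m = m)
  structure(list(network = net, state_table = tab, assignment = assignment,
                 expression = expr_pair, order = ord,
                 s0 = tab$states[, 1L], seed = as.integer(seed)),
            class = "gmn_ground_truth")
}

# staggered contiguous ON bands marching from the anterior end (module 1)
# to the posterior end (module m). Band starts tile the axis so that every
# adjacent position pair differs in at least one module (a band boundary
# falls in every interval); the three posterior-most modules stay ON through
# the terminal position, emulating the morphogen-producing compartment,
# while anterior modules are OFF there. Randomness enters through the band
# lengths only.
staggered_band_table <- function(m, p) {
  if (m < 5L || p < m + 1L) stopf("band table needs m >= 5 and p >= m + 1")
  n_ant <- m - 3L
  starts <- round(seq(1, p - 4L, length.out = n_ant))
  lens <- sample(2:4, n_ant, replace = TRUE)
  lens[n_ant] <- p - starts[n_ant]           # last anterior band ends at p - 1
  tab <- matrix(0L, nrow = m, ncol = p)
  for (i in seq_len(n_ant)) {
    end <- min(starts[i] + lens[i] - 1L, p - 1L)
    tab[i, starts[i]:end] <- 1L
  }
  post_lens <- c(4L, 3L, 2L)
  for (j in 1:3)
    tab[n_ant + j, (p - post_lens[j] + 1L):p] <- 1L
  # canonical module order: first ON position, then run centre (matches the
  # activation-onset renumbering used by cluster_genes)
  first_on <- apply(tab, 1, function(r) which(r == 1L)[1])
  centre <- apply(tab, 1, function(r) mean(which(r == 1L)))
  tab <- tab[order(first_on, centre), , drop = FALSE]
  rownames(tab) <- paste0("M", seq_len(m))
  tab
}

# study-style interleaved position labels (A1, B1, A2, B2, B3, A3, ... , B7
# for 13 positions; alternating A/B with a terminal B otherwise)
integrated_labels <- function(p) {
  if (p == 13L)
    return(c("A1", "B1", "A2", "B2", "B3", "A3", "B4", "A4", "B5", "A5", "B6", "A6", "B7"))
  side <- rep(c("A", "B"), length.out = p)
  side[p] <- "B"
  idx <- stats::ave(seq_len(p), side, FUN = seq_along)
  paste0(side, idx)
}

#' @export
print.gmn_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic GMN ground truth (seed %d): %d modules, %d positions, %d genes/batch\n",
              x$seed, nrow(x$state_table$states),
              ncol(observed_states(x$state_table)),
              nrow(x$expression[[1]]$values)))
  invisible(x)
}
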