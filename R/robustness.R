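#' Randomly flip bits in the observed columns of a state table
#'
#' Flips `n_flips` distinct uniformly chosen cells among the observed
#' columns. The duplicated terminal column is never drawn; if a flip lands
#' in the terminal observed column the duplicate is re-synchronized, so the
#' constancy assumption beyond the last position is preserved.
#'
#' @param table a `state_table`.
#' @param n_flips number of cells to flip (default 2).
#' @param seed integer seed.
#' @return A `state_table` of the same shape.
#' @export
perturb_table <- function(table, n_flips = 2L, seed = 1L) {
  stopifnot(inherits(table, "state_table"))
  obs <- observed_states(table)
  ncell <- length(obs)
  if (n_flips > ncell)
    stopf("n_flips (%d) exceeds the %d flippable cells", n_flips, ncell)
  if (n_flips > 0L) {
    cells <- withr::with_seed(as.integer(seed), sample.int(ncell, n_flips))
    obs[cells] <- 1L - obs[cells]
  }
  out <- state_table(obs)
  if (table$terminal_duplicated)
    out <- duplicate_terminal(out, label = colnames(table$states)[ncol(table$states)])
  out
}

# canonical key for an attractor set: cycles as sorted state sets
attractor_key <- function(report) {
  keys <- vapply(report$attractors,
                 function(a) paste(sort(a$states), collapse = "|"), character(1))
  paste(sort(keys), collapse = " ; ")
}

#' Bit-flip perturbation study of the observed state table
#'
#' Repeats: flip `n_flips` bits in the observed table, re-infer the Boolean
#' network and enumerate its attractors; reports the percentage of
#' replicates whose attractor set equals the original's, the mean basin
#' size of each original attractor across matching replicates, and a
#' comparison of trajectory overlap-ratio distributions between the
#' original network and the first matching perturbed one. A replicate whose
#' inference fails is recorded as non-matching, not aborted.
#'
#' @param table a `state_table` (terminal duplicated recommended).
#' @param reps number of replicates (default 1000).
#' @param n_flips bits flipped per replicate (default 2).
#' @param max_indegree,completion,method passed to [infer_network]; the
#'   original and every replicate are inferred with the same options.
#' @param seed integer seed; results are fully reproducible.
#' @return A `perturbation_result`: `same_attractor_fraction` (percent),
#'   `mean_basins` (named by attractor state string, over matching
#'   replicates), `overlap_original`, `overlap_perturbed`, `comparison`
#'   (statistic/p-value), `replicates` data frame, and `seed`.
#' @export
perturbation_study <- function(table, reps = 1000L, n_flips = 2L,
                               max_indegree = 4L, completion = "zero",
                               method = "consistent", seed = 1L) {
  stopifnot(inherits(table, "state_table"))
  if (reps < 1L) stopf("reps must be >= 1")
  max_indegree <- min(max_indegree, nrow(table$states))
  net0 <- infer_network(table, max_indegree = max_indegree, completion = completion,
                        method = method)
  rep0 <- find_attractors(net0)
  key0 <- attractor_key(rep0)
  s0 <- table$states[, 1L]
  target <- state_to_string(observed_states(table)[, ncol(observed_states(table))])
  major0 <- trajectory(net0, s0)
  ov0 <- overlap_distribution(net0, major0, target)
  att_names <- vapply(rep0$attractors, function(a) a$states[1], character(1))
  basin_mat <- matrix(NA_real_, nrow = reps, ncol = length(att_names),
                      dimnames = list(NULL, att_names))
  match_v <- logical(reps)
  reason <- character(reps)
  ov1 <- NULL
  rep_seeds <- vapply(seq_len(reps), function(r) derive_seed(seed, r), integer(1))
  for (r in seq_len(reps)) {
    tab_r <- perturb_table(table, n_flips = n_flips, seed = rep_seeds[r])
    net_r <- tryCatch(infer_network(tab_r, max_indegree = max_indegree,
                                    completion = completion, method = method),
                      error = function(e) e)
    if (inherits(net_r, "error")) {
      match_v[r] <- FALSE
      reason[r] <- paste("inference failed:", conditionMessage(net_r))
      next
    }
    rep_r <- find_attractors(net_r)
    if (attractor_key(rep_r) == key0) {
      match_v[r] <- TRUE
      keys_r <- vapply(rep_r$attractors, function(a) a$states[1], character(1))
      basin_mat[r, ] <- vapply(att_names, function(k)
        rep_r$attractors[[match(k, keys_r)]]$basin_size, numeric(1))
      if (is.null(ov1))
        ov1 <- overlap_distribution(net_r, trajectory(net_r, s0), target)
    } else {
      reason[r] <- "different attractor set"
    }
  }
  if (is.null(ov1)) ov1 <- numeric(0)
  comparison <- if (length(ov1)) compare_distributions(ov0, ov1) else
    list(statistic = NA_real_, p.value = NA_real_, method = "none (no matching replicate)")
  structure(list(
    replicates = data.frame(replicate = seq_len(reps), seed = rep_seeds,
                            same_attractors = match_v, reason = reason,
                            basin_mat, check.names = FALSE),
    same_attractor_fraction = 100 * mean(match_v),
    mean_basins = colMeans(basin_mat[match_v, , drop = FALSE]),
    overlap_original = ov0, overlap_perturbed = ov1,
    comparison = comparison, n_flips = n_flips, seed = as.integer(seed)),
    class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("Perturbation study: %d replicates, %d bit flips each (seed %d)\n",
              nrow(x$replicates), x$n_flips, x$seed))
  cat(sprintf("  same attractor set: %.2f%% of replicates\n", x$same_attractor_fraction))
  if (length(x$mean_basins)) {
    cat("  mean basin sizes over matching replicates:\n")
    for (k in names(x$mean_basins))
      cat(sprintf("    %s: %.1f\n", k, x$mean_basins[[k]]))
  }
  cat(sprintf("  overlap-ratio comparison (%s): statistic %.4f, p = %.4g\n",
              x$comparison$method, x$comparison$statistic, x$comparison$p.value))
  invisible(x)
}

#' Trajectory overlap ratios against the major trajectory
#'
#' For every initial state whose trajectory reaches `target_attractor`,
#' excluding the states that lie on the major path itself, the ratio of its
#' trajectory states that are shared with the major path, over its
#' trajectory length.
#'
#' @param net a `boolean_network`.
#' @param major_path character vector of bit-strings (see [trajectory]).
#' @param target_attractor a fixed-point state (0/1 vector or bit-string)
#'   that must be an attractor of `net`.
#' @return Numeric vector of ratios in `[0, 1]`, named by initial state.
#' @export
overlap_distribution <- function(net, major_path, target_attractor) {
  stopifnot(inherits(net, "boolean_network"))
  if (!length(major_path)) stopf("major_path must be non-empty")
  if (!is.character(target_attractor))
    target_attractor <- state_to_string(check_bits(target_attractor))
  rep <- find_attractors(net)
  att_idx <- which(vapply(rep$attractors, function(a)
    target_attractor %in% a$states, logical(1)))
  if (!length(att_idx)) stopf("state %s is not an attractor of the network", target_attractor)
  m <- net$m
  basin_ids <- which(rep$attractor_of == att_idx) - 1L
  succ <- successor_map(net) + 1L
  id_of <- function(s) state_id(string_to_state(s))
  major_ids <- vapply(major_path, id_of, integer(1))
  on_major <- logical(2^m)
  on_major[major_ids + 1L] <- TRUE
  # trajectory state-id lists via memoized successor walking
  ratios <- numeric(0)
  for (id in basin_ids) {
    if (on_major[id + 1L]) next
    traj <- integer(0)
    seen <- logical(2^m)
    cur <- id + 1L
    while (!seen[cur]) { seen[cur] <- TRUE; traj <- c(traj, cur); cur <- succ[cur] }
    ratio <- sum(on_major[traj]) / length(traj)
    ratios <- c(ratios, stats::setNames(ratio, state_to_string(id_to_state(id, m))))
  }
  ratios
}

#' Compare two overlap-ratio distributions
#'
#' Default: two-sample Kolmogorov-Smirnov test; ties are expected with
#' discrete ratios, so the exact p-value is not attempted.
#'
#' @param d1,d2 non-empty numeric vectors.
#' @param test `"ks"` (default) or `"wilcoxon"`.
#' @return List with `statistic`, `p.value`, `method`.
#' @export
compare_distributions <- function(d1, d2, test = c("ks", "wilcoxon")) {
  test <- match.arg(test)
  if (!length(d1) || !length(d2)) stopf("both distributions must be non-empty")
  res <- if (test == "ks")
    suppressWarnings(stats::ks.test(d1, d2, exact = FALSE))
  else
    suppressWarnings(stats::wilcox.test(d1, d2, exact = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value, method = res$method)
}

#' Morphogen-production scan via boundary shifts of one module's ON run
#'
#' The scanned module (default M8, the Hedgehog-responsive module) must be
#' ON over one contiguous interval of observed positions abutting the
#' posterior (morphogen-producing) side. For each shift `delta`: `delta > 0`
#' (production increase) extends the ON run by `delta` positions away from
#' the posterior boundary; `delta < 0` shrinks it from that anterior edge;
#' a run shrunk past empty is all-OFF with a warning. Each modified table
#' is re-duplicated at the terminal, the network re-inferred, and the
#' percentage of all `2^m` states converging to the baseline normal
#' attractor (the table's terminal state) recorded; `delta = 0` reproduces
#' the unmodified analysis.
#'
#' @param table a `state_table` (terminal duplicated recommended).
#' @param module_index module to shift (default 8).
#' @param shifts integer shifts (default `-4:4`).
#' @param max_indegree,completion,method passed to [infer_network]; the scan
#'   defaults to the best-fit extension so a scenario whose modified table is
#'   no longer perfectly consistent is still analysed rather than dropped.
#' @return A `morphogen_scan` data frame: `shift`, `m8_pattern` (modified
#'   module row over observed positions), `pct_normal` (`NA` if inference
#'   fails for a scenario).
#' @export
morphogen_scan <- function(table, module_index = 8L, shifts = -4:4,
                           max_indegree = 4L, completion = "zero",
                           method = "bestfit") {
  stopifnot(inherits(table, "state_table"))
  obs <- observed_states(table)
  m <- nrow(obs); p <- ncol(obs)
  max_indegree <- min(max_indegree, m)
  if (module_index < 1L || module_index > m) stopf("module_index out of range")
  row0 <- obs[module_index, ]
  on <- which(row0 == 1L)
  if (!length(on)) stopf("module M%d is never ON; override the row explicitly", module_index)
  if (any(diff(on) != 1L))
    stopf("module M%d's ON region is not contiguous; override the row explicitly", module_index)
  a <- min(on); b <- max(on)
  target <- state_to_string(obs[, p])
  res <- lapply(shifts, function(delta) {
    row <- integer(p)
    a2 <- a - delta
    if (a2 > b) {
      warnf("shift %d empties module M%d's ON run", delta, module_index)
    } else {
      row[max(a2, 1L):b] <- 1L
    }
    obs2 <- obs
    obs2[module_index, ] <- row
    tab2 <- state_table(obs2)
    if (table$terminal_duplicated)
      tab2 <- duplicate_terminal(tab2, label = colnames(table$states)[ncol(table$states)])
    net2 <- tryCatch(infer_network(tab2, max_indegree = max_indegree,
                                   completion = completion, method = method),
                     error = function(e) e)
    if (inherits(net2, "error")) {
      warnf("shift %d: inference failed (%s)", delta, conditionMessage(net2))
      return(data.frame(shift = delta, m8_pattern = paste(row, collapse = ""),
                        pct_normal = NA_real_))
    }
    rep2 <- find_attractors(net2)
    hit <- which(vapply(rep2$attractors, function(x)
      x$is_fixed_point && x$states[1] == target, logical(1)))
    pct <- if (length(hit)) rep2$attractors[[hit]]$basin_pct else 0
    data.frame(shift = delta, m8_pattern = paste(row, collapse = ""),
               pct_normal = pct)
  })
  out <- do.call(rbind, res)
  class(out) <- c("morphogen_scan", class(out))
  out
}
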