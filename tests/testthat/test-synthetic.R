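test_that("random networks respect in-degree bounds, seeds, and truth tables", {
  net0 <- make_random_network(3, 0, seed = 1)
  for (fn in net0$functions) {
    expect_length(fn$regulators, 0L)
    expect_true(fn$expr %in% c("0", "1"))
  }
  expect_identical(serialize_rules(make_random_network(12, 3, seed = 7)),
                   serialize_rules(make_random_network(12, 3, seed = 7)))
  expect_false(identical(serialize_rules(make_random_network(12, 3, seed = 7)),
                         serialize_rules(make_random_network(12, 3, seed = 8))))
  net <- make_random_network(2, 2, seed = 5)
  for (fn in net$functions)
    for (id in 0:3) {
      s <- as.integer(id %/% 2^(0:1) %% 2)
      expect_identical(evaluate_rule(fn, s), oracle_eval(fn, s))
    }
  expect_error(make_random_network(3, 4, seed = 1), "max_indegree")
})

test_that("state sequences follow synchronous updates", {
  tab <- simulate_state_sequence(constant_net(3), c(1L, 1L, 1L), steps = 2)
  expect_identical(unname(tab$states), cbind(c(1L, 1L, 1L), 0L, 0L) + 0L)
  s0 <- c(1L, 0L, 1L, 1L)
  tab_id <- simulate_state_sequence(identity_net(4), s0, steps = 3)
  for (j in 1:4) expect_identical(unname(tab_id$states[, j]), s0)
  net <- boolean_network(list(boolean_function(1, integer(0), 0L),
                              boolean_function(2, integer(0), 1L)))
  tab2 <- simulate_state_sequence(net, c(1L, 0L), steps = 2)
  expect_identical(unname(tab2$states), matrix(c(1L, 0L, 0L, 1L, 0L, 1L), nrow = 2))
  expect_error(simulate_state_sequence(net, c(1L, 0L, 1L), steps = 1), "modules")
})

test_that("noise-free expression hits the ON/OFF levels exactly", {
  gt <- small_ground_truth()
  out <- expression_from_states(gt$state_table, genes_per_module = 3, mu_on = 80,
                                mu_off = 8, sigma = 0, batch_offsets = c(A = 1),
                                n_background = 2, seed = 9)
  expect_length(out, 1L)
  e <- out$A
  g <- e$values["M01_g001", ]
  on <- gt$state_table$states[1, colnames(e$values)] == 1L
  expect_true(all(g[on] == 80) && all(g[!on] == 8))
  expect_error(expression_from_states(gt$state_table, mu_on = 5, mu_off = 8),
               "mu_on")
})

test_that("batch offsets scale gene values exactly and markers are deterministic", {
  gt <- small_ground_truth()
  out <- expression_from_states(gt$state_table, genes_per_module = 3, sigma = 0,
                                batch_offsets = c(A = 1, B = 2), seed = 3)
  expect_equal(out$B$values, out$A$values * 2, tolerance = 1e-12)
  p <- ncol(out$A$values)
  hh <- out$A$values["hh_like", ]
  expect_identical(unname(which.max(hh)), p)          # terminal-exclusive
  expect_true(all(hh[-p] < hh[p]))
  ci <- out$A$values["ci_like", ]
  expect_identical(unname(which.min(ci)), p)          # terminal-excluded
  dpp <- out$A$values["dpp_like", ]
  peak <- which.max(dpp)
  expect_true(peak > 1 && peak < p)                    # interior peak
  expect_identical(attr(out$A, "flagged_non_mrg"),
                   sprintf("bg_%03d", 1:20))
})

test_that("background genes fail the monotone screen; module genes pass it", {
  gt <- small_ground_truth()
  e <- expression_from_states(gt$state_table, genes_per_module = 5, sigma = 0,
                              batch_offsets = c(A = 1), n_background = 8,
                              seed = 4)[[1]]
  pass <- screen_mrgs(e, window_intervals = 4, fold = 1)
  expect_length(intersect(pass, attr(e, "flagged_non_mrg")), 0L)
  mg <- grep("^M[0-9]+_g", rownames(e$values), value = TRUE)
  expect_gte(length(intersect(pass, mg)) / length(mg), 0.9)
})

test_that("ground truth is internally consistent", {
  gt <- small_ground_truth(seed = 11)
  tab <- gt$state_table
  # simulating the network from the first column reproduces the table
  sim <- simulate_state_sequence(gt$network, tab$states[, 1],
                                 steps = ncol(tab$states) - 1L)
  expect_identical(unname(sim$states), unname(tab$states))
  # assignment: non-empty disjoint modules covering the module genes
  expect_identical(sort(unique(gt$assignment$module_of)), 1:12)
  expect_false(anyDuplicated(names(gt$assignment$module_of)) > 0)
  # expression strictly positive
  for (e in gt$expression) expect_true(all(e$values > 0))
  # same seed reproduces everything
  gt2 <- small_ground_truth(seed = 11)
  expect_identical(gt2$state_table$states, tab$states)
  expect_identical(serialize_rules(gt2$network), serialize_rules(gt$network))
  expect_identical(gt2$expression$A$values, gt$expression$A$values)
})

test_that("module-state recovery is exact in at least 95% of noisy replicates", {
  # sigma = 0.2 <= 0.1 * log(mu_on / mu_off) = 0.23 at the default 10x levels
  ok <- 0L
  n_rep <- 20L
  for (seed in seq_len(n_rep)) {
    gt <- make_ground_truth(seed = 300 + seed, genes_per_module = 15, sigma = 0.2,
                            n_background = 0, batch_offsets = c(A = 1))
    e <- gt$expression$A
    mg <- grep("^M[0-9]+_g", rownames(e$values), value = TRUE)
    # batch A holds a subset of positions; regenerate full-position matrix
    full <- expression_from_states(gt$state_table, genes_per_module = 15,
                                   sigma = 0.2, batch_offsets = c(A = 1),
                                   n_background = 0, seed = 300 + seed)[[1]]
    bin <- binarize_genes(expr_matrix(full$values[mg, ], batch = "A"))
    tab <- module_states(bin, gt$assignment)
    ok <- ok + identical(unname(tab$states), unname(gt$state_table$states))
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("inference on simulated sequences reproduces the training trajectory", {
  for (seed in 1:8) {
    gt <- make_ground_truth(seed = seed, genes_per_module = 5, sigma = 0,
                            n_background = 0, batch_offsets = c(A = 1))
    net <- infer_network(gt$state_table)
    sim <- simulate_state_sequence(net, gt$s0, steps = ncol(gt$state_table$states) - 1L)
    expect_identical(unname(sim$states), unname(gt$state_table$states))
  }
})

test_that("generator I/O round-trips through TSV and rule files", {
  gt <- small_ground_truth()
  tdir <- withr::local_tempdir()
  write_state_table(gt$state_table, file.path(tdir, "tab.tsv"))
  tab2 <- read_state_table(file.path(tdir, "tab.tsv"), terminal_duplicated = TRUE)
  expect_identical(tab2$states, gt$state_table$states)
  write_rules(gt$network, file.path(tdir, "rules.txt"))
  net2 <- read_rules(file.path(tdir, "rules.txt"))
  expect_identical(serialize_rules(net2), serialize_rules(gt$network))
  write_expr_tsv(gt$expression$A, file.path(tdir, "exprA.tsv"))
  e2 <- read_expr_tsv(file.path(tdir, "exprA.tsv"), batch = "A")
  expect_equal(e2$values, gt$expression$A$values, tolerance = 1e-12)
})
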