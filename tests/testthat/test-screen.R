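test_that("monotone fold-change screening matches hand enumeration", {
  e <- tiny_expr(matrix(c(32, 16, 8, 4, 2, 1,      # perfect 2-fold decline
                          5, 5, 5, 5, 5, 5,        # flat
                          1, 2, 4, 8, 4, 2),       # rises 3 intervals, then falls
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("down", "flat", "peak"), NULL)))
  expect_identical(screen_mrgs(e, window_intervals = 4, fold = 2), "down")
  expect_identical(screen_mrgs(e, window_intervals = 3, fold = 2), c("down", "peak"))
  expect_error(screen_mrgs(e, window_intervals = 6), "exceeds")
})

test_that("screening is invariant under global positive scaling of a gene", {
  base <- matrix(c(32, 16, 8, 4, 2, 1, 1, 2, 4, 8, 4, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), NULL))
  for (k in c(0.01, 1, 250)) {
    e <- tiny_expr(base * k)
    expect_identical(screen_mrgs(e, window_intervals = 3, fold = 2), c("g1", "g2"))
    expect_identical(screen_mrgs(e, window_intervals = 4, fold = 2), "g1")
  }
})

test_that("fold = 1 degrades to plain monotonicity", {
  e <- tiny_expr(matrix(c(1, 1, 2, 2, 3, 3,      # non-decreasing
                          1, 3, 1, 3, 1, 3),     # oscillating
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("mono", "osc"), NULL)))
  expect_identical(screen_mrgs(e, window_intervals = 4, fold = 1), "mono")
})

test_that("coverage of the common MRG set reproduces the printed arithmetic", {
  # the screen counts of the wing-disc study: |A| = 4524, |B| = 5396,
  # |common| = 4217 give 93.21% and 78.15%
  common <- sprintf("g%05d", 1:4217)
  setA <- c(common, sprintf("a%05d", 1:(4524 - 4217)))
  setB <- c(common, sprintf("b%05d", 1:(5396 - 4217)))
  res <- common_mrgs(setA, setB)
  expect_identical(res$coverage[["A"]], 93.21)
  expect_identical(res$coverage[["B"]], 78.15)
  expect_identical(length(res$common), 4217L)
  # symmetry up to swapping the two coverages
  res2 <- common_mrgs(setB, setA)
  expect_identical(res2$coverage[["A"]], res$coverage[["B"]])
  expect_identical(res2$coverage[["B"]], res$coverage[["A"]])
})

test_that("identical sets give 100% coverage; empty sets warn with NA", {
  res <- common_mrgs(c("a", "b"), c("a", "b"))
  expect_identical(unname(res$coverage), c(100, 100))
  expect_warning(res <- common_mrgs(character(0), c("a")), "empty")
  expect_true(is.na(res$coverage[["A"]]))
})

test_that("a pure multiplicative batch offset is removed by integration", {
  vals <- matrix(c(10, 20, 40, 80, 160, 320,
                   100, 50, 25, 12, 6, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("P", 1:6)))
  ea <- expr_matrix(vals, batch = "A")
  eb <- expr_matrix(vals * 2, batch = "B")
  ord <- data.frame(batch = rep(c("A", "B"), each = 6),
                    position = rep(paste0("P", 1:6), 2))
  ord$position <- paste0(ord$position, ifelse(ord$batch == "B", "b", ""))
  colnames(eb$values) <- paste0(colnames(eb$values), "b")
  out <- integrate_samples(ea, eb, ord, c("g1", "g2"))
  adjA <- out$values[, 1:6]
  adjB <- out$values[, 7:12]
  expect_equal(unname(adjA), unname(adjB), tolerance = 1e-6)
  # grand mean preserved per gene on the log scale (balanced design,
  # strictly positive values so the pseudo-count is negligible)
  expect_equal(rowMeans(log2(out$values)),
               rowMeans(log2(cbind(ea$values, eb$values))),
               tolerance = 1e-6)
})

test_that("integration respects the supplied 13-column interleaving", {
  gt <- small_ground_truth()
  genes <- names(gt$assignment$module_of)[1:40]
  out <- integrate_samples(gt$expression$A, gt$expression$B, gt$order, genes)
  expect_identical(colnames(out$values),
                   c("A1", "B1", "A2", "B2", "B3", "A3", "B4",
                     "A4", "B5", "A5", "B6", "A6", "B7"))
  expect_identical(nrow(out$values), 40L)
})

test_that("missing genes are reported by ID and markers are validated", {
  gt <- small_ground_truth()
  expect_error(integrate_samples(gt$expression$A, gt$expression$B, gt$order,
                                 c("M01_g001", "nope1")), "nope1")
  genes <- c(names(gt$assignment$module_of)[1:10], "hh_like", "dpp_like", "ci_like")
  expect_silent(out <- integrate_samples(gt$expression$A, gt$expression$B, gt$order,
                                         genes, hh_like = "hh_like", dpp_like = "dpp_like"))
  # an hh-like marker that fails to peak terminally triggers a warning
  expect_warning(integrate_samples(gt$expression$A, gt$expression$B, gt$order,
                                   genes, hh_like = "ci_like"), "terminal")
})

test_that("single batch passed twice with no offset is returned unchanged", {
  gt <- small_ground_truth()
  ea <- gt$expression$A
  ord <- data.frame(batch = "A", position = colnames(ea$values))
  genes <- rownames(ea$values)[1:20]
  out <- integrate_samples(ea, ea, ord, genes)
  expect_equal(out$values, ea$values[genes, ], tolerance = 1e-10)
})
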