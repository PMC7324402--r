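# small networks and tables used across tests

constant_net <- function(m, value = 0L) {
  boolean_network(lapply(seq_len(m), function(i)
    boolean_function(i, integer(0), value)))
}

identity_net <- function(m) {
  boolean_network(lapply(seq_len(m), function(i)
    boolean_function(i, i, c(0L, 1L))))
}

# f_A = B, f_B = A
swap_net2 <- function() {
  boolean_network(list(boolean_function(1, 2L, c(0L, 1L)),
                       boolean_function(2, 1L, c(0L, 1L))))
}

# the printed wing-disc rule fragment f1 = !M9 & M10 & !M12 embedded in a
# 12-module network (other modules copy themselves; only f1 is exercised)
f1_network <- function() {
  parse_rules(c("targets, factors",
                "M1, !M9 & M10 & !M12",
                sprintf("M%d, M%d", 2:12, 2:12)))
}

tiny_expr <- function(rows, positions = paste0("P", seq_len(ncol(rows))), batch = "A") {
  colnames(rows) <- positions
  expr_matrix(rows, batch = batch)
}

small_ground_truth <- function(seed = 3, sigma = 0, ...) {
  make_ground_truth(seed = seed, genes_per_module = 20, sigma = sigma,
                    n_background = 5, ...)
}

attractor_keys <- function(rep) {
  sort(vapply(rep$attractors, function(a) paste(sort(a$states), collapse = "|"),
              character(1)))
}
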