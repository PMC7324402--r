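#' Run the full GMN analysis pipeline
#'
#' Executes the stages downstream of the supplied entry point — a pair of
#' expression TSVs (screen, integrate, cluster, binarize), a binary module
#' state table (infer), or a rule file (dynamics only) — then attractor and
#' transition-graph analysis and, optionally, the two robustness studies.
#' Every output is written under `config$out` together with a summary JSON
#' naming the seed and a config hash.
#'
#' @param config named list or path to a YAML/JSON config file. Recognized
#'   keys: exactly one entry point of `expr_a`+`expr_b` (TSV paths, with
#'   `order` a data frame / TSV of `batch`,`position` rows and optional
#'   `genes`), `state_table` (TSV path or `state_table` object), or `rules`
#'   (file path or `boolean_network`); stage parameters `window_intervals`,
#'   `fold`, `m`, `max_indegree`, `completion`, `reps`, `n_flips`, `shifts`,
#'   `scan_module`; `seed`; `out` (output directory, required).
#' @return Invisibly, a list with the computed objects (`screen`,
#'   `state_table`, `network`, `attractors`, `graph`, `major_trajectory`,
#'   `perturbation`, `hh_scan`, `summary`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML/JSON file path")
  defaults <- list(window_intervals = 4L, fold = 2, m = 12L, max_indegree = 4L,
                   completion = "zero", reps = 0L, n_flips = 2L, shifts = NULL,
                   scan_module = 8L, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  entries <- c(expr = !is.null(cfg$expr_a) || !is.null(cfg$expr_b),
               table = !is.null(cfg$state_table),
               rules = !is.null(cfg$rules))
  if (sum(entries) != 1L)
    stopf("config must provide exactly one entry point: expr_a/expr_b, state_table, or rules")
  if (is.null(cfg$out)) stopf("config$out (output directory) is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)

  if (entries[["expr"]]) {
    if (is.null(cfg$expr_a) || is.null(cfg$expr_b))
      stopf("expression entry needs both expr_a and expr_b")
    ea <- if (inherits(cfg$expr_a, "expr_matrix")) cfg$expr_a else read_expr_tsv(cfg$expr_a, batch = "A")
    eb <- if (inherits(cfg$expr_b, "expr_matrix")) cfg$expr_b else read_expr_tsv(cfg$expr_b, batch = "B")
    ord <- cfg$order
    if (is.character(ord)) ord <- utils::read.table(ord, sep = "\t", header = TRUE)
    if (is.null(ord)) stopf("expression entry needs `order` (batch/position interleaving)")
    mrg_a <- screen_mrgs(ea, cfg$window_intervals, cfg$fold)
    mrg_b <- screen_mrgs(eb, cfg$window_intervals, cfg$fold)
    res$screen <- common_mrgs(mrg_a, mrg_b)
    genes <- if (!is.null(cfg$genes)) cfg$genes else res$screen$common
    integrated <- integrate_samples(ea, eb, ord, genes)
    res$integrated <- integrated
    res$assignment <- cluster_genes(integrated, m = cfg$m)
    res$state_table <- module_states(binarize_genes(integrated), res$assignment)
  } else if (entries[["table"]]) {
    res$state_table <- if (inherits(cfg$state_table, "state_table")) cfg$state_table
                       else read_state_table(cfg$state_table, terminal_duplicated = isTRUE(cfg$terminal_duplicated))
    if (!res$state_table$terminal_duplicated)
      res$state_table <- duplicate_terminal(res$state_table)
  }

  if (!entries[["rules"]]) {
    res$network <- infer_network(res$state_table, max_indegree = cfg$max_indegree,
                                 completion = cfg$completion)
  } else {
    res$network <- if (inherits(cfg$rules, "boolean_network")) cfg$rules else read_rules(cfg$rules)
  }

  res$attractors <- find_attractors(res$network)
  res$graph <- transition_graph(res$network)
  if (!is.null(res$state_table)) {
    res$major_trajectory <- trajectory(res$network, res$state_table$states[, 1L])
    if (cfg$reps > 0L)
      res$perturbation <- perturbation_study(res$state_table, reps = cfg$reps,
                                             n_flips = cfg$n_flips,
                                             max_indegree = cfg$max_indegree,
                                             completion = cfg$completion,
                                             seed = cfg$seed)
    if (!is.null(cfg$shifts))
      res$hh_scan <- morphogen_scan(res$state_table, module_index = cfg$scan_module,
                                    shifts = cfg$shifts,
                                    max_indegree = cfg$max_indegree,
                                    completion = cfg$completion)
  }
  write_pipeline_outputs(res, cfg)
  invisible(res)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(res, cfg) {
  out <- cfg$out
  hash <- config_hash(cfg[setdiff(names(cfg), "out")])
  if (!is.null(res$state_table))
    write_state_table(res$state_table, file.path(out, "state_table.tsv"))
  write_rules(res$network, file.path(out, "rules.txt"))
  utils::write.table(as_edge_list(res$graph), file.path(out, "transition_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = cfg$seed, config_md5 = hash,
    n_states = res$attractors$n_states,
    attractors = lapply(res$attractors$attractors, function(a)
      list(states = a$states, fixed_point = a$is_fixed_point,
           basin_size = a$basin_size, basin_pct = a$basin_pct)),
    major_trajectory = res$major_trajectory,
    screen_coverage = if (!is.null(res$screen)) as.list(res$screen$coverage),
    perturbation = if (!is.null(res$perturbation)) list(
      reps = nrow(res$perturbation$replicates),
      n_flips = res$perturbation$n_flips,
      same_attractor_fraction = res$perturbation$same_attractor_fraction,
      mean_basins = as.list(res$perturbation$mean_basins),
      comparison = res$perturbation$comparison),
    hh_scan = if (!is.null(res$hh_scan)) res$hh_scan)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  if (!is.null(res$perturbation))
    utils::write.table(res$perturbation$replicates,
                       file.path(out, "perturbation_replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$hh_scan))
    utils::write.table(res$hh_scan, file.path(out, "hh_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
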