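#!/usr/bin/env Rscript
# Thin command-line wrapper around BoolGMN::run_pipeline().
# Usage:
#   Rscript scripts/run_pipeline.R --config cfg.yaml
#   Rscript scripts/run_pipeline.R --expr-a a.tsv --expr-b b.tsv --order order.tsv \
#       --modules 12 --window 4 --fold 2 --seed 1 --out results/
#   Rscript scripts/run_pipeline.R --state-table table.tsv --reps 1000 --out results/
#   Rscript scripts/run_pipeline.R --rules rules.txt --out results/

suppressPackageStartupMessages({
  library(optparse)
  library(BoolGMN)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML config; file values override flags"),
  make_option("--expr-a", type = "character", default = NULL, dest = "expr_a"),
  make_option("--expr-b", type = "character", default = NULL, dest = "expr_b"),
  make_option("--order", type = "character", default = NULL,
              help = "TSV with columns batch, position (A->P order)"),
  make_option("--state-table", type = "character", default = NULL, dest = "state_table"),
  make_option("--rules", type = "character", default = NULL),
  make_option("--modules", type = "integer", default = 12L, dest = "m"),
  make_option("--window", type = "integer", default = 4L, dest = "window_intervals"),
  make_option("--fold", type = "double", default = 2),
  make_option("--max-indegree", type = "integer", default = 4L, dest = "max_indegree"),
  make_option("--reps", type = "integer", default = 0L),
  make_option("--n-flips", type = "integer", default = 2L, dest = "n_flips"),
  make_option("--shifts", type = "character", default = NULL,
              help = "comma-separated boundary shifts, e.g. -2,-1,0,1,2"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "gmn_out")
)))

cfg <- opts[!vapply(opts, is.null, logical(1))]
cfg$help <- NULL
if (!is.null(cfg$shifts)) cfg$shifts <- as.integer(strsplit(cfg$shifts, ",")[[1]])
if (!is.null(cfg$config)) {
  cfg <- utils::modifyList(cfg, yaml::read_yaml(cfg$config))
  cfg$config <- NULL
}
res <- run_pipeline(cfg)
print(res$attractors)
cat("outputs written to", cfg$out, "\n")
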