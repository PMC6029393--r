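#!/usr/bin/env Rscript

# Thin command-line wrapper over methpanel::run_pipeline().
# Usage:
#   Rscript scripts/run_pipeline.R --out <dir> [--cq <tsv> --clinical <tsv>]
#     [--panel <yaml>] [--threshold <int>] [--ci-method <name>]
#     [--subset-sizes <a:b>] [--seed <int>]
# Without --cq/--clinical a synthetic cohort at the design size is analyzed.

suppressPackageStartupMessages(library(methpanel))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}

out <- get_arg("--out")
if (is.null(out)) stop("--out <dir> is required", call. = FALSE)
ss <- as.integer(strsplit(get_arg("--subset-sizes", "2:6"), ":")[[1]])

run <- run_pipeline(
  cq_path = get_arg("--cq"),
  clinical_path = get_arg("--clinical"),
  panel = get_arg("--panel"),
  out_dir = out,
  threshold = as.integer(get_arg("--threshold", "6")),
  ci_method = get_arg("--ci-method", "wilson"),
  subset_sizes = seq(ss[1], ss[length(ss)]),
  seed = as.integer(get_arg("--seed", "20180703")),
  verbose = TRUE
)
print(run)
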