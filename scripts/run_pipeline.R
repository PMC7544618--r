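#!/usr/bin/env Rscript

# Thin command-line front end over the package's staged pipeline.
# Usage:
#   Rscript scripts/run_pipeline.R --stage all --out artifacts \
#       [--config config.json] [--seed 1]
# Stages: simulate | preprocess | fit | maps | coverage | all

suppressPackageStartupMessages({
  library(optparse)
  library(prfmapr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--stage", type = "character", default = "all"),
  make_option("--config", type = "character", default = NULL,
              help = "JSON run configuration (see write_run_config)"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "artifacts")
)))

cfg <- if (is.null(opts$config)) run_config(seed = opts$seed)
       else read_run_config(opts$config)

stages <- c("simulate", "preprocess", "fit", "maps", "coverage")
todo <- if (opts$stage == "all") stages else match.arg(opts$stage, stages)

for (st in todo) {
  message("== stage: ", st)
  files <- run_stage(st, cfg, opts$out)
  message("   wrote: ", paste(files, collapse = ", "))
}
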