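#!/usr/bin/env Rscript

# Thin command-line wrapper over hgscompare::run_pipeline(): runs the full
# synthetic-cohort analysis and writes the result bundle.
#
# Usage: Rscript scripts/pipeline.R [--config cfg.yaml] [--seed 17] --out DIR

suppressPackageStartupMessages({
  library(optparse)
  library(hgscompare)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration (defaults used when omitted)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "overrides the configured RNG seed"),
  make_option("--out", type = "character", default = "pipeline_results",
              help = "output directory")
)))

cfg <- read_run_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed
message("seed: ", cfg$seed)
run_pipeline(cfg, opts$out)
message("results written to ", opts$out)
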