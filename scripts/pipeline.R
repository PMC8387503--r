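#!/usr/bin/env Rscript
# Thin command-line wrapper over trophoniche::run_pipeline().
# Usage:
#   Rscript scripts/pipeline.R --config run.yaml --seed 1 --out outdir

suppressPackageStartupMessages({
  library(optparse)
  library(trophoniche)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (optional; defaults ship the regime_shift scenario)"),
  make_option("--seed", type = "integer", default = 1L,
              help = "master seed [default %default]"),
  make_option("--out", type = "character", default = "trophoniche_run",
              help = "output directory [default %default]")
)))

cfg <- if (is.null(opts$config)) run_config(seed = opts$seed)
       else read_run_config(opts$config, seed = opts$seed)
cfg$out_dir <- opts$out
report <- run_pipeline(cfg)
cat("report written to", file.path(opts$out, "report.json"),
    "(fingerprint", report$fingerprint, ")\n")
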