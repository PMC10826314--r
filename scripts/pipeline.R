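#!/usr/bin/env Rscript

# Thin command-line wrapper over rsmbo::run_pipeline():
#   Rscript scripts/pipeline.R <generate|simulate|pilot|evaluate>
#          [--config config.yaml] [--seed INT] [--reps INT] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(rsmbo)
})

parser <- OptionParser(
  usage = "%prog <generate|simulate|pilot|evaluate> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML run configuration"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the config seed"),
    make_option("--reps", type = "integer", default = NULL,
                help = "override the study repetitions (scaled-down run)"),
    make_option("--out", type = "character", default = "results",
                help = "output directory [default %default]")))
args <- parse_args(parser, positional_arguments = 1)
command <- args$args

cfg <- if (is.null(args$options$config)) default_run_config()
       else read_run_config(args$options$config)
if (!is.null(args$options$seed)) {
  cfg <- unclass(cfg)
  cfg$seed <- args$options$seed
  cfg <- validate_run_config(cfg)
}

art <- run_pipeline(command, cfg, args$options$out,
                    reps = args$options$reps)
message("wrote: ", paste(art$files, collapse = ", "))
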