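#!/usr/bin/env Rscript

# Thin command-line wrapper over actiwear::run_pipeline(). Either point it
# at a directory of epoch/diary/clinical CSVs or let it generate a
# synthetic cohort; the report bundle (summaries.tsv, cohort_stats.json,
# run_log.txt) lands in --out-dir.
#
#   Rscript scripts/actiwear-pipeline.R --seed 7 --out-dir out/
#   Rscript scripts/actiwear-pipeline.R --config run.yaml
#   Rscript scripts/actiwear-pipeline.R --show-config

suppressPackageStartupMessages({
  library(optparse)
  library(actiwear)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON pipeline config; flags below override it"),
  make_option("--input-dir", type = "character", default = NULL, dest = "input_dir",
              help = "directory of epoch CSVs + diary.csv + clinical.csv"),
  make_option("--out-dir", type = "character", default = "actiwear-out",
              dest = "out_dir"),
  make_option("--seed", type = "integer", default = 20220307L),
  make_option("--n-frda", type = "integer", default = 26L, dest = "n_frda"),
  make_option("--n-ctr", type = "integer", default = 13L, dest = "n_ctr"),
  make_option("--days", type = "integer", default = 7L),
  make_option("--choi-window", type = "double", default = 90, dest = "choi_window"),
  make_option("--choi-spike", type = "double", default = 2, dest = "choi_spike"),
  make_option("--choi-flank", type = "double", default = 30, dest = "choi_flank"),
  make_option("--min-wear-hours", type = "double", default = 8,
              dest = "min_wear_hours"),
  make_option("--delta", type = "double", default = 1,
              help = "trial effect fraction for sample sizing"),
  make_option("--no-reliability", action = "store_true", default = FALSE,
              dest = "no_reliability"),
  make_option("--show-config", action = "store_true", default = FALSE,
              dest = "show_config", help = "print the resolved config and exit")
))
opt <- parse_args(parser)

base <- if (!is.null(opt$config)) read_pipeline_config(opt$config) else
  pipeline_config()
keys <- c("input_dir", "out_dir", "seed", "n_frda", "n_ctr", "days",
          "choi_window", "choi_spike", "choi_flank", "min_wear_hours",
          "delta")
for (k in keys) if (!is.null(opt[[k]])) base[[k]] <- opt[[k]]
base$reliability <- !opt$no_reliability
cfg <- do.call(pipeline_config, unclass(base)[names(formals(pipeline_config))])

if (opt$show_config) {
  cat(yaml::as.yaml(unclass(cfg)))
  quit(status = 0)
}

report <- run_pipeline(cfg)
print(report)
cat("report bundle written to ", cfg$out_dir, "\n", sep = "")
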