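#!/usr/bin/env Rscript
# Thin shell wrapper over mirisc::run_stage().
#
# Usage:
#   Rscript scripts/pipeline.R <stage> --out-dir DIR [--seed N]
#       [--alpha-mirna A] [--alpha-gene A] [--min-reliable K]
#       [--pseudocount P] [--show-config]
#   stages: simulate mirna-enrich target-enrich seed-scan overlap report

suppressMessages(library(mirisc))

argv <- commandArgs(trailingOnly = TRUE)
usage_stages <- c("simulate", "mirna-enrich", "target-enrich", "seed-scan",
                  "overlap", "report")

flag <- function(name, default) {
  i <- which(argv == name)
  if (length(i) == 1L && i < length(argv)) argv[i + 1L] else default
}

stage <- if (length(argv) >= 1L && argv[1] %in% usage_stages) argv[1] else NA
cfg <- try(run_config(
  seed = as.integer(flag("--seed", "1")),
  out_dir = flag("--out-dir", "mirisc_out"),
  alpha_mirna = as.numeric(flag("--alpha-mirna", "0.01")),
  alpha_gene = as.numeric(flag("--alpha-gene", "0.001")),
  min_reliable = as.integer(flag("--min-reliable", "2")),
  pseudocount = as.numeric(flag("--pseudocount", "0.5"))), silent = TRUE)

if (inherits(cfg, "try-error")) {
  message("configuration error: ", attr(cfg, "condition")$message)
  quit(status = 3)
}
if ("--show-config" %in% argv) {
  str(unclass(cfg)[setdiff(names(cfg), "sim")])
  quit(status = 0)
}
if (is.na(stage)) {
  message("usage: pipeline.R <", paste(usage_stages, collapse = "|"),
          "> [flags]")
  quit(status = 2)
}

status <- tryCatch({
  run_stage(stage, cfg)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("missing input", conditionMessage(e))) 2L else 1L
})
quit(status = status)
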