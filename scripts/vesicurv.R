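#!/usr/bin/env Rscript
# Thin command-line wrapper over the vesicurv pipeline functions.
#
# Usage:
#   Rscript scripts/vesicurv.R <subcommand> [--config FILE] [--seed INT]
#                              [--out-dir DIR]
# Subcommands: simulate | analyze-buds | limit-line | deformation | partitioning
#
# Exit codes: 0 success, 2 validation error, 1 runtime failure.

suppressPackageStartupMessages(library(vesicurv))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  message("usage: vesicurv.R <simulate|analyze-buds|limit-line|deformation|partitioning> [--config FILE] [--seed INT] [--out-dir DIR]")
  quit(status = 2)
}
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) return(args[i + 1L])
  default
}
config <- get_arg("--config")
seed <- get_arg("--seed")
if (!is.null(seed)) seed <- as.integer(seed)
out_dir <- get_arg("--out-dir", ".")

run <- function() {
  switch(cmd,
    "simulate" = run_simulate(config, seed, out_dir),
    "analyze-buds" = run_analyze_buds(config, seed, out_dir),
    "limit-line" = {
      cfg <- load_config(config, seed, out_dir)
      for (kr in cfg$analysis$kappa_ratio_grid) {
        ln <- limit_shape_line(kr)
        utils::write.csv(as.data.frame(ln),
                         file.path(out_dir, sprintf("limit_line_kr%g.csv", kr)),
                         row.names = FALSE)
      }
      invisible(NULL)
    },
    "deformation" = run_deformation(config, seed, out_dir),
    "partitioning" = run_partitioning(config, seed, out_dir),
    {
      message("unknown subcommand: ", cmd)
      quit(status = 2)
    })
}

status <- tryCatch({ run(); 0L },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config|column|lacks|unknown|not found|required",
              conditionMessage(e))) 2L else 1L
  })
quit(status = status)
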