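# Shared plumbing for the numbered analysis scripts: seed parsing and the
# results layout. Every script is runnable from the repository root as
#   Rscript analysis/<script>.R [--seed <int>]
suppressPackageStartupMessages(library(circumir))

args <- commandArgs(trailingOnly = TRUE)
seed_ix <- which(args == "--seed")
SEED <- if (length(seed_ix) == 1 && seed_ix < length(args))
  as.integer(args[seed_ix + 1]) else 1L

DATA_DIR <- file.path("results", "data")
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

need_data <- function(...) {
  paths <- file.path(DATA_DIR, c(...))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing ", paste(missing, collapse = ", "),
         " — run 'Rscript analysis/01_simulate.R --seed ", SEED, "' first",
         call. = FALSE)
  invisible(paths)
}
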