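# Shared settings for the analysis scripts. Everything downstream is
# deterministic in MASTER_SEED; intermediate bulky arrays go to scratch/
# (disposable), tables and figures-ready summaries to results/.

library(mmgdecode)

MASTER_SEED <- 20260923L
RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch/analysis"

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)

default_experiment <- function() {
  generate_experiment(generator_config(), seed = MASTER_SEED)
}

write_tsv <- function(df, name, dir = RESULTS_DIR) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
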