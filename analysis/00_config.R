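# Shared settings for the numbered analysis scripts. Each script can be run
# in order from the repository root:
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_fit_models.R
#   ...
# Intermediate artefacts and tables land under results/.

suppressPackageStartupMessages(library(statescape))

MASTER_SEED <- 20260921L
OUT <- "results"
COHORT_DIR <- file.path(OUT, "cohort")
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

write_tsv <- function(df, name) {
  path <- file.path(OUT, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
write_json_out <- function(x, name) {
  path <- file.path(OUT, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", path)
}
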