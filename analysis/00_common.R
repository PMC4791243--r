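# Shared setup for the analysis drivers: one deterministic, fully planted
# synthetic study (six samples) used by every downstream script. Rebuilding
# from the seed takes a couple of seconds, so each driver stays standalone.

suppressPackageStartupMessages(library(gbmcharter))

STUDY_SEED <- 1L

build_study <- function(seed = STUDY_SEED) {
  b <- generate_reference_bundle(seed)
  b <- plant_cohort_variants(b, seed)
  b <- plant_editing_data(b, seed)
  b <- plant_fusions(b, seed)
  b$de <- plant_de_tables(seed)
  b
}

results_dir <- file.path("results")
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

save_table <- function(df, name) {
  path <- file.path(results_dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
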