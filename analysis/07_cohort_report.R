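#!/usr/bin/env Rscript
# Full end-to-end run from the serialized fixtures (external formats only):
# exercises every reader, all stages and the report writer in one pass.
# Requires analysis/01_simulate.R to have written scratch/bundle.

source(file.path("analysis", "00_common.R"))

bundle_dir <- file.path("scratch", "bundle")
if (!dir.exists(bundle_dir)) {
  message("scratch/bundle missing; building it first")
  write_bundle(build_study(), bundle_dir)
}
res <- run_cohort(bundle_dir, file.path(results_dir, "cohort_reports"))
message("cohort reports written to results/cohort_reports; ",
        "cancer-specific fraction ",
        round(res$cascade$fraction_cancer_specific, 3),
        ", editing events ", nrow(res$editing$sites),
        ", consensus fusions ", nrow(res$fusions$consensus))
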