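#!/usr/bin/env Rscript
# Builds the synthetic six-sample study with planted truth and serializes
# every fixture (genome, gene models, repeat track, VCFs, site tables,
# pileups, fusion caller tables, DE tables) under scratch/bundle for the
# other drivers and for end-to-end runs.

source(file.path("analysis", "00_common.R"))

study <- build_study()
bundle_dir <- file.path("scratch", "bundle")
write_bundle(study, bundle_dir)
message("fixtures written to ", bundle_dir, ": ",
        length(list.files(bundle_dir)), " files")

truth_summary <- rbind(
  data.frame(component = "cohort_snv",
             category = names(table(study$cohort$truth$snv$reason)),
             n = as.integer(table(study$cohort$truth$snv$reason))),
  data.frame(component = "cohort_indel", category = "planted",
             n = nrow(study$cohort$indels)),
  data.frame(component = "editing_true",
             category = names(table(study$editing$truth$sites$category)),
             n = as.integer(table(study$editing$truth$sites$category))),
  data.frame(component = "editing_artifact",
             category = study$editing$truth$artifacts$stage, n = 1L),
  data.frame(component = "fusion_consensus",
             category = c("in_frame", "out_of_frame"),
             n = c(sum(study$fusions$truth$in_frame),
                   sum(!study$fusions$truth$in_frame)))
)
save_table(truth_summary, "simulation_truth_summary.tsv")
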