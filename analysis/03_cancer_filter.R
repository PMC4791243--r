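#!/usr/bin/env Rscript
# Cancer-specific SNV cascade over the pooled cohort: per-reason attrition,
# the cancer-specific fraction, zygosity and Ti/Tv of the cancer-specific
# set, a gene-by-sample alteration matrix, and the mismatch-repair screen.

source(file.path("analysis", "00_common.R"))

study <- build_study()
co <- study$cohort

res <- run_cascade(co$variants, co$db, n_samples = co$n_samples)
message(sprintf("cancer-specific: %d of %d SNV calls (%.1f%%)",
                nrow(res$cancer_specific), nrow(co$variants),
                100 * res$fraction_cancer_specific))
save_table(res$attrition, "cascade_attrition.tsv")
save_table(res$verdicts[c("sample_id", "chrom", "pos", "ref", "alt",
                          "zygosity", "reason", "label")],
           "cascade_verdicts.tsv")

cs <- res$cancer_specific
zz <- zygosity_split(cs)
tt <- titv_ratio(cs)
message(sprintf("cancer-specific set: hom:het = %d:%d (ratio %.2f), Ti/Tv %.2f",
                zz$hom, zz$het, zz$ratio, tt$ratio))

cs$functional_class <- classify_functional(cs, study$models, study$genome)
save_table(as.data.frame(table(class = cs$functional_class),
                         responseName = "n"), "functional_classes.tsv")

panel <- c("EGFR", "TP53", "MSH2", "FUSA", "FUSB", "GFC", "GFD", "GFE", "GFF")
mat <- gene_panel_matrix(rbind(cs[names(co$indels)], co$indels), panel,
                         study$models, samples = co$sample_ids)
save_table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
           "gene_panel_matrix.tsv")

mmr <- mmr_status(cs, study$models, samples = co$sample_ids)
message("samples with an MMR-gene hit: ",
        if (any(mmr)) paste(names(mmr)[mmr], collapse = ", ") else "none")
save_table(data.frame(sample_id = names(mmr), mmr_mutated = unname(mmr)),
           "mmr_status.tsv")
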