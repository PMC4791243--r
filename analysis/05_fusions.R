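#!/usr/bin/env Rscript
# Gene-fusion consensus across the three caller dialects, in-frame ORF
# assembly for every consensus pair, and a PCR validation scheme for the
# worked in-frame product.

source(file.path("analysis", "00_common.R"))

study <- build_study()
calls <- study$fusions$calls_by_tool
message("calls per tool: ",
        paste(sprintf("%s=%d", names(calls), vapply(calls, nrow, integer(1))),
              collapse = ", "),
        " (", sum(vapply(calls, nrow, integer(1))), " total)")

cons <- consensus_fusions(calls)
message(nrow(cons$consensus), " fusions called by all three tools; ",
        nrow(cons$pairwise), " by at least two")
save_table(cons$consensus, "fusion_consensus.tsv")

by_gene <- setNames(study$models, sapply(study$models, `[[`, "gene"))
products <- lapply(seq_len(nrow(cons$consensus)), function(i) {
  cc <- cons$consensus[i, ]
  pr <- assemble_fusion_orf(by_gene[[cc$gene5]], cc$pos5,
                            by_gene[[cc$gene3]], cc$pos3, study$genome)
  print(pr)
  data.frame(gene5 = cc$gene5, gene3 = cc$gene3, in_frame = pr$in_frame,
             cds_len5 = pr$cds_len5, entry_phase3 = pr$entry_phase3,
             protein_length = pr$protein_length,
             junction_peptide = pr$junction_peptide)
})
save_table(do.call(rbind, products), "fusion_products.tsv")

# validation primer scheme for the worked in-frame fusion
cc <- cons$consensus[cons$consensus$gene5 == "FUSA", ]
pr <- assemble_fusion_orf(by_gene[["FUSA"]], cc$pos5, by_gene[["FUSB"]],
                          cc$pos3, study$genome)
scheme <- junction_primers(pr, by_gene[["FUSA"]], by_gene[["FUSB"]],
                           study$genome)
message("validation amplicons (nt): ",
        paste(sprintf("%s=%s", scheme$amplicons$name, scheme$amplicons$length),
              collapse = ", "))
save_table(scheme$amplicons, "fusion_primer_scheme.tsv")
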