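#!/usr/bin/env Rscript
# Direction concordance between the cell-line DE table (fold-change and
# adjusted p) and the comparison tumour dataset (p-value), over the genes
# significant in both.

source(file.path("analysis", "00_common.R"))

study <- build_study()
de <- study$de

cc <- direction_concordance(de$de_a, de$de_b)
message(sprintf(
  "%d genes significant in both tables; %d concordant in direction (%.1f%%)",
  cc$n_common, cc$n_concordant, 100 * cc$fraction))
save_table(data.frame(n_common = cc$n_common, n_concordant = cc$n_concordant,
                      fraction = round(cc$fraction, 4)), "concordance.tsv")
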