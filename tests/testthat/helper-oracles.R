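# independent brute-force evaluation of the written cascade rules, used as
# the oracle against the vectorized implementation
oracle_cascade <- function(esp, kg, in_cosmic, in_tcga, ds, in_dbsnp, th) {
  if (esp >= th$esp_cut) return("esp_common")
  if (kg >= th$kg_cut) return("kg_common")
  if (in_cosmic) return("cosmic_hit")
  if (in_tcga) return("tcga_hit")
  if (ds >= th$dataset_cut) return("dataset_recurrent")
  if (in_dbsnp) return("dbsnp_known")
  "passed_all"
}

# build a cohort + annotation db in which case i has exactly the requested
# attributes (frequencies, memberships, number of carrier samples)
cascade_case_world <- function(cases, n_samples = 8L) {
  n <- nrow(cases)
  pos <- seq_len(n)
  base <- data.frame(chrom = "chrT", pos = pos, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  tab <- function(sel, freq = NULL) {
    df <- base[sel, , drop = FALSE]
    if (!is.null(freq)) df$freq <- rep(freq[sel], length.out = nrow(df))
    df
  }
  db <- annotation_db(
    esp6500 = tab(cases$esp > 0, cases$esp),
    kg1000 = tab(cases$kg > 0, cases$kg),
    cosmic = tab(cases$cosmic),
    tcga_gbm = tab(cases$tcga),
    dbsnp137 = tab(cases$dbsnp)
  )
  cohort <- do.call(rbind, lapply(seq_len(n), function(i) {
    variant_calls(paste0("S", seq_len(cases$carriers[i])), "chrT", pos[i],
                  "A", "G", "het", depth = 50L, alt_reads = 25L, base_qual = 35)
  }))
  variants <- variant_calls("S1", "chrT", pos, "A", "G", "het",
                            depth = 50L, alt_reads = 25L, base_qual = 35)
  list(variants = variants, cohort = cohort, db = db, n_samples = n_samples)
}
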