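# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

# fully planted bundle at a fixed seed; every truth element attached
planted_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    b <- generate_reference_bundle(1L)
    b <- plant_cohort_variants(b, 1L)
    b <- plant_editing_data(b, 1L)
    b <- plant_fusions(b, 1L)
    b$de <- plant_de_tables(1L)
    .fixture_cache$bundle <- b
  }
  .fixture_cache$bundle
}

models_by_gene <- function(bundle) {
  stats::setNames(bundle$models,
                  vapply(bundle$models, `[[`, character(1), "gene"))
}

# quick single-sample SNV table
snvs <- function(ref, alt, zygosity = "het", chrom = "chr1",
                 pos = seq_along(ref), sample_id = "S1", ...) {
  variant_calls(sample_id, chrom, pos, ref, alt, zygosity, ...)
}

# a single-exon plus-strand coding toy world for codon-level tests:
# genome "chrT" = 5' pad + CDS + 3' pad, CDS of n_codons (incl. stop)
toy_cds_world <- function(cds, pad5 = 50L, pad3 = 50L, seed = 42L) {
  set.seed(seed)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  seq <- paste0(pad(pad5), cds, pad(pad3))
  genome <- Biostrings::DNAStringSet(c(chrT = seq))
  cds_start <- pad5 + 1L
  cds_end <- pad5 + nchar(cds)
  tx <- gene_model("TOY", "TOY.1", "chrT", "+",
                   data.frame(start = 1L, end = nchar(seq)),
                   cds_start, cds_end, "protein_coding")
  list(genome = genome, tx = tx, models = list(TOY.1 = tx),
       cds_start = cds_start, cds_end = cds_end)
}

# random CDS with a start, no internal stop, and a terminal stop
random_cds <- function(n_codons, seed = 7L) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2L, TRUE), collapse = ""), "TAA")
}

# independent functional-classification oracle for coding SNVs: translate the
# whole mutated CDS and compare protein strings
oracle_coding_class <- function(cds, i, alt_base) {
  mut <- cds
  substr(mut, i, i) <- alt_base
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s),
                                                       no.init.codon = TRUE))
  p_ref <- tr(cds)
  p_alt <- tr(mut)
  codon <- (i - 1L) %/% 3L + 1L
  if (codon == 1L) {
    if (p_ref == p_alt && substr(cds, 1, 3) == substr(mut, 1, 3)) return("silent")
    return("translation_start")
  }
  aa_ref <- substr(p_ref, codon, codon)
  aa_alt <- substr(p_alt, codon, codon)
  if (aa_ref == aa_alt) return("silent")
  if (aa_alt == "*") return("nonsense")
  if (aa_ref == "*") return("nonstop")
  "missense"
}
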