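#' Run the full characterization over a cohort directory
#'
#' Orchestrates every stage over a directory laid out as written by
#' [write_bundle()]: call-level filters and per-sample spectrum statistics,
#' the cancer-specific SNV cascade with per-reason attrition, the RNA-editing
#' detection cascade with its breakdowns, fusion consensus plus in-frame ORF
#' assembly for consensus pairs with known gene models, and (when DE tables
#' are present) direction concordance. All inputs are validated before any
#' output is written, so a missing file aborts with its name and leaves no
#' partial reports. Given identical inputs the run is fully deterministic and
#' the reports are byte-identical.
#'
#' @param input_dir directory containing the inputs (see [write_bundle()]).
#' @param out_dir directory for the TSV reports and the JSON run manifest.
#' @return invisibly, a list with every stage's in-memory results.
#' @export
run_cohort <- function(input_dir, out_dir) {
  p <- function(...) file.path(input_dir, ...)
  required <- c("genome.fa", "models.gtf", "repeats.bed", "targets.bed",
                "thresholds.yaml", "esp6500.tsv", "kg1000.tsv", "cosmic.tsv",
                "tcga_gbm.tsv", "dbsnp137.tsv", "pileup.tsv",
                "normal_editome.tsv")
  missing <- required[!file.exists(p(required))]
  dna_files <- sort(list.files(input_dir, "^dna_.*\\.vcf$", full.names = TRUE))
  rna_files <- sort(list.files(input_dir, "^rna_.*\\.vcf$", full.names = TRUE))
  fusion_files <- sort(list.files(input_dir, "^fusions_.*\\.tsv$", full.names = TRUE))
  if (!length(dna_files)) missing <- c(missing, "dna_<sample>.vcf")
  if (!length(rna_files)) missing <- c(missing, "rna_<sample>.vcf")
  if (length(missing))
    stop("missing input file(s) in ", input_dir, ": ", paste(missing, collapse = ", "))

  th <- read_thresholds(p("thresholds.yaml"))
  genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  models <- read_gene_models(p("models.gtf"))
  repeats <- read_repeat_track(p("repeats.bed"))
  targets <- read_target_regions(p("targets.bed"))
  db <- read_annotation_db(list(
    esp6500 = p("esp6500.tsv"), kg1000 = p("kg1000.tsv"), cosmic = p("cosmic.tsv"),
    tcga_gbm = p("tcga_gbm.tsv"), dbsnp137 = p("dbsnp137.tsv")
  ))
  normal_editome <- read.delim(p("normal_editome.tsv"), stringsAsFactors = FALSE)
  support <- read_support_table(p("pileup.tsv"))

  sample_of <- function(f) sub("^(dna|rna)_(.*)\\.vcf$", "\\2", basename(f))
  samples <- sample_of(dna_files)
  message("cohort of ", length(samples), " sample(s): ", paste(samples, collapse = ", "))

  # --- per-sample call filters and spectrum stats ----------------------------
  filtered <- list()
  sample_summary <- do.call(rbind, lapply(seq_along(dna_files), function(i) {
    calls <- read_vcf(dna_files[i], samples[i])
    ff <- apply_call_filters(calls, targets, th)
    filtered[[samples[i]]] <<- ff$retained
    snv <- ff$retained[ff$retained$kind == "SNV", , drop = FALSE]
    tt <- titv_ratio(snv)
    zz <- zygosity_split(snv)
    known <- db_member(db, "dbsnp137", snv)
    data.frame(
      sample_id = samples[i], total_calls = nrow(ff$retained),
      snvs = nrow(snv), indels = nrow(ff$retained) - nrow(snv),
      dbsnp_known = sum(known), novel = sum(!known),
      hom = zz$hom, het = zz$het, titv = tt$ratio,
      removed_off_target = ff$attrition$count[1],
      removed_low_qual = ff$attrition$count[2],
      removed_low_support = ff$attrition$count[3],
      stringsAsFactors = FALSE
    )
  }))

  # --- cancer-specific cascade ----------------------------------------------
  pooled <- do.call(rbind, filtered)
  pooled_snv <- pooled[pooled$kind == "SNV", , drop = FALSE]
  cascade <- run_cascade(pooled_snv, db, n_samples = length(samples), thresholds = th)
  cs <- cascade$cancer_specific
  cs$functional_class <- classify_functional(cs, models, genome, th)
  cs_titv <- titv_ratio(cs)
  cs_zyg <- zygosity_split(cs)

  # --- RNA editing -----------------------------------------------------------
  rna <- do.call(rbind, lapply(rna_files, function(f) read_vcf(f, sample_of(f))))
  editing <- run_editing_pipeline(rna, db, support, models, repeats, genome,
                                  normal_editome, filtered, th)

  # --- fusions ---------------------------------------------------------------
  fusion_report <- NULL
  products <- list()
  if (length(fusion_files) >= 2L) {
    tools <- sub("^fusions_(.*)\\.tsv$", "\\1", basename(fusion_files))
    calls <- stats::setNames(lapply(seq_along(fusion_files), function(i)
      read_fusion_calls(fusion_files[i], tools[i])), tools)
    cons <- consensus_fusions(calls)
    by_gene <- stats::setNames(models, vapply(models, `[[`, character(1), "gene"))
    prod_rows <- lapply(seq_len(nrow(cons$consensus)), function(i) {
      g5 <- cons$consensus$gene5[i]; g3 <- cons$consensus$gene3[i]
      if (!g5 %in% names(by_gene) || !g3 %in% names(by_gene)) return(NULL)
      pr <- assemble_fusion_orf(by_gene[[g5]], cons$consensus$pos5[i],
                                by_gene[[g3]], cons$consensus$pos3[i], genome)
      products[[paste(g5, g3, sep = "-")]] <<- pr
      data.frame(gene5 = g5, gene3 = g3, in_frame = pr$in_frame,
                 protein_length = pr$protein_length,
                 cds_len5 = pr$cds_len5, entry_phase3 = pr$entry_phase3,
                 junction_peptide = pr$junction_peptide,
                 stringsAsFactors = FALSE)
    })
    fusion_report <- list(consensus = cons$consensus, pairwise = cons$pairwise,
                          products = do.call(rbind, prod_rows))
  }

  # --- DE concordance (optional inputs) --------------------------------------
  concordance <- NULL
  if (file.exists(p("de_a.tsv")) && file.exists(p("de_b.tsv"))) {
    de_a <- read.delim(p("de_a.tsv"), stringsAsFactors = FALSE)
    de_b <- read.delim(p("de_b.tsv"), stringsAsFactors = FALSE)
    concordance <- direction_concordance(de_a, de_b, th)
  }

  # --- reports ---------------------------------------------------------------
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(out_dir, ...)
  wt <- function(df, f) write.table(df, o(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(sample_summary, "sample_summary.tsv")
  wt(cascade$verdicts[c("sample_id", "chrom", "pos", "ref", "alt", "zygosity",
                        "reason", "step_index", "label")],
     "cascade_verdicts.tsv")
  wt(cascade$attrition, "cascade_attrition.tsv")
  cs_out <- cs[c("sample_id", "chrom", "pos", "ref", "alt", "zygosity",
                 "reason", "functional_class")]
  wt(cs_out, "cancer_specific.tsv")
  wt(editing$sites, "editing_sites.tsv")
  wt(editing$attrition, "editing_attrition.tsv")
  wt(data.frame(class = names(editing$breakdowns$region),
                fraction = as.numeric(editing$breakdowns$region)),
     "editing_region_breakdown.tsv")
  wt(data.frame(class = names(editing$breakdowns$genic),
                fraction = as.numeric(editing$breakdowns$genic)),
     "editing_genic_breakdown.tsv")
  wt(data.frame(recurrence = names(editing$breakdowns$recurrence),
                n_sites = as.integer(editing$breakdowns$recurrence)),
     "editing_recurrence.tsv")
  if (!is.null(fusion_report)) {
    wt(fusion_report$consensus, "fusion_consensus.tsv")
    if (!is.null(fusion_report$products)) wt(fusion_report$products, "fusion_products.tsv")
  }
  if (!is.null(concordance)) {
    wt(data.frame(n_common = concordance$n_common,
                  n_concordant = concordance$n_concordant,
                  fraction = concordance$fraction), "concordance.tsv")
  }
  inputs <- sort(list.files(input_dir, full.names = TRUE))
  inputs <- inputs[!dir.exists(inputs)]
  manifest <- list(
    package = "gbmcharter",
    version = as.character(utils::packageVersion("gbmcharter")),
    thresholds = unclass(th),
    samples = samples,
    inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                             basename(inputs))
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    sample_summary = sample_summary, filtered = filtered, cascade = cascade,
    cancer_specific = cs, cancer_titv = cs_titv, cancer_zygosity = cs_zyg,
    editing = editing, fusions = fusion_report, products = products,
    concordance = concordance, thresholds = th
  ))
}
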