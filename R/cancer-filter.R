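#' Dataset frequency of alleles across the cohort
#'
#' The fraction of cohort samples carrying an identical allele (chrom, pos,
#' ref, alt). A sample contributes at most once per allele however many times
#' the allele appears in its file.
#'
#' @param variants variant-call data.frame: the alleles to look up.
#' @param cohort_variants variant-call data.frame pooled over all samples.
#' @param n_samples number of samples in the cohort (>= 1).
#' @return numeric vector of fractions, parallel to \code{variants}.
#' @export
dataset_frequency <- function(variants, cohort_variants, n_samples) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (nrow(variants) == 0L) return(numeric(0))
  carrier <- unique(cohort_variants[c("sample_id", "chrom", "pos", "ref", "alt")])
  n_carriers <- table(allele_key(carrier))
  k <- allele_key(variants)
  cnt <- as.integer(n_carriers[k])
  cnt[is.na(cnt)] <- 0L
  cnt / n_samples
}

cascade_reasons <- c("esp_common", "kg_common", "cosmic_hit", "tcga_hit",
                     "dataset_recurrent", "dbsnp_known", "passed_all")
cascade_labels <- c(
  esp_common = "non_specific", kg_common = "non_specific",
  cosmic_hit = "cancer_specific", tcga_hit = "cancer_specific",
  dataset_recurrent = "non_specific", dbsnp_known = "non_specific",
  passed_all = "cancer_specific"
)

#' Classify SNVs as cancer-specific or non-specific
#'
#' The decision cascade, applied in this exact order; the first matching step
#' decides the verdict:
#' \enumerate{
#'   \item ESP6500 frequency >= \code{esp_cut} -> non-specific (polymorphism);
#'   \item 1000 Genomes frequency >= \code{kg_cut} -> non-specific;
#'   \item present in COSMIC -> cancer-specific;
#'   \item present in the TCGA GBM call set -> cancer-specific;
#'   \item dataset frequency >= \code{dataset_cut} -> non-specific (recurrent
#'     across samples, likely germline/platform artifact);
#'   \item present in dbSNP 137 -> non-specific;
#'   \item otherwise -> cancer-specific (novel candidate).
#' }
#' Database membership requires the full allele (chrom, pos, ref, alt) to
#' match; positional-only matches are rejected. Frequency comparisons are
#' inclusive (\code{>=}).
#'
#' @param variants variant-call data.frame (SNVs unless \code{allow_indels}).
#' @param db an \code{annotation_db} providing \code{esp6500}, \code{kg1000},
#'   \code{cosmic}, \code{tcga_gbm} and \code{dbsnp137}.
#' @param cohort_variants pooled cohort calls for dataset frequency.
#' @param n_samples cohort size.
#' @param thresholds a \code{gbm_thresholds} object.
#' @param allow_indels the cascade is defined for SNVs; set TRUE to apply it
#'   to indels as well (off by default).
#' @return data.frame: the input plus \code{reason} (one of esp_common,
#'   kg_common, cosmic_hit, tcga_hit, dataset_recurrent, dbsnp_known,
#'   passed_all), \code{step_index} (1-7) and \code{label}
#'   (cancer_specific/non_specific).
#' @export
classify_cancer_specific <- function(variants, db, cohort_variants, n_samples,
                                     thresholds = default_thresholds(),
                                     allow_indels = FALSE) {
  validate_variant_calls(variants)
  if (!allow_indels && nrow(variants) && any(variants$kind != "SNV"))
    stop("the cascade is defined for SNVs; set allow_indels = TRUE to include indels")
  for (src in c("esp6500", "kg1000", "cosmic", "tcga_gbm", "dbsnp137")) db_source(db, src)
  esp <- db_frequency(db, "esp6500", variants)
  kg <- db_frequency(db, "kg1000", variants)
  in_cosmic <- db_member(db, "cosmic", variants)
  in_tcga <- db_member(db, "tcga_gbm", variants)
  ds <- dataset_frequency(variants, cohort_variants, n_samples)
  in_dbsnp <- db_member(db, "dbsnp137", variants)

  reason <- rep("passed_all", nrow(variants))
  step <- rep(7L, nrow(variants))
  undecided <- rep(TRUE, nrow(variants))
  decide <- function(hit, r, s) {
    take <- undecided & hit
    reason[take] <<- r
    step[take] <<- s
    undecided[take] <<- FALSE
  }
  decide(esp >= thresholds$esp_cut, "esp_common", 1L)
  decide(kg >= thresholds$kg_cut, "kg_common", 2L)
  decide(in_cosmic, "cosmic_hit", 3L)
  decide(in_tcga, "tcga_hit", 4L)
  decide(ds >= thresholds$dataset_cut, "dataset_recurrent", 5L)
  decide(in_dbsnp, "dbsnp_known", 6L)

  out <- variants
  out$reason <- reason
  out$step_index <- step
  out$label <- unname(cascade_labels[reason])
  out
}

#' Run the cascade over a cohort and partition the calls
#'
#' Applies [classify_cancer_specific()] to every call in the cohort (dataset
#' frequency computed against the same cohort) and reports the
#' cancer-specific/non-specific partition with a per-step attrition log.
#' Every input variant lands in exactly one partition.
#'
#' @param cohort_variants pooled variant-call data.frame over all samples.
#' @param db an \code{annotation_db} (see [classify_cancer_specific()]).
#' @param n_samples cohort size; defaults to the number of distinct
#'   \code{sample_id}s present.
#' @inheritParams classify_cancer_specific
#' @return list with \code{verdicts} (annotated table), \code{cancer_specific}
#'   and \code{non_specific} (the two partitions), \code{attrition}
#'   (reason/count over the seven outcomes) and \code{fraction_cancer_specific}.
#' @export
run_cascade <- function(cohort_variants, db, n_samples = NULL,
                        thresholds = default_thresholds(), allow_indels = FALSE) {
  if (is.null(n_samples)) n_samples <- max(1L, length(unique(cohort_variants$sample_id)))
  verdicts <- classify_cancer_specific(cohort_variants, db, cohort_variants,
                                       n_samples, thresholds, allow_indels)
  attrition <- data.frame(
    reason = cascade_reasons,
    count = vapply(cascade_reasons, function(r) sum(verdicts$reason == r), integer(1)),
    row.names = NULL
  )
  cs <- verdicts[verdicts$label == "cancer_specific", , drop = FALSE]
  ns <- verdicts[verdicts$label == "non_specific", , drop = FALSE]
  stopifnot(nrow(cs) + nrow(ns) == nrow(cohort_variants))
  for (i in seq_len(nrow(attrition))) {
    message("cascade ", attrition$reason[i], ": ", attrition$count[i])
  }
  list(verdicts = verdicts, cancer_specific = cs, non_specific = ns,
       attrition = attrition,
       fraction_cancer_specific = if (nrow(verdicts)) nrow(cs) / nrow(verdicts) else NA_real_)
}

#' Gene-by-sample alteration matrix
#'
#' For a panel of genes, reports per sample whether it harbors an SNV, an
#' indel, both, or no alteration among the supplied (typically
#' cancer-specific) calls mapped to genes through the gene models.
#'
#' @param verdicts variant-call data.frame (e.g. the cancer-specific
#'   partition), all samples pooled.
#' @param panel character vector of gene symbols (matrix rows).
#' @param models named list of \code{gene_model}s used to map variants to
#'   genes by transcript-span overlap.
#' @param samples optional sample order for the columns; defaults to the
#'   distinct samples present.
#' @return character matrix gene x sample with values in
#'   \code{none/SNV/indel/both}. Panel genes absent from the models produce a
#'   warning and an all-none row.
#' @export
gene_panel_matrix <- function(verdicts, panel, models, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(verdicts$sample_id))
  m <- matrix("none", nrow = length(panel), ncol = length(samples),
              dimnames = list(panel, samples))
  if (!length(panel)) return(m)
  known <- unique(vapply(models, `[[`, character(1), "gene"))
  absent <- setdiff(panel, known)
  if (length(absent))
    warning("panel gene(s) absent from gene models: ", paste(absent, collapse = ", "))
  if (!nrow(verdicts) || !length(samples)) return(m)
  gene_hits <- genes_at(verdicts, models)
  for (i in seq_len(nrow(verdicts))) {
    if (is.na(gene_hits[i])) next
    for (g in intersect(strsplit(gene_hits[i], ",", fixed = TRUE)[[1]], panel)) {
      s <- verdicts$sample_id[i]
      typ <- if (verdicts$kind[i] == "SNV") "SNV" else "indel"
      cur <- m[g, s]
      m[g, s] <- if (cur == "none") typ else if (cur == typ) cur else "both"
    }
  }
  m
}

#' Mismatch-repair gene status per sample
#'
#' TRUE for a sample iff at least one of the supplied calls maps to a
#' mismatch-repair gene. The default list is the ten canonical MMR genes
#' (MSH2, MSH3, MSH6, MLH1, PMS2, MSH4, MSH5, MLH3, PMS1, PMS2L3); an intact
#' MMR panel (all FALSE) argues against a hypermutator/MSI phenotype.
#'
#' @param verdicts variant-call data.frame (typically the cancer-specific
#'   partition), all samples pooled.
#' @param models named list of \code{gene_model}s.
#' @param mmr_genes gene symbols to screen.
#' @param samples optional sample vector; defaults to those present.
#' @return named logical vector per sample.
#' @export
mmr_status <- function(verdicts, models,
                       mmr_genes = c("MSH2", "MSH3", "MSH6", "MLH1", "PMS2",
                                     "MSH4", "MSH5", "MLH3", "PMS1", "PMS2L3"),
                       samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(verdicts$sample_id))
  out <- stats::setNames(rep(FALSE, length(samples)), samples)
  if (!nrow(verdicts) || !length(samples)) return(out)
  gene_hits <- genes_at(verdicts, models)
  hit <- vapply(gene_hits, function(g) {
    !is.na(g) && length(intersect(strsplit(g, ",", fixed = TRUE)[[1]], mmr_genes)) > 0
  }, logical(1))
  for (s in unique(verdicts$sample_id[hit])) out[s] <- TRUE
  out
}
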