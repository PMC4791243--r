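#' Numeric cutoffs used throughout the pipeline
#'
#' Returns the full set of filtering thresholds as a named list of class
#' \code{gbm_thresholds}. Defaults are the cutoffs applied throughout the
#' analysis; every stage of the cascade takes this object so a run is fully
#' described by one configuration record.
#'
#' @param ... named overrides for individual cutoffs.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{min_alt_reads_dna}{minimum reads carrying the variant base for an
#'     exome SNV call to be kept (6).}
#'   \item{min_base_qual}{minimum Phred base quality (30, inclusive).}
#'   \item{esp_cut}{ESP6500 population frequency at or above which an SNV is
#'     considered a polymorphism (9e-05).}
#'   \item{kg_cut}{1000 Genomes frequency cutoff (5e-04).}
#'   \item{dataset_cut}{fraction of cohort samples carrying an identical allele
#'     at or above which it is treated as recurrent/germline (0.5).}
#'   \item{min_alt_reads_rna}{minimum altered-base reads supporting an editing
#'     candidate (3).}
#'   \item{min_edit_freq}{minimum altered-base frequency for an editing
#'     candidate (0.1).}
#'   \item{splice_dist}{editing candidates within this many bases of an
#'     annotated splice junction are removed (4, inclusive).}
#'   \item{homopolymer_min}{minimum reference single-base run length that
#'     disqualifies an editing candidate (5).}
#'   \item{read_trim}{number of bases discarded from the start of each read to
#'     suppress random-hexamer mispriming artifacts (6).}
#'   \item{multimap_flank}{flank (each side) of the uniqueness window used as a
#'     deterministic stand-in for a BLAT similarity search (25).}
#'   \item{splice_class_dist}{distance from an exon edge (intronic side) within
#'     which an SNV is classified as splice-site (2).}
#'   \item{flank_size}{upstream window defining the 5' flank class (3000).}
#'   \item{fc_cut}{absolute fold-change cutoff for differential expression (2).}
#'   \item{padj_cut}{adjusted-p cutoff for the RNA-seq DE table (0.05).}
#'   \item{p_cut}{p-value cutoff for the comparison DE table (0.05).}
#' }
#'
#' @return A named list of class \code{gbm_thresholds}.
#' @export
#' @examples
#' th <- default_thresholds(min_alt_reads_rna = 5)
#' th$esp_cut
default_thresholds <- function(...) {
  th <- list(
    min_alt_reads_dna = 6L,
    min_base_qual     = 30,
    esp_cut           = 0.00009,
    kg_cut            = 0.0005,
    dataset_cut       = 0.5,
    min_alt_reads_rna = 3L,
    min_edit_freq     = 0.1,
    splice_dist       = 4L,
    homopolymer_min   = 5L,
    read_trim         = 6L,
    multimap_flank    = 25L,
    splice_class_dist = 2L,
    flank_size        = 3000L,
    fc_cut            = 2,
    padj_cut          = 0.05,
    p_cut             = 0.05
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) stop("unknown threshold field(s): ", paste(bad, collapse = ", "))
    th[names(dots)] <- dots
  }
  validate_thresholds(th)
}

#' Validate a thresholds object
#'
#' @param th a named list as produced by [default_thresholds()] or read from
#'   YAML via [read_thresholds()].
#' @return the validated object, classed \code{gbm_thresholds}.
#' @export
validate_thresholds <- function(th) {
  need <- names(default_thresholds_fields())
  miss <- setdiff(need, names(th))
  if (length(miss)) stop("thresholds missing field(s): ", paste(miss, collapse = ", "))
  num <- vapply(th[need], function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) stop("thresholds must be single finite numbers: ",
                      paste(need[!num], collapse = ", "))
  if (any(unlist(th[need]) <= 0)) stop("all thresholds must be strictly positive")
  for (f in c("esp_cut", "kg_cut", "dataset_cut", "min_edit_freq", "padj_cut", "p_cut")) {
    if (th[[f]] > 1) stop("threshold '", f, "' is a frequency and must lie in (0, 1]")
  }
  structure(th[need], class = "gbm_thresholds")
}

default_thresholds_fields <- function() {
  list(min_alt_reads_dna = 1, min_base_qual = 1, esp_cut = 1, kg_cut = 1,
       dataset_cut = 1, min_alt_reads_rna = 1, min_edit_freq = 1,
       splice_dist = 1, homopolymer_min = 1, read_trim = 1, multimap_flank = 1,
       splice_class_dist = 1, flank_size = 1, fc_cut = 1, padj_cut = 1, p_cut = 1)
}

#' Read thresholds from a YAML configuration file
#'
#' @param path path to a YAML file whose top-level keys are threshold fields.
#' @return a validated \code{gbm_thresholds} object; fields absent from the
#'   file take their defaults.
#' @export
read_thresholds <- function(path) {
  y <- yaml::read_yaml(path)
  th <- unclass(default_thresholds())
  if (length(y)) {
    bad <- setdiff(names(y), names(th))
    if (length(bad)) stop("unknown threshold field(s) in ", path, ": ",
                          paste(bad, collapse = ", "))
    th[names(y)] <- y
  }
  validate_thresholds(th)
}

#' Write thresholds to YAML
#'
#' @param th a \code{gbm_thresholds} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_thresholds <- function(th, path) {
  th <- validate_thresholds(th)
  yaml::write_yaml(unclass(th), path)
  invisible(path)
}

#' @export
print.gbm_thresholds <- function(x, ...) {
  cat("Pipeline thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}
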