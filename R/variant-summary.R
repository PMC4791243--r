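#' Call-level quality filters for exome SNVs/indels
#'
#' Retains calls that fall inside the capture target, have base quality at or
#' above the cutoff, and are supported by at least the minimum number of
#' variant-carrying reads. Input order is preserved. Removals are attributed to
#' the first failing reason in the order off_target, low_qual, low_support.
#'
#' @param variants variant-call data.frame.
#' @param target_regions a \code{GRanges} of capture intervals (1-based, e.g.
#'   from [read_target_regions()]); an empty set is an error, distinct from
#'   "no overlap".
#' @param thresholds a \code{gbm_thresholds} object.
#' @return list with \code{retained} (filtered data.frame) and
#'   \code{attrition} (data.frame of reason/count).
#' @export
apply_call_filters <- function(variants, target_regions, thresholds = default_thresholds()) {
  if (length(target_regions) == 0L)
    stop("target region set is empty; refusing to filter against no capture design")
  validate_variant_calls(variants)
  if (nrow(variants) == 0L) {
    return(list(retained = variants,
                attrition = data.frame(reason = c("off_target", "low_qual", "low_support"),
                                       count = c(0L, 0L, 0L))))
  }
  q <- GenomicRanges::GRanges(variants$chrom, IRanges::IRanges(variants$pos, variants$pos))
  in_target <- IRanges::overlapsAny(q, target_regions, ignore.strand = TRUE)
  good_qual <- !is.na(variants$base_qual) & variants$base_qual >= thresholds$min_base_qual
  good_support <- !is.na(variants$alt_reads) &
    variants$alt_reads >= thresholds$min_alt_reads_dna
  reason <- rep(NA_character_, nrow(variants))
  reason[!good_support] <- "low_support"
  reason[!good_qual] <- "low_qual"
  reason[!in_target] <- "off_target"
  attrition <- data.frame(
    reason = c("off_target", "low_qual", "low_support"),
    count = c(sum(reason == "off_target", na.rm = TRUE),
              sum(reason == "low_qual", na.rm = TRUE),
              sum(reason == "low_support", na.rm = TRUE))
  )
  message("call filters removed ", sum(!is.na(reason)), "/", nrow(variants),
          " calls (off_target=", attrition$count[1], ", low_qual=",
          attrition$count[2], ", low_support=", attrition$count[3], ")")
  list(retained = variants[is.na(reason), , drop = FALSE], attrition = attrition)
}

#' Transition/transversion spectrum
#'
#' Counts the six unordered base-change types over an SNV set and reports the
#' transition/transversion ratio. Transitions are A<->G and C<->T.
#'
#' @param variants variant-call data.frame containing only SNVs.
#' @return list with \code{counts} (named vector over \code{A:G, C:T, A:C,
#'   A:T, C:G, G:T}), \code{ti}, \code{tv} and \code{ratio} (\code{NA} when
#'   there are no transversions: the ratio is undefined, not infinite).
#' @export
titv_ratio <- function(variants) {
  if (nrow(variants) && any(variants$kind != "SNV"))
    stop("titv_ratio() accepts SNVs only")
  pair <- function(r, a) paste(pmin(r, a), pmax(r, a), sep = ":")
  types <- c("A:G", "C:T", "A:C", "A:T", "C:G", "G:T")
  counts <- table(factor(pair(variants$ref, variants$alt), levels = types))
  counts <- stats::setNames(as.integer(counts), types)
  ti <- sum(counts[c("A:G", "C:T")])
  tv <- sum(counts[c("A:C", "A:T", "C:G", "G:T")])
  list(counts = counts, ti = ti, tv = tv,
       ratio = if (tv == 0L) NA_real_ else ti / tv)
}

#' Homozygous/heterozygous composition
#'
#' @param variants variant-call data.frame.
#' @return list with \code{hom}, \code{het} counts, \code{pct_hom},
#'   \code{pct_het} (summing to 100 on non-empty input) and \code{ratio}
#'   (hom/het; \code{NA} when there are no heterozygous calls).
#' @export
zygosity_split <- function(variants) {
  hom <- sum(variants$zygosity == "hom")
  het <- sum(variants$zygosity == "het")
  n <- hom + het
  list(hom = hom, het = het,
       pct_hom = if (n) 100 * hom / n else 0,
       pct_het = if (n) 100 * het / n else 0,
       ratio = if (het) hom / het else NA_real_)
}

functional_severity <- c(
  "nonsense", "frameshift_indel", "nonstop", "translation_start", "splice_site",
  "missense", "inframe_indel", "silent", "five_utr", "three_utr", "rna",
  "intron", "five_flank", "intergenic"
)

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Functional classification of a variant against gene models
#'
#' A simplified location/consequence annotator: each overlapping transcript
#' contributes one class by containment (CDS codon logic for coding SNVs,
#' frame arithmetic for coding indels, UTRs, non-coding-gene overlap as
#' \code{rna}, splice-site within 2 intronic bases of an exon edge, 5' flank
#' within \code{flank_size} upstream of the TSS, else intron/intergenic), and
#' the variant-level class is the most severe across transcripts under the
#' ranking nonsense > frameshift_indel > nonstop > translation_start >
#' splice_site > missense > inframe_indel > silent > 5'UTR > 3'UTR > rna >
#' intron > 5' flank > intergenic.
#'
#' @param variants variant-call data.frame.
#' @param models named list of \code{gene_model}s.
#' @param genome named \code{DNAStringSet} (needed for codon translation).
#' @param thresholds a \code{gbm_thresholds} object (uses
#'   \code{splice_class_dist} and \code{flank_size}).
#' @return character vector of classes, one per variant.
#' @export
classify_functional <- function(variants, models, genome,
                                thresholds = default_thresholds()) {
  validate_variant_calls(variants)
  vapply(seq_len(nrow(variants)), function(i)
    classify_one(variants[i, ], models, genome, thresholds), character(1))
}

classify_one <- function(v, models, genome, th) {
  classes <- vapply(models, function(tx) classify_against_tx(v, tx, genome, th),
                    character(1))
  classes <- classes[!is.na(classes)]
  if (!length(classes)) return("intergenic")
  classes[which.min(match(classes, functional_severity))]
}

classify_against_tx <- function(v, tx, genome, th) {
  if (tx$chrom != v$chrom) return(NA_character_)
  span <- c(min(tx$exons$start), max(tx$exons$end))
  pos <- v$pos
  if (pos >= span[1] && pos <= span[2]) {
    in_exon <- any(pos >= tx$exons$start & pos <= tx$exons$end)
    if (in_exon) {
      if (tx$biotype != "protein_coding") return("rna")
      if (is.na(tx$cds_start)) return("rna")
      if (v$kind != "SNV") {
        affected <- pos:(pos + max(nchar(v$ref), nchar(v$alt)) - 1L)
        in_cds <- any(affected >= tx$cds_start & affected <= tx$cds_end)
        if (!in_cds) return(utr_side(tx, pos))
        if (cds_length(tx) < 3L)
          stop("degenerate CDS (< 1 codon) in ", tx$transcript_id)
        sz <- nchar(v$alt) - nchar(v$ref)
        return(if (sz %% 3L != 0L) "frameshift_indel" else "inframe_indel")
      }
      if (pos < tx$cds_start || pos > tx$cds_end) return(utr_side(tx, pos))
      if (cds_length(tx) < 3L)
        stop("degenerate CDS (< 1 codon) in ", tx$transcript_id)
      return(coding_snv_class(v, tx, genome))
    }
    edges <- c(tx$exons$start, tx$exons$end)
    if (min(abs(pos - edges)) <= th$splice_class_dist) return("splice_site")
    return("intron")
  }
  if (tx$strand == "+") {
    if (pos >= span[1] - th$flank_size && pos < span[1]) return("five_flank")
  } else {
    if (pos > span[2] && pos <= span[2] + th$flank_size) return("five_flank")
  }
  NA_character_
}

utr_side <- function(tx, pos) {
  before_cds <- pos < tx$cds_start
  if (tx$strand == "+") {
    if (before_cds) "five_utr" else "three_utr"
  } else {
    if (before_cds) "three_utr" else "five_utr"
  }
}

coding_snv_class <- function(v, tx, genome) {
  cpos <- cds_positions(tx)
  i <- match(v$pos, cpos)
  if (is.na(i)) {
    # inside genomic CDS bounds but in an intron: splice/intron handled upstream
    return("intron")
  }
  codon_i <- (i - 1L) %/% 3L        # 0-based codon index
  within <- (i - 1L) %% 3L + 1L
  codon_pos <- cpos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  chr_seq <- genome[[tx$chrom]]
  bases <- vapply(codon_pos, function(p) as.character(chr_seq[p]), character(1))
  alt <- v$alt
  if (tx$strand == "-") {
    bases <- complement_base(bases)
    alt <- complement_base(alt)
  }
  ref_codon <- paste(bases, collapse = "")
  alt_bases <- bases
  alt_bases[within] <- alt
  alt_codon <- paste(alt_bases, collapse = "")
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (codon_i == 0L) {
    if (ref_codon == alt_codon) return("silent")
    return("translation_start")
  }
  if (identical(ref_aa, alt_aa)) return("silent")
  if (identical(alt_aa, "*")) return("nonsense")
  if (identical(ref_aa, "*")) return("nonstop")
  "missense"
}

#' Indel size spectrum
#'
#' Histograms signed indel sizes (insertions positive, deletions negative),
#' optionally restricted to indels overlapping coding sequence, and reports
#' the fraction of coding indels whose size is a multiple of three (in-frame).
#'
#' @param indels variant-call data.frame of insertions/deletions only.
#' @param models optional named list of \code{gene_model}s; when supplied, the
#'   coding histogram counts indels whose affected bases overlap a CDS exon.
#' @return list with \code{sizes} (named count vector), \code{coding_sizes},
#'   and \code{inframe_fraction} (\code{NA} with no coding indels).
#' @export
indel_spectrum <- function(indels, models = NULL) {
  if (nrow(indels) && any(indels$kind == "SNV"))
    stop("indel_spectrum() accepts insertions/deletions only")
  sz <- indel_size(indels)
  sizes <- table(sz)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  coding <- rep(TRUE, nrow(indels))
  if (!is.null(models) && nrow(indels)) {
    cds_gr <- cds_granges(models)
    if (length(cds_gr)) {
      q <- GenomicRanges::GRanges(
        indels$chrom,
        IRanges::IRanges(indels$pos, indels$pos + nchar(indels$ref) - 1L)
      )
      coding <- IRanges::overlapsAny(q, cds_gr, ignore.strand = TRUE)
    } else coding <- rep(FALSE, nrow(indels))
  }
  csz <- sz[coding]
  coding_sizes <- table(csz)
  coding_sizes <- stats::setNames(as.integer(coding_sizes), names(coding_sizes))
  list(sizes = sizes, coding_sizes = coding_sizes,
       inframe_fraction = if (length(csz)) mean(csz %% 3L == 0L) else NA_real_)
}

# exon-clipped CDS intervals of all coding models
cds_granges <- function(models) {
  rows <- lapply(models, function(tx) {
    if (is.na(tx$cds_start)) return(NULL)
    keep <- tx$exons$end >= tx$cds_start & tx$exons$start <= tx$cds_end
    ce <- tx$exons[keep, , drop = FALSE]
    data.frame(chrom = tx$chrom, start = pmax(ce$start, tx$cds_start),
               end = pmin(ce$end, tx$cds_end), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Direction concordance between two differential-expression tables
#'
#' Table \code{de_a} (RNA-seq of the cell lines vs normal) is filtered to
#' genes with at least a 2-fold change and adjusted p at or below 0.05; table
#' \code{de_b} (the comparison dataset) is filtered on its p-value at or below
#' 0.05. Over the genes common to both filtered sets, a gene is concordant
#' when its fold-change direction agrees.
#'
#' @param de_a data.frame with columns \code{gene}, \code{log2fc}, \code{padj}.
#' @param de_b data.frame with columns \code{gene}, \code{log2fc},
#'   \code{pvalue}.
#' @param thresholds a \code{gbm_thresholds} object (\code{fc_cut},
#'   \code{padj_cut}, \code{p_cut}).
#' @return list with \code{n_common}, \code{n_concordant} and \code{fraction}
#'   (\code{NA} when no genes are common — undefined, not zero).
#' @export
direction_concordance <- function(de_a, de_b, thresholds = default_thresholds()) {
  for (nm in c("gene", "log2fc")) {
    if (!nm %in% names(de_a) || !nm %in% names(de_b))
      stop("DE tables need 'gene' and 'log2fc' columns")
  }
  if (anyDuplicated(de_a$gene)) stop("duplicate genes in first DE table")
  if (anyDuplicated(de_b$gene)) stop("duplicate genes in second DE table")
  if (!"padj" %in% names(de_a)) stop("first DE table needs a 'padj' column")
  if (!"pvalue" %in% names(de_b)) stop("second DE table needs a 'pvalue' column")
  a <- de_a[abs(de_a$log2fc) >= log2(thresholds$fc_cut) &
              de_a$padj <= thresholds$padj_cut, , drop = FALSE]
  b <- de_b[de_b$pvalue <= thresholds$p_cut, , drop = FALSE]
  common <- intersect(a$gene, b$gene)
  if (!length(common))
    return(list(n_common = 0L, n_concordant = 0L, fraction = NA_real_))
  sa <- sign(a$log2fc[match(common, a$gene)])
  sb <- sign(b$log2fc[match(common, b$gene)])
  conc <- sum(sa == sb)
  list(n_common = length(common), n_concordant = conc,
       fraction = conc / length(common))
}
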