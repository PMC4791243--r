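#' Deterministic synthetic reference bundle with planted truth
#'
#' Builds the small multi-chromosome world every pipeline stage consumes: a
#' random genome (~1 Mb over three chromosomes) carrying planted features — a
#' labelled Alu/simple-repeat/other-repeat track, a homopolymer run, one
#' exactly duplicated 200-base segment (for the sequence-uniqueness filter),
#' capture-target intervals, and a set of multi-exon gene models whose coding
#' sequences are written into the genome (ATG, no internal stops, terminal
#' stop). Two of the genes mirror the exon architecture of the worked fusion
#' example: a 20-exon 5' partner whose first three exons carry 489 coding
#' bases ending at an exon boundary in phase 0, and a 5-exon 3' partner whose
#' exons 2-5 carry 177 coding bases followed by the stop codon. Everything is
#' a pure function of the seed.
#'
#' @param seed integer RNG seed.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a \code{truth_bundle} list: \code{genome} (DNAStringSet),
#'   \code{models}, \code{repeats}, \code{targets}, \code{homopolymer},
#'   \code{dup} (source/copy intervals), \code{chrom_sizes}, \code{seed}.
#' @export
generate_reference_bundle <- function(seed = 1L,
                                      chrom_sizes = c(chr1 = 400000L,
                                                      chr2 = 300000L,
                                                      chr3 = 300000L)) {
  stopifnot(all(chrom_sizes > 0))
  set.seed(seed)
  chars <- lapply(chrom_sizes, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))

  models <- list()
  add_gene <- function(gene, chrom, strand, tx_start, exon_lens, intron_len,
                       utr5, utr3, biotype = "protein_coding") {
    starts <- tx_start + c(0L, cumsum(exon_lens[-length(exon_lens)] + intron_len))
    ends <- starts + exon_lens - 1L
    exons <- data.frame(start = starts, end = ends)
    if (biotype == "protein_coding") {
      # utr5/utr3 are given in transcription sense
      epos <- unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))
      tpos <- if (strand == "-") rev(epos) else epos
      cds_t <- tpos[(utr5 + 1L):(length(tpos) - utr3)]
      cds_start <- min(cds_t); cds_end <- max(cds_t)
      n_cds <- length(cds_t)
      stopifnot(n_cds %% 3L == 0L)
      n_mid <- n_cds / 3L - 2L
      codons <- Biostrings::GENETIC_CODE
      sense <- names(codons)[codons != "*" ]
      cds_seq <- c("A", "T", "G",
                   unlist(strsplit(sample(sense, n_mid, replace = TRUE), "")),
                   "T", "A", "A")
      # write the mRNA-sense CDS into the genome at the transcription-ordered
      # positions; on the minus strand the genomic base is the complement
      chars[[chrom]][cds_t] <<- if (strand == "-") complement_base(cds_seq) else cds_seq
      tx <- gene_model(gene, paste0(gene, ".1"), chrom, strand, exons,
                       cds_start, cds_end, biotype)
    } else {
      tx <- gene_model(gene, paste0(gene, ".1"), chrom, strand, exons,
                       biotype = biotype)
    }
    models[[tx$transcript_id]] <<- tx
  }

  # 20-exon 5' fusion partner: exons 1-3 carry 100 UTR + 489 CDS (phase 0 at
  # the end of exon 3); 16 internal 120-nt coding exons; terminal exon with
  # 90 CDS (incl. stop) + 80 UTR
  add_gene("FUSA", "chr1", "+", 50001L,
           exon_lens = c(250L, 180L, 159L, rep(120L, 16L), 170L),
           intron_len = 400L, utr5 = 100L, utr3 = 80L)
  # 5-exon 3' partner: exon 1 = 60 UTR + 120 CDS (phase 0 entering exon 2);
  # exons 2-5 carry 177 CDS + stop, then 40 UTR
  add_gene("FUSB", "chr2", "+", 50001L,
           exon_lens = c(180L, 60L, 48L, 42L, 73L),
           intron_len = 300L, utr5 = 60L, utr3 = 43L)
  add_gene("MSH2", "chr1", "+", 80001L, exon_lens = c(220L, 180L, 200L),
           intron_len = 500L, utr5 = 70L, utr3 = 80L)
  add_gene("EGFR", "chr1", "+", 100001L, exon_lens = c(200L, 150L, 250L),
           intron_len = 450L, utr5 = 50L, utr3 = 100L)
  add_gene("GFD", "chr2", "+", 70001L, exon_lens = c(150L, 120L, 210L),
           intron_len = 350L, utr5 = 60L, utr3 = 60L)
  add_gene("GFE", "chr2", "+", 90001L, exon_lens = c(210L, 120L, 180L),
           intron_len = 350L, utr5 = 60L, utr3 = 90L)
  add_gene("GFF", "chr2", "+", 110001L, exon_lens = c(160L, 140L, 190L),
           intron_len = 400L, utr5 = 40L, utr3 = 90L)
  add_gene("TP53", "chr2", "-", 130001L, exon_lens = c(180L, 160L, 200L),
           intron_len = 420L, utr5 = 60L, utr3 = 60L)
  add_gene("GFC", "chr3", "-", 50001L, exon_lens = c(150L, 130L, 170L, 220L),
           intron_len = 380L, utr5 = 70L, utr3 = 60L)
  add_gene("LNC1", "chr3", "+", 100001L, exon_lens = c(300L, 250L),
           intron_len = 600L, utr5 = 0L, utr3 = 0L, biotype = "lncRNA")

  # planted homopolymer (7 A's), flanked so the run length is exactly 7
  chars[["chr1"]][199999L] <- "C"
  chars[["chr1"]][200000L:200006L] <- "A"
  chars[["chr1"]][200007L] <- "C"
  # one exactly duplicated 200-base segment (chr1 -> chr3)
  chars[["chr3"]][250001L:250200L] <- chars[["chr1"]][150001L:150200L]

  repeats_df <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3",
              "chr1", "chr2", "chr3", "chr1", "chr3"),
    start = c(250001L, 260001L, 270001L, 200001L, 210001L, 150001L,
              280001L, 220001L, 160001L, 285001L, 165001L),
    end = c(250300L, 260300L, 270300L, 200300L, 210300L, 150300L,
            280100L, 220100L, 160100L, 285100L, 165100L),
    class = c(rep("Alu", 6L), rep("simple_repeat", 3L), rep("other_repeat", 2L)),
    stringsAsFactors = FALSE
  )
  repeats <- GenomicRanges::GRanges(repeats_df$chrom,
                                    IRanges::IRanges(repeats_df$start, repeats_df$end))
  S4Vectors::mcols(repeats)$name <- repeats_df$class
  S4Vectors::mcols(repeats)$class <- repeats_df$class

  targets <- GenomicRanges::GRanges(
    names(chrom_sizes),
    IRanges::IRanges(1L, pmax(1L, as.integer(chrom_sizes) - 50000L))
  )

  genome <- Biostrings::DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- names(chrom_sizes)
  structure(list(
    genome = genome, models = models, repeats = repeats, targets = targets,
    homopolymer = list(chrom = "chr1", start = 200000L, end = 200006L),
    dup = list(src = list(chrom = "chr1", start = 150001L, end = 150200L),
               copy = list(chrom = "chr3", start = 250001L, end = 250200L)),
    chrom_sizes = chrom_sizes, seed = seed
  ), class = "truth_bundle")
}

base_at <- function(genome, chrom, pos) {
  vapply(seq_along(pos), function(i)
    as.character(genome[[chrom[i]]][pos[i]]), character(1))
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# candidate positions inside the capture targets, away from planted features
target_positions <- function(bundle) {
  unlist(lapply(seq_along(bundle$targets), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(bundle$targets))[i]
    seq.int(BiocGenerics::start(bundle$targets)[i],
            BiocGenerics::end(bundle$targets)[i])
  }), use.names = FALSE)
}

#' Plant a cohort of exome variants with forced cascade outcomes
#'
#' Emits per-sample variant calls whose database annotations force exactly the
#' requested cascade reason for each planted SNV, together with the site
#' tables for the five annotation sources. Zygosity is drawn with a
#' configurable hom:het ratio (default 1:8) and the substitution spectrum with
#' a configurable Ti/Tv ratio (default 2.42). Variants are given support and
#' quality that pass the call-level filters and unique positions inside the
#' capture targets. Indels with a skewed signed-size spectrum are planted
#' separately (half inside coding exons).
#'
#' @param bundle a \code{truth_bundle}.
#' @param seed integer seed (independent of the bundle seed).
#' @param n_samples cohort size (default 6).
#' @param mix named counts per cascade reason (esp_common, kg_common,
#'   cosmic_hit, tcga_hit, dataset_recurrent, dbsnp_known, passed_all).
#' @param hom_het_ratio expected hom/het ratio (default 1/8).
#' @param titv expected transition/transversion ratio (default 2.42).
#' @param n_indels number of planted indels.
#' @param esp_freq,kg_freq frequencies written for esp_common/kg_common
#'   alleles; must be at or above the respective cutoffs or the requested mix
#'   is impossible (the cascade would not produce the requested reason).
#' @param thresholds a \code{gbm_thresholds} object (mix consistency checks).
#' @return the bundle with a \code{cohort} element: \code{variants} (pooled
#'   SNVs), \code{by_sample}, \code{indels}, \code{db} (annotation_db),
#'   \code{db_tables}, \code{n_samples} and \code{truth} (per-variant planted
#'   reason and per-indel sizes).
#' @export
plant_cohort_variants <- function(bundle, seed = 1L, n_samples = 6L,
                                  mix = c(esp_common = 20L, kg_common = 20L,
                                          cosmic_hit = 15L, tcga_hit = 15L,
                                          dataset_recurrent = 10L,
                                          dbsnp_known = 60L, passed_all = 25L),
                                  hom_het_ratio = 1 / 8, titv = 2.42,
                                  n_indels = 40L,
                                  esp_freq = 0.001, kg_freq = 0.01,
                                  thresholds = default_thresholds()) {
  stopifnot(inherits(bundle, "truth_bundle"))
  bad <- setdiff(names(mix), cascade_reasons)
  if (length(bad)) stop("unknown mix categor(ies): ", paste(bad, collapse = ", "))
  if (esp_freq < thresholds$esp_cut)
    stop("impossible mix: esp_common planted below the ESP6500 cutoff")
  if (kg_freq < thresholds$kg_cut)
    stop("impossible mix: kg_common planted below the 1000 Genomes cutoff")
  n_recurrent_samples <- as.integer(ceiling(n_samples * thresholds$dataset_cut))
  if (n_recurrent_samples / n_samples < thresholds$dataset_cut)
    stop("impossible mix: dataset_recurrent cannot reach the dataset cutoff")
  set.seed(seed + 1L)

  n_snv <- sum(mix)
  pool <- target_positions(bundle)
  pick <- sample(seq_along(pool), n_snv + n_indels + 200L)
  # map flat indices back to (chrom, pos)
  widths <- BiocGenerics::width(bundle$targets)
  chrom_of <- rep(as.character(GenomeInfoDb::seqnames(bundle$targets)), widths)
  pos_all <- pool[pick]
  chrom_all <- chrom_of[pick]
  keep <- !duplicated(paste(chrom_all, pos_all))
  pos_all <- pos_all[keep][seq_len(n_snv + n_indels)]
  chrom_all <- chrom_all[keep][seq_len(n_snv + n_indels)]

  reason <- rep(names(mix), times = mix)
  idx <- seq_len(n_snv)
  chrom <- chrom_all[idx]; pos <- pos_all[idx]
  ref <- base_at(bundle$genome, chrom, pos)
  is_ti <- stats::runif(n_snv) < titv / (1 + titv)
  alt <- ifelse(is_ti, transition_of[ref],
                vapply(ref, function(b) sample(transversions_of[[b]], 1L), character(1)))
  zyg <- ifelse(stats::runif(n_snv) < hom_het_ratio / (1 + hom_het_ratio), "hom", "het")
  depth <- 60L
  alt_reads <- ifelse(zyg == "hom", 57L, 31L)
  qual <- sample(30:40, n_snv, replace = TRUE)

  carriers <- lapply(seq_len(n_snv), function(i) {
    if (reason[i] == "dataset_recurrent") {
      sort(sample(n_samples, n_recurrent_samples))
    } else sample(n_samples, 1L)
  })
  sample_ids <- paste0("S", seq_len(n_samples))

  site_df <- function(sel, freq = NULL) {
    df <- data.frame(chrom = chrom[sel], pos = pos[sel], ref = ref[sel],
                     alt = alt[sel], stringsAsFactors = FALSE)
    if (!is.null(freq)) df$freq <- rep(freq, length.out = nrow(df))
    df
  }
  db_tables <- list(
    esp6500 = site_df(reason == "esp_common", esp_freq),
    kg1000 = site_df(reason == "kg_common", kg_freq),
    cosmic = site_df(reason == "cosmic_hit"),
    tcga_gbm = site_df(reason == "tcga_hit"),
    # cosmic/tcga alleles are also known SNP positions: the rescue steps
    # precede the dbSNP step, so the planted reason must survive
    dbsnp137 = site_df(reason %in% c("dbsnp_known", "cosmic_hit", "tcga_hit"))
  )
  check_reason <- vapply(seq_len(n_snv), function(i) {
    # independent re-statement of the written rules, for mix validation only
    if (reason[i] == "esp_common" && !(esp_freq >= thresholds$esp_cut)) return(FALSE)
    if (reason[i] == "kg_common" && !(kg_freq >= thresholds$kg_cut)) return(FALSE)
    if (reason[i] == "dataset_recurrent" &&
        !(length(carriers[[i]]) / n_samples >= thresholds$dataset_cut)) return(FALSE)
    TRUE
  }, logical(1))
  if (!all(check_reason)) stop("impossible mix: a planted category cannot force its reason")

  rows <- lapply(seq_len(n_snv), function(i) {
    data.frame(
      sample_id = sample_ids[carriers[[i]]], chrom = chrom[i], pos = pos[i],
      ref = ref[i], alt = alt[i], zygosity = zyg[i], depth = depth,
      alt_reads = alt_reads[i], base_qual = qual[i],
      esp6500 = if (reason[i] == "esp_common") esp_freq else 0,
      kg1000 = if (reason[i] == "kg_common") kg_freq else 0,
      dbsnp137 = reason[i] %in% c("dbsnp_known", "cosmic_hit", "tcga_hit"),
      cosmic = reason[i] == "cosmic_hit",
      tcga_gbm = reason[i] == "tcga_hit",
      stringsAsFactors = FALSE
    )
  })
  variants <- do.call(rbind, rows)
  variants$kind <- variant_kind(variants$ref, variants$alt)
  validate_variant_calls(variants)

  # indels: skewed size spectrum, half anchored inside coding exons
  if (n_indels == 0L) {
    indels <- variants[0, , drop = FALSE]
    isz <- integer(0); ichrom <- character(0); ipos <- integer(0)
    n_coding <- 0L
  } else {
  ipos <- pos_all[n_snv + seq_len(n_indels)]
  ichrom <- chrom_all[n_snv + seq_len(n_indels)]
  cds_gr <- cds_granges(bundle$models)
  cds_chrom <- as.character(GenomeInfoDb::seqnames(cds_gr))
  n_coding <- n_indels %/% 2L
  cds_pick <- sample(length(cds_gr), n_coding, replace = TRUE)
  ichrom[seq_len(n_coding)] <- cds_chrom[cds_pick]
  ipos[seq_len(n_coding)] <- vapply(cds_pick, function(k)
    sample(seq.int(BiocGenerics::start(cds_gr)[k],
                   BiocGenerics::end(cds_gr)[k] - 10L), 1L), integer(1))
  size_support <- c(-49:-1, 1:29)
  size_p <- 1 / abs(size_support)^1.5
  size_p[size_support %% 3L == 0L] <- size_p[size_support %% 3L == 0L] * 3
  isz <- sample(size_support, n_indels, replace = TRUE, prob = size_p / sum(size_p))
  iref <- character(n_indels); ialt <- character(n_indels)
  for (i in seq_len(n_indels)) {
    anchor <- base_at(bundle$genome, ichrom[i], ipos[i])
    if (isz[i] < 0) {
      delled <- paste(vapply(seq_len(-isz[i]), function(k)
        base_at(bundle$genome, ichrom[i], ipos[i] + k), character(1)), collapse = "")
      iref[i] <- paste0(anchor, delled); ialt[i] <- anchor
    } else {
      iref[i] <- anchor
      ialt[i] <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), isz[i],
                                             replace = TRUE), collapse = ""))
    }
  }
  indels <- data.frame(
    sample_id = sample_ids[sample(n_samples, n_indels, replace = TRUE)],
    chrom = ichrom, pos = ipos, ref = iref, alt = ialt,
    zygosity = sample(c("hom", "het"), n_indels, TRUE, prob = c(1, 8)),
    depth = depth, alt_reads = 25L, base_qual = 34,
    esp6500 = 0, kg1000 = 0, dbsnp137 = FALSE, cosmic = FALSE, tcga_gbm = FALSE,
    stringsAsFactors = FALSE
  )
  indels$kind <- variant_kind(indels$ref, indels$alt)
  validate_variant_calls(indels)
  }

  truth <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      reason = reason, zygosity = zyg, is_transition = is_ti,
                      n_carriers = lengths(carriers), stringsAsFactors = FALSE)
  all_calls <- rbind(variants, indels)
  bundle$cohort <- list(
    variants = variants, indels = indels, all = all_calls,
    by_sample = split(all_calls, factor(all_calls$sample_id, levels = sample_ids)),
    db_tables = db_tables, db = do.call(annotation_db, db_tables),
    n_samples = n_samples, sample_ids = sample_ids,
    truth = list(snv = truth,
                 indel = data.frame(chrom = ichrom, pos = ipos, size = isz,
                                    coding = seq_len(n_indels) <= n_coding))
  )
  bundle
}
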