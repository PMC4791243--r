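#' Discard read-start base observations
#'
#' Removes pileup observations whose base sits within the first
#' \code{read_trim} bases of its read (default 6), suppressing artificial
#' mismatches caused by random-hexamer priming. Site support is always
#' recomputed from the retained observations.
#'
#' @param support a read-support table (see [read_support_table()]).
#' @param thresholds a \code{gbm_thresholds} object.
#' @return the trimmed support table.
#' @export
trim_read_start_support <- function(support, thresholds = default_thresholds()) {
  validate_support_table(support)
  support[support$read_offset > thresholds$read_trim, , drop = FALSE]
}

#' Per-site support counts from a pileup table
#'
#' @param sites data.frame with sample_id, chrom, pos, alt columns.
#' @param support read-support table (already trimmed, if desired).
#' @return \code{sites} with \code{alt_reads}, \code{total_reads} and
#'   \code{edit_freq} columns recomputed (freq NA when total is 0).
#' @export
site_support <- function(sites, support) {
  skey <- paste(support$sample_id, support$chrom, support$pos, sep = ":")
  qkey <- paste(sites$sample_id, sites$chrom, sites$pos, sep = ":")
  tot <- table(skey)
  m <- match(skey, qkey)
  altc <- table(skey[!is.na(m) & support$base == sites$alt[m]])
  n_tot <- as.integer(tot[qkey]); n_tot[is.na(n_tot)] <- 0L
  n_alt <- as.integer(altc[qkey]); n_alt[is.na(n_alt)] <- 0L
  sites$alt_reads <- n_alt
  sites$total_reads <- n_tot
  sites$edit_freq <- ifelse(n_tot > 0L, n_alt / n_tot, NA_real_)
  sites
}

#' Region class of candidate editing sites
#'
#' @param sites data.frame with chrom, pos.
#' @param repeats a \code{repeat_track}.
#' @return character vector: \code{Alu}, \code{non_Alu_repeat} or
#'   \code{non_repeat}.
#' @export
classify_region <- function(sites, repeats) {
  cl <- repeat_class_at(repeats, sites$chrom, sites$pos)
  out <- rep("non_repeat", nrow(sites))
  out[!is.na(cl) & cl == "Alu"] <- "Alu"
  out[!is.na(cl) & cl != "Alu"] <- "non_Alu_repeat"
  out
}

#' Reference homopolymer run length containing a position
#' @param genome named \code{DNAStringSet}.
#' @param chrom,pos site coordinates (scalar).
#' @return integer length of the single-base run that contains \code{pos}.
#' @export
homopolymer_run_length <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) stop("genome lacks chromosome ", chrom)
  s <- genome[[chrom]]
  n <- length(s)
  b <- as.character(s[pos])
  left <- pos
  while (left > 1L && as.character(s[left - 1L]) == b) left <- left - 1L
  right <- pos
  while (right < n && as.character(s[right + 1L]) == b) right <- right + 1L
  right - left + 1L
}

# number of exact genomic occurrences (both strands) of the window centred on
# a site; > 1 marks regions with high similarity elsewhere in the genome
multimap_occurrences <- function(genome, chrom, pos, flank) {
  if (!chrom %in% names(genome)) stop("genome lacks chromosome ", chrom)
  s <- genome[[chrom]]
  from <- max(1L, pos - flank)
  to <- min(length(s), pos + flank)
  win <- s[from:to]
  fwd <- sum(Biostrings::vcountPattern(win, genome))
  rev <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(win), genome))
  fwd + rev
}

#' Artifact filters for non-Alu editing candidates
#'
#' Computes a pass/fail verdict per candidate for the five filters applied to
#' sites outside Alu elements (Alu sites bypass all five):
#' \describe{
#'   \item{support}{at least \code{min_alt_reads_rna} altered-base reads and
#'     altered-base frequency at least \code{min_edit_freq} (both inclusive).}
#'   \item{simple_repeat}{fails inside a simple-repeat interval.}
#'   \item{splice}{fails within \code{splice_dist} bases (inclusive) of an
#'     annotated splice junction.}
#'   \item{homopolymer}{fails when the site lies in a reference single-base
#'     run of length >= \code{homopolymer_min} (the site's own base counts
#'     toward the run).}
#'   \item{multimap}{fails when the (2*flank+1)-base reference window centred
#'     on the site occurs more than once in the genome (either strand) — a
#'     deterministic sequence-uniqueness stand-in for a similarity search.}
#' }
#'
#' @param sites data.frame with sample_id, chrom, pos, alt and the support
#'   columns from [site_support()] (computed on the trimmed pileup).
#' @param genome named \code{DNAStringSet}.
#' @param junctions data.frame of splice junctions (chrom, pos), e.g. from
#'   [splice_junctions()].
#' @param repeats a \code{repeat_track}.
#' @param thresholds a \code{gbm_thresholds} object.
#' @return logical data.frame with columns \code{support},
#'   \code{simple_repeat}, \code{splice}, \code{homopolymer},
#'   \code{multimap}; TRUE = pass.
#' @export
site_filters <- function(sites, genome, junctions, repeats,
                         thresholds = default_thresholds()) {
  n <- nrow(sites)
  if (n == 0L) {
    return(data.frame(support = logical(0), simple_repeat = logical(0),
                      splice = logical(0), homopolymer = logical(0),
                      multimap = logical(0)))
  }
  support <- sites$alt_reads >= thresholds$min_alt_reads_rna &
    !is.na(sites$edit_freq) & sites$edit_freq >= thresholds$min_edit_freq
  simple <- S4Vectors::mcols(repeats)$class == "simple_repeat"
  in_simple <- if (any(simple)) {
    q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    IRanges::overlapsAny(q, repeats[simple], ignore.strand = TRUE)
  } else rep(FALSE, n)
  near_junction <- vapply(seq_len(n), function(i) {
    j <- junctions$pos[junctions$chrom == sites$chrom[i]]
    length(j) > 0L && min(abs(sites$pos[i] - j)) <= thresholds$splice_dist
  }, logical(1))
  homopoly <- vapply(seq_len(n), function(i) {
    homopolymer_run_length(genome, sites$chrom[i], sites$pos[i]) >=
      thresholds$homopolymer_min
  }, logical(1))
  multi <- vapply(seq_len(n), function(i) {
    multimap_occurrences(genome, sites$chrom[i], sites$pos[i],
                         thresholds$multimap_flank) > 1L
  }, logical(1))
  data.frame(support = support, simple_repeat = !in_simple,
             splice = !near_junction, homopolymer = !homopoly,
             multimap = !multi)
}

#' Subtract known editing and matched genomic variation
#'
#' Removes candidates whose exact allele is in the normal-brain editome (no
#' disease-context interest) or whose position carries a DNA variant in the
#' matched whole-exome calls of the same sample (genomic variation, not
#' editing). A sample without a matched WES call set is an error, because
#' silently skipping the subtraction inflates the call set.
#'
#' @param sites candidate data.frame (sample_id, chrom, pos, ref, alt).
#' @param normal_editome site table (chrom, pos, ref, alt).
#' @param wes_by_sample named list, sample_id -> variant-call data.frame of
#'   that sample's exome calls (possibly zero-row).
#' @return list with \code{retained}, \code{n_editome}, \code{n_wes}.
#' @export
subtract_known <- function(sites, normal_editome, wes_by_sample) {
  miss <- setdiff(unique(sites$sample_id), names(wes_by_sample))
  if (length(miss))
    stop("no matched WES call set for sample(s): ", paste(miss, collapse = ", "))
  in_editome <- allele_key(sites) %in% allele_key(normal_editome)
  site_poskey <- paste(sites$sample_id, sites$chrom, sites$pos, sep = ":")
  wes_poskey <- unlist(lapply(names(wes_by_sample), function(s) {
    w <- wes_by_sample[[s]]
    if (!nrow(w)) character(0) else paste(s, w$chrom, w$pos, sep = ":")
  }))
  in_wes <- site_poskey %in% wes_poskey
  drop_editome <- in_editome
  drop_wes <- !in_editome & in_wes
  list(retained = sites[!(drop_editome | drop_wes), , drop = FALSE],
       n_editome = sum(drop_editome), n_wes = sum(drop_wes))
}

#' Editing type from the base change
#'
#' Reported on reference-strand alleles: A>G and its complementary read T>C
#' are ADAR-type (A-to-I); C>T and G>A are APOBEC-type (C-to-U); anything
#' else is \code{other}.
#'
#' @param ref,alt single-base allele vectors.
#' @return character vector in \code{ADAR}/\code{APOBEC}/\code{other}.
#' @export
edit_type <- function(ref, alt) {
  chg <- paste0(ref, ">", alt)
  out <- rep("other", length(chg))
  out[chg %in% c("A>G", "T>C")] <- "ADAR"
  out[chg %in% c("C>T", "G>A")] <- "APOBEC"
  out
}

#' Genic class of sites (exonic / UTR / intronic / intergenic)
#'
#' Coding-exon positions are \code{exonic}; exon positions of a coding gene
#' outside its CDS are \code{UTR}; exon positions of non-coding genes are
#' counted as \code{exonic}; positions inside a transcript span but not in an
#' exon are \code{intronic}; everything else is \code{intergenic}. When
#' transcripts disagree the most gene-proximal class wins
#' (exonic > UTR > intronic > intergenic).
#'
#' @param sites data.frame with chrom, pos.
#' @param models named list of \code{gene_model}s.
#' @return character vector of classes.
#' @export
genic_class <- function(sites, models) {
  rank <- c(exonic = 1L, UTR = 2L, intronic = 3L, intergenic = 4L)
  vapply(seq_len(nrow(sites)), function(i) {
    best <- "intergenic"
    for (tx in models) {
      if (tx$chrom != sites$chrom[i]) next
      pos <- sites$pos[i]
      if (pos < min(tx$exons$start) || pos > max(tx$exons$end)) next
      cl <- if (any(pos >= tx$exons$start & pos <= tx$exons$end)) {
        if (tx$biotype == "protein_coding" && !is.na(tx$cds_start) &&
            pos >= tx$cds_start && pos <= tx$cds_end) "exonic"
        else if (tx$biotype == "protein_coding") "UTR"
        else "exonic"
      } else "intronic"
      if (rank[cl] < rank[best]) best <- cl
    }
    best
  }, character(1))
}

#' Recurrence of editing sites across samples
#'
#' @param sites data.frame with sample_id, chrom, pos, ref, alt.
#' @param n_samples total samples in the cohort (defaults to those present).
#' @return list with \code{per_site} (data.frame chrom/pos/ref/alt/n_samples)
#'   and \code{distribution} (named count vector over 1..n_samples; sums to
#'   the number of distinct sites).
#' @export
recurrence <- function(sites, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- max(1L, length(unique(sites$sample_id)))
  u <- unique(sites[c("sample_id", "chrom", "pos", "ref", "alt")])
  k <- allele_key(u)
  cnt <- table(k)
  per_site <- unique(u[c("chrom", "pos", "ref", "alt")])
  per_site$n_samples <- as.integer(cnt[allele_key(per_site)])
  dist <- table(factor(per_site$n_samples, levels = seq_len(n_samples)))
  list(per_site = per_site,
       distribution = stats::setNames(as.integer(dist), seq_len(n_samples)))
}

editing_stages <- c("polymorphism", "read_trim", "support", "simple_repeat",
                    "splice", "homopolymer", "multimap", "editome", "wes")

#' Run the full RNA-editing detection cascade
#'
#' Stage order: (1) polymorphism subtraction — any candidate whose allele is
#' listed in dbSNP 137, 1000 Genomes or ESP6500 is removed (membership, not
#' frequency, at this stage); (2) the first \code{read_trim} bases of every
#' read are discarded and site support recomputed; (3) candidates split into
#' Alu and non-Alu by the repeat track; (4) the five artifact filters of
#' [site_filters()] applied to non-Alu candidates only (a support failure
#' caused by the trim — passing before, failing after — is attributed to the
#' \code{read_trim} stage, otherwise to \code{support}; the remaining filters
#' attribute in the order simple_repeat, splice, homopolymer, multimap);
#' (5) survivors merged with the Alu set; (6) normal-editome then matched-WES
#' subtraction; (7) typing (ADAR/APOBEC/other), region and genic
#' classification, and cross-sample recurrence.
#'
#' @param rna_variants RNA variant candidates: variant-call data.frame (SNVs).
#' @param db an \code{annotation_db} providing dbsnp137, kg1000, esp6500.
#' @param support read-support (pileup) table, untrimmed.
#' @param models named list of \code{gene_model}s.
#' @param repeats a \code{repeat_track}.
#' @param genome named \code{DNAStringSet}.
#' @param normal_editome site table (chrom, pos, ref, alt).
#' @param wes_by_sample named list of matched exome call sets per sample.
#' @param thresholds a \code{gbm_thresholds} object.
#' @return list with \code{sites} (retained editing events with support,
#'   region/genic class, type and filter verdicts), \code{attrition}
#'   (stage/count; sums to input minus output), \code{breakdowns} (region,
#'   genic, type-by-region fractions and recurrence distribution).
#' @export
run_editing_pipeline <- function(rna_variants, db, support, models, repeats,
                                 genome, normal_editome, wes_by_sample,
                                 thresholds = default_thresholds()) {
  validate_variant_calls(rna_variants)
  if (nrow(rna_variants) && any(rna_variants$kind != "SNV"))
    stop("editing candidates must be single-base substitutions")
  n_in <- nrow(rna_variants)
  attr_count <- stats::setNames(integer(length(editing_stages)), editing_stages)

  # (1) polymorphism subtraction by database membership
  poly <- db_member(db, "dbsnp137", rna_variants) |
    db_member(db, "kg1000", rna_variants) |
    db_member(db, "esp6500", rna_variants)
  attr_count["polymorphism"] <- sum(poly)
  sites <- rna_variants[!poly, , drop = FALSE]

  # (2) read-start trim; support before and after
  trimmed <- trim_read_start_support(support, thresholds)
  pre <- site_support(sites, support)
  sites <- site_support(sites, trimmed)

  # (3) Alu / non-Alu split
  sites$region_class <- classify_region(sites, repeats)
  is_alu <- sites$region_class == "Alu"
  alu <- sites[is_alu, , drop = FALSE]
  non_alu <- sites[!is_alu, , drop = FALSE]
  pre_non_alu <- pre[!is_alu, , drop = FALSE]

  # (4) five artifact filters, non-Alu only
  verdicts <- site_filters(non_alu, genome, splice_junctions(models), repeats,
                           thresholds)
  pre_support_ok <- pre_non_alu$alt_reads >= thresholds$min_alt_reads_rna &
    !is.na(pre_non_alu$edit_freq) &
    pre_non_alu$edit_freq >= thresholds$min_edit_freq
  stage <- rep(NA_character_, nrow(non_alu))
  stage[!verdicts$multimap] <- "multimap"
  stage[!verdicts$homopolymer] <- "homopolymer"
  stage[!verdicts$splice] <- "splice"
  stage[!verdicts$simple_repeat] <- "simple_repeat"
  stage[!verdicts$support] <- ifelse(pre_support_ok[!verdicts$support],
                                     "read_trim", "support")
  for (s in c("read_trim", "support", "simple_repeat", "splice", "homopolymer",
              "multimap")) {
    attr_count[s] <- sum(stage == s, na.rm = TRUE)
  }
  for (nm in names(verdicts)) non_alu[[paste0("filter_", nm)]] <- verdicts[[nm]]
  kept_non_alu <- non_alu[is.na(stage), , drop = FALSE]

  # (5) merge Alu (bypasses the five filters) with surviving non-Alu
  for (nm in names(verdicts)) alu[[paste0("filter_", nm)]] <- NA
  merged <- rbind(alu, kept_non_alu)

  # (6) normal editome, then matched WES subtraction
  sub <- subtract_known(merged, normal_editome, wes_by_sample)
  attr_count["editome"] <- sub$n_editome
  attr_count["wes"] <- sub$n_wes
  out <- sub$retained

  # (7) typing, genic classification, recurrence
  out$edit_type <- edit_type(out$ref, out$alt)
  out$genic_class <- genic_class(out, models)
  n_samples <- max(1L, length(unique(rna_variants$sample_id)))
  rec <- recurrence(out, n_samples)

  attrition <- data.frame(stage = editing_stages,
                          count = unname(attr_count[editing_stages]))
  stopifnot(n_in - nrow(out) == sum(attrition$count))
  for (i in seq_len(nrow(attrition))) {
    message("editing ", attrition$stage[i], ": removed ", attrition$count[i])
  }
  frac_tab <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    if (length(x)) as.numeric(t) / length(x) else as.numeric(t) * NA
  }
  breakdowns <- list(
    region = stats::setNames(frac_tab(out$region_class,
                                      c("Alu", "non_Alu_repeat", "non_repeat")),
                             c("Alu", "non_Alu_repeat", "non_repeat")),
    genic = stats::setNames(frac_tab(out$genic_class,
                                     c("exonic", "UTR", "intronic", "intergenic")),
                            c("exonic", "UTR", "intronic", "intergenic")),
    type_by_region = if (nrow(out)) {
      prop.table(table(out$region_class, out$edit_type), margin = 1)
    } else NULL,
    recurrence = rec$distribution
  )
  list(sites = out, attrition = attrition, breakdowns = breakdowns,
       recurrence = rec)
}
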