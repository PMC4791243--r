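# planting of RNA-editing fixtures, fusion caller tables and DE tables on top
# of a reference bundle; all pure functions of (bundle, seed, parameters)

edit_alt_for <- function(ref, type) {
  switch(type,
    ADAR = c(A = "G", T = "C")[ref],
    APOBEC = c(C = "T", G = "A")[ref],
    other = {
      cand <- setdiff(c("A", "C", "G", "T"), ref)
      cand <- cand[!paste0(ref, ">", cand) %in% c("A>G", "T>C", "C>T", "G>A")]
      sample(cand, 1L)
    }
  )
}

ref_ok_for <- function(ref, type) {
  switch(type, ADAR = ref %in% c("A", "T"), APOBEC = ref %in% c("C", "G"), TRUE)
}

#' Plant RNA-editing candidates, per-stage artifacts and their pileups
#'
#' Generates RNA variant candidates with planted truth: true editing sites in
#' Alu regions (default 50, of which 75\% are ADAR-type changes) and in clean
#' non-Alu positions (default 10), plus exactly one artifact per removal stage
#' of the detection cascade — a known SNP, a read-start mispriming artifact
#' (supported only by the first six read bases), a low-support site, a
#' simple-repeat site, a splice-adjacent site, a homopolymer site, a site in
#' the duplicated (multi-mapping) segment, a normal-editome site, and a site
#' co-located with a matched exome DNA variant. Each artifact is constructed
#' to fail exactly its intended stage; candidate positions are re-drawn
#' deterministically until they collide with no other category. A few true
#' sites are shared by two samples to give a non-trivial recurrence profile.
#'
#' @param bundle a \code{truth_bundle}, ideally after
#'   [plant_cohort_variants()] (the cohort's exome calls then serve as the
#'   matched WES sets).
#' @param seed integer seed.
#' @param n_alu,n_non_alu counts of true sites by region.
#' @param alu_adar_frac fraction of Alu-region changes that are ADAR-type
#'   (default 0.75); the remainder split between APOBEC and other types.
#' @param non_alu_adar_frac ADAR fraction among true non-Alu sites.
#' @param n_shared number of true sites planted in two samples.
#' @param thresholds a \code{gbm_thresholds} object.
#' @return the bundle with an \code{editing} element: \code{rna_variants},
#'   \code{support} (pileup), \code{db}, \code{normal_editome},
#'   \code{wes_by_sample}, \code{truth} (\code{sites} per carrier sample and
#'   \code{artifacts} with their expected stage).
#' @export
plant_editing_data <- function(bundle, seed = 1L, n_alu = 50L, n_non_alu = 10L,
                               alu_adar_frac = 0.75, non_alu_adar_frac = 0.6,
                               n_shared = 3L,
                               thresholds = default_thresholds()) {
  stopifnot(inherits(bundle, "truth_bundle"))
  set.seed(seed + 2L)
  genome <- bundle$genome
  repeats <- bundle$repeats
  models <- bundle$models
  junc <- splice_junctions(models)
  has_cohort <- !is.null(bundle$cohort)
  n_samples <- if (has_cohort) bundle$cohort$n_samples else 6L
  sample_ids <- if (has_cohort) bundle$cohort$sample_ids else paste0("S", 1:6)
  used <- if (has_cohort)
    paste(bundle$cohort$all$chrom, bundle$cohort$all$pos, sep = ":") else character(0)

  take <- function(chrom, pos) {
    used <<- c(used, paste(chrom, pos, sep = ":"))
  }
  is_used <- function(chrom, pos) paste(chrom, pos, sep = ":") %in% used

  cls <- S4Vectors::mcols(repeats)$class
  enum_positions <- function(iv) {
    data.frame(
      chrom = rep(as.character(GenomeInfoDb::seqnames(iv)), BiocGenerics::width(iv)),
      pos = unlist(mapply(seq.int, BiocGenerics::start(iv), BiocGenerics::end(iv),
                          SIMPLIFY = FALSE)),
      stringsAsFactors = FALSE
    )
  }
  alu_cand <- enum_positions(repeats[cls == "Alu"])
  alu_cand <- alu_cand[sample(nrow(alu_cand)), , drop = FALSE]
  alu_i <- 0L
  pick_alu <- function(type) {
    repeat {
      alu_i <<- alu_i + 1L
      if (alu_i > nrow(alu_cand)) stop("ran out of Alu positions")
      chrom <- alu_cand$chrom[alu_i]; pos <- alu_cand$pos[alu_i]
      if (is_used(chrom, pos)) next
      ref <- base_at(genome, chrom, pos)
      if (!ref_ok_for(ref, type)) next
      take(chrom, pos)
      return(list(chrom = chrom, pos = pos, ref = ref,
                  alt = edit_alt_for(ref, type)))
    }
  }
  far_from_junctions <- function(chrom, pos) {
    j <- junc$pos[junc$chrom == chrom]
    !length(j) || min(abs(pos - j)) > thresholds$splice_dist
  }
  clean_here <- function(chrom, pos) {
    is.na(repeat_class_at(repeats, chrom, pos)) &&
      far_from_junctions(chrom, pos) &&
      homopolymer_run_length(genome, chrom, pos) < thresholds$homopolymer_min &&
      multimap_occurrences(genome, chrom, pos, thresholds$multimap_flank) <= 1L
  }
  pick_clean <- function(type) {
    repeat {
      chrom <- sample(names(bundle$chrom_sizes), 1L,
                      prob = as.numeric(bundle$chrom_sizes))
      pos <- sample(1000L:(bundle$chrom_sizes[[chrom]] - 1000L), 1L)
      if (is_used(chrom, pos)) next
      ref <- base_at(genome, chrom, pos)
      if (!ref_ok_for(ref, type)) next
      if (!clean_here(chrom, pos)) next
      take(chrom, pos)
      return(list(chrom = chrom, pos = pos, ref = ref,
                  alt = edit_alt_for(ref, type)))
    }
  }

  # --- true sites ------------------------------------------------------------
  n_alu_adar <- round(n_alu * alu_adar_frac)
  n_alu_rest <- n_alu - n_alu_adar
  alu_types <- c(rep("ADAR", n_alu_adar),
                 rep(c("APOBEC", "other"), length.out = n_alu_rest))
  non_types <- c(rep("ADAR", round(n_non_alu * non_alu_adar_frac)),
                 rep("APOBEC", n_non_alu - round(n_non_alu * non_alu_adar_frac)))
  true_sites <- rbind(
    do.call(rbind, lapply(alu_types, function(tp) {
      s <- pick_alu(tp)
      data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                 type = tp, category = "true_alu", stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(non_types, function(tp) {
      s <- pick_clean(tp)
      data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                 type = tp, category = "true_non_alu", stringsAsFactors = FALSE)
    }))
  )
  carrier <- lapply(seq_len(nrow(true_sites)), function(i) {
    first <- ((i - 1L) %% n_samples) + 1L
    if (i <= n_shared) c(first, (first %% n_samples) + 1L) else first
  })

  # --- artifacts, one per stage ----------------------------------------------
  art <- list()
  art$polymorphism <- pick_alu("ADAR")
  art$read_trim <- pick_clean("ADAR")
  art$support <- pick_clean("ADAR")
  simple_cand <- enum_positions(repeats[cls == "simple_repeat"])
  simple_cand <- simple_cand[sample(nrow(simple_cand)), , drop = FALSE]
  for (i in seq_len(nrow(simple_cand))) {
    chrom <- simple_cand$chrom[i]; pos <- simple_cand$pos[i]
    ref <- base_at(genome, chrom, pos)
    if (!is_used(chrom, pos) && ref_ok_for(ref, "ADAR")) {
      take(chrom, pos)
      art$simple_repeat <- list(chrom = chrom, pos = pos, ref = ref,
                                alt = edit_alt_for(ref, "ADAR"))
      break
    }
  }
  found <- FALSE
  for (ji in sample(nrow(junc))) {
    for (off in sample(c(-4:-1, 1:4))) {
      chrom <- junc$chrom[ji]; pos <- junc$pos[ji] + off
      ref <- base_at(genome, chrom, pos)
      if (!is_used(chrom, pos) && ref_ok_for(ref, "ADAR") &&
          is.na(repeat_class_at(repeats, chrom, pos)) &&
          homopolymer_run_length(genome, chrom, pos) < thresholds$homopolymer_min &&
          multimap_occurrences(genome, chrom, pos, thresholds$multimap_flank) <= 1L) {
        take(chrom, pos)
        art$splice <- list(chrom = chrom, pos = pos, ref = ref,
                           alt = edit_alt_for(ref, "ADAR"))
        found <- TRUE; break
      }
    }
    if (found) break
  }
  hp <- bundle$homopolymer
  hp_pos <- hp$start + (hp$end - hp$start) %/% 2L
  art$homopolymer <- list(chrom = hp$chrom, pos = hp_pos,
                          ref = base_at(genome, hp$chrom, hp_pos), alt = NA)
  art$homopolymer$alt <- edit_alt_for(art$homopolymer$ref, "ADAR")
  take(hp$chrom, hp_pos)
  dupr <- bundle$dup$src
  for (pos in sample(seq.int(dupr$start + 30L, dupr$end - 30L))) {
    ref <- base_at(genome, dupr$chrom, pos)
    if (!is_used(dupr$chrom, pos) &&
        homopolymer_run_length(genome, dupr$chrom, pos) < thresholds$homopolymer_min &&
        far_from_junctions(dupr$chrom, pos) &&
        is.na(repeat_class_at(repeats, dupr$chrom, pos))) {
      take(dupr$chrom, pos)
      alt <- if (ref %in% c("A", "T")) edit_alt_for(ref, "ADAR") else
        edit_alt_for(ref, "APOBEC")
      art$multimap <- list(chrom = dupr$chrom, pos = pos, ref = ref, alt = alt)
      break
    }
  }
  art$editome <- pick_alu("ADAR")
  art$wes <- pick_alu("ADAR")
  stopifnot(setequal(names(art), c("polymorphism", "read_trim", "support",
                                   "simple_repeat", "splice", "homopolymer",
                                   "multimap", "editome", "wes")))
  artifacts <- do.call(rbind, lapply(names(art), function(st) {
    a <- art[[st]]
    data.frame(chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
               stage = st, stringsAsFactors = FALSE)
  }))
  artifacts$sample_id <- sample_ids[rep_len(seq_len(n_samples), nrow(artifacts))]

  # --- candidate table and pileups -------------------------------------------
  truth_sites <- do.call(rbind, lapply(seq_len(nrow(true_sites)), function(i) {
    data.frame(sample_id = sample_ids[carrier[[i]]],
               true_sites[i, ], row.names = NULL, stringsAsFactors = FALSE)
  }))
  cand <- rbind(
    truth_sites[c("sample_id", "chrom", "pos", "ref", "alt")],
    artifacts[c("sample_id", "chrom", "pos", "ref", "alt")]
  )
  support_rows <- vector("list", nrow(cand))
  stage_of <- c(rep(NA_character_, nrow(truth_sites)), artifacts$stage)
  for (i in seq_len(nrow(cand))) {
    st <- stage_of[i]
    if (identical(st, "read_trim")) {
      alt_off <- c(2L, 3L, 4L, 5L); n_ref <- 20L
    } else if (identical(st, "support")) {
      alt_off <- sample(7:45, 2L); n_ref <- 20L
    } else {
      alt_off <- sample(7:45, 6L); n_ref <- 18L
    }
    support_rows[[i]] <- data.frame(
      sample_id = cand$sample_id[i], chrom = cand$chrom[i], pos = cand$pos[i],
      base = c(rep(cand$alt[i], length(alt_off)), rep(cand$ref[i], n_ref)),
      read_offset = c(alt_off, sample(7:45, n_ref, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  }
  support <- do.call(rbind, support_rows)

  rna_variants <- data.frame(
    sample_id = cand$sample_id, chrom = cand$chrom, pos = cand$pos,
    ref = cand$ref, alt = cand$alt, zygosity = "het",
    depth = 24L, alt_reads = 6L, base_qual = 35,
    esp6500 = NA_real_, kg1000 = NA_real_, dbsnp137 = NA, cosmic = NA,
    tcga_gbm = NA, stringsAsFactors = FALSE
  )
  rna_variants$kind <- variant_kind(rna_variants$ref, rna_variants$alt)

  # --- databases, editome, matched WES ---------------------------------------
  tabs <- if (has_cohort) bundle$cohort$db_tables else list(
    esp6500 = data.frame(chrom = character(), pos = integer(), ref = character(),
                         alt = character(), freq = numeric()),
    kg1000 = data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), freq = numeric()),
    cosmic = data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character()),
    tcga_gbm = data.frame(chrom = character(), pos = integer(), ref = character(),
                          alt = character()),
    dbsnp137 = data.frame(chrom = character(), pos = integer(), ref = character(),
                          alt = character())
  )
  a <- art$polymorphism
  tabs$dbsnp137 <- rbind(tabs$dbsnp137[c("chrom", "pos", "ref", "alt")],
                         data.frame(chrom = a$chrom, pos = a$pos, ref = a$ref,
                                    alt = a$alt, stringsAsFactors = FALSE))
  db <- do.call(annotation_db, tabs)

  e <- art$editome
  decoy <- do.call(rbind, lapply(1:5, function(k) {
    s <- pick_clean("ADAR")
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               stringsAsFactors = FALSE)
  }))
  normal_editome <- rbind(
    data.frame(chrom = e$chrom, pos = e$pos, ref = e$ref, alt = e$alt,
               stringsAsFactors = FALSE), decoy)

  # the co-located genomic variant behind the WES artifact is a real DNA call:
  # it goes into that sample's exome call set (and, with a cohort, into the
  # cohort tables and cascade truth — absent from every database, private to
  # one sample, so its cascade reason is passed_all)
  w <- art$wes
  ws <- artifacts$sample_id[artifacts$stage == "wes"]
  wes_extra <- data.frame(
    sample_id = ws, chrom = w$chrom, pos = w$pos, ref = w$ref, alt = w$alt,
    zygosity = "het", depth = 60L, alt_reads = 28L, base_qual = 33,
    esp6500 = 0, kg1000 = 0, dbsnp137 = FALSE, cosmic = FALSE,
    tcga_gbm = FALSE, stringsAsFactors = FALSE
  )
  wes_extra$kind <- variant_kind(wes_extra$ref, wes_extra$alt)
  if (has_cohort) {
    bundle$cohort$variants <- rbind(bundle$cohort$variants, wes_extra)
    bundle$cohort$all <- rbind(bundle$cohort$all, wes_extra)
    bundle$cohort$by_sample[[ws]] <-
      rbind(bundle$cohort$by_sample[[ws]], wes_extra)
    bundle$cohort$truth$snv <- rbind(
      bundle$cohort$truth$snv,
      data.frame(chrom = w$chrom, pos = w$pos, ref = w$ref, alt = w$alt,
                 reason = "passed_all", zygosity = "het",
                 is_transition = edit_type(w$ref, w$alt) == "ADAR",
                 n_carriers = 1L, stringsAsFactors = FALSE))
  }
  wes_by_sample <- stats::setNames(lapply(sample_ids, function(s) {
    if (has_cohort) return(bundle$cohort$by_sample[[s]])
    base <- variant_calls(character(), character(), integer(), character(),
                          character(), character())
    if (identical(s, ws)) base <- rbind(base[names(wes_extra)], wes_extra)
    base
  }), sample_ids)

  bundle$editing <- list(
    rna_variants = rna_variants, support = support, db = db, db_tables = tabs,
    normal_editome = normal_editome, wes_by_sample = wes_by_sample,
    n_samples = n_samples, sample_ids = sample_ids,
    truth = list(sites = truth_sites, artifacts = artifacts)
  )
  bundle
}

# coding bases in the first k transcription-order exons of tx (plain
# arithmetic, kept local to the generator)
gen_cds_in_first_exons <- function(tx, k) {
  n <- nrow(tx$exons)
  t_idx <- if (tx$strand == "-") n:1 else 1:n
  sum(vapply(t_idx[seq_len(k)], function(gi) {
    max(0L, min(tx$exons$end[gi], tx$cds_end) -
          max(tx$exons$start[gi], tx$cds_start) + 1L)
  }, integer(1)))
}

tx_exon_tx_end <- function(tx, k) {
  n <- nrow(tx$exons)
  if (tx$strand == "+") tx$exons$end[k] else tx$exons$start[n + 1L - k]
}
tx_exon_tx_start <- function(tx, k) {
  n <- nrow(tx$exons)
  if (tx$strand == "+") tx$exons$start[k] else tx$exons$end[n + 1L - k]
}

#' Plant three fusion-caller tables with a known consensus
#'
#' Builds call tables for the three supported callers with a configurable
#' all-tool intersection (default 5 gene pairs, of which 2 assemble in frame —
#' one shaped like the worked example: exons 1-3 of the 20-exon gene joined to
#' exons 2-5 of the 5-exon gene, reported with 19 junction-spanning reads by
#' the most stringent caller), a few pairs shared by exactly two tools, and
#' per-tool filler calls on synthetic gene symbols (defaults give 389 calls in
#' total). One shared pair carries a deliberately discordant breakpoint in one
#' tool to exercise majority reconciliation.
#'
#' @param bundle a \code{truth_bundle}.
#' @param seed integer seed.
#' @param n_per_tool named counts of calls per tool.
#' @param n_shared_two pairs present in exactly two tools.
#' @return the bundle with a \code{fusions} element: \code{calls_by_tool} and
#'   \code{truth} (consensus pairs with breakpoints and in-frame flags).
#' @export
plant_fusions <- function(bundle, seed = 1L,
                          n_per_tool = c(prada = 39L, fusionmap = 200L,
                                         tophat_fusion = 150L),
                          n_shared_two = 3L) {
  stopifnot(inherits(bundle, "truth_bundle"))
  set.seed(seed + 3L)
  m <- bundle$models
  by_gene <- stats::setNames(m, vapply(m, `[[`, character(1), "gene"))
  spec <- list(
    list(g5 = "FUSA", e5 = 3L, g3 = "FUSB", e3 = 2L, shift5 = 0L),
    list(g5 = "GFD", e5 = 2L, g3 = "GFE", e3 = 2L, shift5 = 0L),
    list(g5 = "GFF", e5 = 2L, g3 = "GFE", e3 = 2L, shift5 = 0L),
    list(g5 = "GFC", e5 = 1L, g3 = "GFD", e3 = 2L, shift5 = -1L),
    list(g5 = "EGFR", e5 = 2L, g3 = "TP53", e3 = 2L, shift5 = 0L)
  )
  truth <- do.call(rbind, lapply(spec, function(s) {
    tx5 <- by_gene[[s$g5]]; tx3 <- by_gene[[s$g3]]
    bp5 <- tx_exon_tx_end(tx5, s$e5) + (if (tx5$strand == "+") s$shift5 else -s$shift5)
    bp3 <- tx_exon_tx_start(tx3, s$e3)
    cds5 <- gen_cds_in_first_exons(tx5, s$e5) + s$shift5
    entry3 <- gen_cds_in_first_exons(tx3, s$e3 - 1L) %% 3L
    data.frame(gene5 = s$g5, gene3 = s$g3, chrom5 = tx5$chrom, pos5 = bp5,
               chrom3 = tx3$chrom, pos3 = bp3,
               in_frame = (cds5 %% 3L) == entry3, stringsAsFactors = FALSE)
  }))

  tools <- names(n_per_tool)
  shared_two <- data.frame(
    gene5 = paste0("SHA", seq_len(n_shared_two)),
    gene3 = paste0("SHB", seq_len(n_shared_two)), stringsAsFactors = FALSE
  )
  calls_by_tool <- stats::setNames(lapply(tools, function(tool) {
    rows <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      jr <- if (tool == "prada" && truth$gene5[i] == "FUSA") 19L else
        sample(5:30, 1L)
      pos5 <- truth$pos5[i] +
        (if (tool == "tophat_fusion" && truth$gene5[i] == "GFD") 1L else 0L)
      data.frame(tool = tool, gene5 = truth$gene5[i], gene3 = truth$gene3[i],
                 chrom5 = truth$chrom5[i], pos5 = pos5,
                 chrom3 = truth$chrom3[i], pos3 = truth$pos3[i],
                 junction_reads = jr, stringsAsFactors = FALSE)
    }))
    if (tool != "prada") {
      rows <- rbind(rows, data.frame(
        tool = tool, gene5 = shared_two$gene5, gene3 = shared_two$gene3,
        chrom5 = "chr1", pos5 = sample(1e5, n_shared_two),
        chrom3 = "chr2", pos3 = sample(1e5, n_shared_two),
        junction_reads = sample(2:20, n_shared_two, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    n_fill <- n_per_tool[[tool]] - nrow(rows)
    if (n_fill < 0L) stop("intersection larger than tool call list: ", tool)
    if (n_fill > 0L) {
      rows <- rbind(rows, data.frame(
        tool = tool,
        gene5 = sprintf("%s5X%03d", toupper(substr(tool, 1, 2)), seq_len(n_fill)),
        gene3 = sprintf("%s3X%03d", toupper(substr(tool, 1, 2)), seq_len(n_fill)),
        chrom5 = sample(names(bundle$chrom_sizes), n_fill, replace = TRUE),
        pos5 = sample(2e5, n_fill),
        chrom3 = sample(names(bundle$chrom_sizes), n_fill, replace = TRUE),
        pos3 = sample(2e5, n_fill),
        junction_reads = sample(1:50, n_fill, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    rows$low_support <- rows$junction_reads == 0L
    rows
  }), tools)

  bundle$fusions <- list(calls_by_tool = calls_by_tool, truth = truth)
  bundle
}

#' Plant a pair of differential-expression tables with known concordance
#'
#' Builds an RNA-seq style DE table (log2 fold change + adjusted p) and a
#' comparison-array style table (log2 fold change + p), sharing a set of
#' significant genes with an exact planted direction-concordance fraction.
#' Defaults mirror the study scale: 3,428 significant genes in the first
#' table, 2,214 of them significant in the second, 1,621 with the same
#' direction (fraction ~0.732).
#'
#' @param seed integer seed.
#' @param n_a_sig significant genes in table A.
#' @param n_common of those, genes also significant in table B.
#' @param n_concordant of the common genes, how many agree in direction.
#' @param n_a_null non-significant padding genes in table A.
#' @param n_b_only genes significant only in table B.
#' @return list with \code{de_a}, \code{de_b} and \code{truth}.
#' @export
plant_de_tables <- function(seed = 1L, n_a_sig = 3428L, n_common = 2214L,
                            n_concordant = 1621L, n_a_null = 500L,
                            n_b_only = 300L) {
  stopifnot(n_common <= n_a_sig, n_concordant <= n_common)
  set.seed(seed + 4L)
  n_genes <- n_a_sig + n_a_null + n_b_only
  genes <- sprintf("G%05d", seq_len(n_genes))
  sig_a <- genes[seq_len(n_a_sig)]
  common <- sample(sig_a, n_common)
  sign_a <- stats::setNames(sample(c(-1, 1), n_a_sig, replace = TRUE), sig_a)
  de_a <- data.frame(
    gene = c(sig_a, genes[n_a_sig + seq_len(n_a_null)]),
    log2fc = c(sign_a * stats::runif(n_a_sig, 1, 5),
               stats::runif(n_a_null, -0.5, 0.5)),
    padj = c(stats::runif(n_a_sig, 0, 0.01), stats::runif(n_a_null, 0.3, 1)),
    stringsAsFactors = FALSE
  )
  conc <- common[seq_len(n_concordant)]
  disc <- setdiff(common, conc)
  b_only <- genes[n_a_sig + n_a_null + seq_len(n_b_only)]
  de_b <- data.frame(
    gene = c(conc, disc, b_only),
    log2fc = c(sign_a[conc] * stats::runif(n_concordant, 0.5, 4),
               -sign_a[disc] * stats::runif(length(disc), 0.5, 4),
               stats::runif(n_b_only, -3, 3)),
    pvalue = stats::runif(n_concordant + length(disc) + n_b_only, 0, 0.04),
    stringsAsFactors = FALSE
  )
  list(de_a = de_a, de_b = de_b,
       truth = list(n_common = n_common, n_concordant = n_concordant,
                    fraction = n_concordant / n_common))
}

#' Write a fully planted bundle to disk in the external formats
#'
#' Serializes every fixture the pipeline consumes: genome FASTA, gene-model
#' GTF, repeat and target BEDs, per-sample DNA and RNA VCFs, the annotation
#' site tables and normal editome as TSV, the pileup TSV, the three fusion
#' caller tables in their dialects, a thresholds YAML and a machine-readable
#' \code{truth.json}.
#'
#' @param bundle a \code{truth_bundle} after the plant_* steps.
#' @param dir output directory (created if needed).
#' @param thresholds a \code{gbm_thresholds} object to serialize.
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir, thresholds = default_thresholds()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(bundle$genome, p("genome.fa"))
  write_gene_models(bundle$models, p("models.gtf"))
  write_repeat_track(bundle$repeats, p("repeats.bed"))
  tdf <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(bundle$targets)),
                    start = BiocGenerics::start(bundle$targets) - 1L,
                    end = BiocGenerics::end(bundle$targets))
  write.table(tdf, p("targets.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth <- list(seed = bundle$seed)
  if (!is.null(bundle$cohort)) {
    for (s in bundle$cohort$sample_ids) {
      write_vcf(bundle$cohort$by_sample[[s]], p(paste0("dna_", s, ".vcf")))
    }
    for (src in names(bundle$cohort$db_tables)) {
      write_site_table(bundle$cohort$db_tables[[src]], p(paste0(src, ".tsv")))
    }
    truth$cohort <- bundle$cohort$truth
    truth$samples <- bundle$cohort$sample_ids
  }
  if (!is.null(bundle$editing)) {
    ed <- bundle$editing
    for (s in ed$sample_ids) {
      rv <- ed$rna_variants[ed$rna_variants$sample_id == s, , drop = FALSE]
      write_vcf(rv, p(paste0("rna_", s, ".vcf")))
    }
    write_support_table(ed$support, p("pileup.tsv"))
    write_site_table(ed$normal_editome, p("normal_editome.tsv"))
    # editing-stage dbSNP includes the planted RNA SNP artifact
    write_site_table(ed$db_tables$dbsnp137, p("dbsnp137.tsv"))
    truth$editing <- ed$truth
  }
  if (!is.null(bundle$de)) {
    write.table(bundle$de$de_a, p("de_a.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bundle$de$de_b, p("de_b.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth$de <- bundle$de$truth
  }
  if (!is.null(bundle$fusions)) {
    for (tool in names(bundle$fusions$calls_by_tool)) {
      write_fusion_calls(bundle$fusions$calls_by_tool[[tool]],
                         p(paste0("fusions_", tool, ".tsv")), tool)
    }
    truth$fusions <- bundle$fusions$truth
  }
  write_thresholds(thresholds, p("thresholds.yaml"))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
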