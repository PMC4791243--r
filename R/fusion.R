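#' Multi-caller fusion consensus
#'
#' Intersects fusion calls across callers keyed on the ordered gene pair
#' (gene5, gene3) — symbols, not coordinates, because the callers report
#' breakpoints in different conventions. For each all-tool pair the breakpoint
#' tuple is reconciled by majority across tools; ties fall back to the PRADA
#' coordinates when PRADA called the pair, else to the first tool supplied.
#'
#' @param calls_by_tool named list of normalized fusion-call data.frames (from
#'   [read_fusion_calls()]), one per tool; at least two tools.
#' @return list with \code{consensus} (pairs in all tools, reconciled
#'   breakpoints, \code{junction_reads} = maximum across tools, \code{n_tools})
#'   and \code{pairwise} (pairs in at least two tools with their tool count).
#' @export
consensus_fusions <- function(calls_by_tool) {
  if (length(calls_by_tool) < 2L)
    stop("consensus requires calls from at least two tools")
  pair_key <- function(df) paste(df$gene5, df$gene3, sep = "~")
  keys <- lapply(calls_by_tool, pair_key)
  all_keys <- unique(unlist(keys))
  n_tools_per <- vapply(all_keys, function(k)
    sum(vapply(keys, function(kk) k %in% kk, logical(1))), integer(1))
  shared <- all_keys[n_tools_per >= 2L]
  full <- all_keys[n_tools_per == length(calls_by_tool)]

  pairwise <- data.frame(
    gene5 = sub("~.*", "", shared), gene3 = sub(".*~", "", shared),
    n_tools = n_tools_per[match(shared, all_keys)],
    row.names = NULL, stringsAsFactors = FALSE
  )

  rows <- lapply(full, function(k) {
    per_tool <- lapply(names(calls_by_tool), function(tool) {
      df <- calls_by_tool[[tool]]
      hit <- df[pair_key(df) == k, , drop = FALSE][1L, , drop = FALSE]
      hit$tool <- tool
      hit
    })
    bp <- do.call(rbind, per_tool)
    tup <- paste(bp$chrom5, bp$pos5, bp$chrom3, bp$pos3, sep = "|")
    tab <- sort(table(tup), decreasing = TRUE)
    winners <- names(tab)[tab == max(tab)]
    pick <- if (length(winners) == 1L) winners[1L] else {
      prada_tup <- tup[bp$tool == "prada"]
      if (length(prada_tup) && prada_tup[1L] %in% winners) prada_tup[1L] else winners[1L]
    }
    win <- bp[match(pick, tup), , drop = FALSE]
    data.frame(gene5 = win$gene5, gene3 = win$gene3,
               chrom5 = win$chrom5, pos5 = win$pos5,
               chrom3 = win$chrom3, pos3 = win$pos3,
               junction_reads = max(bp$junction_reads),
               n_tools = length(calls_by_tool),
               stringsAsFactors = FALSE)
  })
  consensus <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene5 = character(), gene3 = character(), chrom5 = character(),
               pos5 = integer(), chrom3 = character(), pos3 = integer(),
               junction_reads = integer(), n_tools = integer(),
               stringsAsFactors = FALSE)
  list(consensus = consensus, pairwise = pairwise)
}

#' Map a genomic breakpoint onto a transcript
#'
#' @param tx a \code{gene_model}.
#' @param genomic_pos 1-based genomic position within the transcript span.
#' @return list with \code{exon} (1-based exon index in transcription order;
#'   for an intronic breakpoint, the nearest upstream exon), \code{cds_offset}
#'   (cumulative coding nucleotides at or 5' of the breakpoint in
#'   transcription order; 0 before the CDS start), \code{boundary} (is the
#'   position an exon edge) and \code{intronic} (flag).
#' @export
map_breakpoint <- function(tx, genomic_pos) {
  span <- c(min(tx$exons$start), max(tx$exons$end))
  if (genomic_pos < span[1] || genomic_pos > span[2])
    stop("breakpoint ", genomic_pos, " outside span of ", tx$transcript_id)
  n <- nrow(tx$exons)
  g_idx <- which(genomic_pos >= tx$exons$start & genomic_pos <= tx$exons$end)
  intronic <- length(g_idx) == 0L
  if (intronic) {
    # nearest exon on the 5' (transcription) side of the intron
    g_idx <- if (tx$strand == "+") max(which(tx$exons$end < genomic_pos))
             else min(which(tx$exons$start > genomic_pos))
  }
  exon_t <- if (tx$strand == "+") g_idx else n + 1L - g_idx
  cds_off <- 0L
  if (!is.na(tx$cds_start)) {
    cpos <- cds_positions(tx)
    cds_off <- if (tx$strand == "+") sum(cpos <= genomic_pos)
               else sum(cpos >= genomic_pos)
  }
  boundary <- genomic_pos %in% tx$exons$start || genomic_pos %in% tx$exons$end
  list(exon = as.integer(exon_t), cds_offset = as.integer(cds_off),
       boundary = boundary, intronic = intronic)
}

#' Assemble and translate a fusion open reading frame
#'
#' Concatenates the 5' partner's coding sequence retained up to (and
#' including) its breakpoint with the 3' partner's coding sequence from its
#' breakpoint onward, computes the entry phase of the 3' segment, and
#' translates the chimera from the 5' partner's start codon until the first
#' stop. The product is in frame exactly when the retained 5' CDS length
#' modulo 3 equals the 3' entry phase (coding nucleotides upstream of the 3'
#' breakpoint modulo 3), so the 3' partner is read in its native frame.
#'
#' @param tx5,tx3 coding \code{gene_model}s of the 5' and 3' partners.
#' @param bp5 last retained genomic base of the 5' partner (1-based).
#' @param bp3 first retained genomic base of the 3' partner (1-based).
#' @param genome named \code{DNAStringSet}.
#' @param junction_flank residues reported on each side of the junction
#'   peptide (default 10).
#' @return a \code{fusion_product} list: gene5/gene3, retained exon indices,
#'   \code{cds_len5}, \code{entry_phase3}, \code{in_frame},
#'   \code{protein_length} (residues before the first stop), \code{protein},
#'   \code{junction_peptide}, \code{truncated} (stop before the junction),
#'   \code{no_stop}, and the breakpoints.
#' @export
assemble_fusion_orf <- function(tx5, bp5, tx3, bp3, genome, junction_flank = 10L) {
  for (tx in list(tx5, tx3)) {
    if (tx$biotype != "protein_coding" || is.na(tx$cds_start))
      stop("fusion partner ", tx$transcript_id, " is not protein coding")
  }
  m5 <- map_breakpoint(tx5, bp5)
  m3 <- map_breakpoint(tx3, bp3)
  cpos5 <- cds_positions(tx5)
  cpos3 <- cds_positions(tx3)
  keep5 <- if (tx5$strand == "+") cpos5[cpos5 <= bp5] else cpos5[cpos5 >= bp5]
  keep3 <- if (tx3$strand == "+") cpos3[cpos3 >= bp3] else cpos3[cpos3 <= bp3]
  seq5 <- segment_sequence(genome, tx5, keep5)
  seq3 <- segment_sequence(genome, tx3, keep3)
  cds_len5 <- length(keep5)
  entry_phase3 <- (length(cpos3) - length(keep3)) %% 3L
  in_frame <- (cds_len5 %% 3L) == entry_phase3

  chimera <- Biostrings::xscat(seq5, seq3)
  n_cod <- length(chimera) %/% 3L
  protein_length <- 0L
  aa <- ""
  no_stop <- TRUE
  if (n_cod > 0L) {
    aa <- as.character(Biostrings::translate(
      Biostrings::subseq(chimera, 1L, 3L * n_cod), no.init.codon = TRUE))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0L) {
      protein_length <- as.integer(stop_at) - 1L
      aa <- substr(aa, 1L, protein_length)
      no_stop <- FALSE
    } else {
      protein_length <- nchar(aa)
    }
  }
  truncated <- !no_stop && (protein_length * 3L) < cds_len5
  j_aa <- cds_len5 %/% 3L  # last full 5'-partner codon
  jp_from <- max(1L, j_aa - junction_flank + 1L)
  jp_to <- min(nchar(aa), j_aa + junction_flank)
  structure(list(
    gene5 = tx5$gene, gene3 = tx3$gene,
    retained_exons5 = seq_len(m5$exon), retained_exons3 = m3$exon:nrow(tx3$exons),
    bp5 = bp5, bp3 = bp3,
    cds_len5 = cds_len5, cds_len3 = length(keep3),
    entry_phase3 = entry_phase3, in_frame = in_frame,
    protein_length = protein_length, protein = aa,
    junction_peptide = if (jp_to >= jp_from) substr(aa, jp_from, jp_to) else "",
    truncated = truncated, no_stop = no_stop
  ), class = "fusion_product")
}

# sequence of a set of genomic positions, in transcription order
segment_sequence <- function(genome, tx, gpos) {
  if (length(gpos) == 0L) return(Biostrings::DNAString(""))
  chr_seq <- genome[[tx$chrom]]
  if (tx$strand == "-") {
    Biostrings::reverseComplement(chr_seq[sort(gpos)])
  } else {
    chr_seq[sort(gpos)]
  }
}

#' @export
print.fusion_product <- function(x, ...) {
  cat(sprintf("<fusion_product> %s-%s: %s, %d aa (5' CDS %d nt, entry phase %d)\n",
              x$gene5, x$gene3, if (x$in_frame) "in-frame" else "out-of-frame",
              x$protein_length, x$cds_len5, x$entry_phase3))
  if (nzchar(x$junction_peptide)) cat("  junction peptide: ", x$junction_peptide, "\n")
  invisible(x)
}

#' Fusion-validation primer scheme
#'
#' Designs the three-amplicon scheme used to confirm a fusion by PCR: a
#' forward primer on the 5' partner upstream of the junction, a reverse
#' primer on the 3' partner downstream of it, plus wild-type companion
#' primers, so that (i) fwd5 x rev5 amplifies the wild-type 5' transcript,
#' (ii) fwd3 x rev3 amplifies the wild-type 3' transcript, and (iii) fwd5 x
#' rev3 amplifies only the fused transcript. The three predicted amplicon
#' lengths must be pairwise distinct, so a gel separates all products.
#'
#' @param product a \code{fusion_product} from [assemble_fusion_orf()].
#' @param tx5,tx3 the partner \code{gene_model}s.
#' @param genome named \code{DNAStringSet}.
#' @param primer_len primer length in bases (default 20).
#' @param gap distance between each junction-side primer and the junction
#'   (default 30); primer windows overlapping the junction are an error.
#' @return list with \code{primers} (named character vector), \code{amplicons}
#'   (data.frame: name, template, length) where the fusion pair yields no
#'   product on either wild-type template.
#' @export
junction_primers <- function(product, tx5, tx3, genome, primer_len = 20L, gap = 30L) {
  if (gap < 0L) stop("primer window overlaps the junction (gap < 0)")
  cdna5 <- spliced_sequence(tx5, genome)
  cdna3 <- spliced_sequence(tx3, genome)
  tpos5 <- exon_positions(tx5)
  if (tx5$strand == "-") tpos5 <- rev(tpos5)
  tpos3 <- exon_positions(tx3)
  if (tx3$strand == "-") tpos3 <- rev(tpos3)
  j5 <- match(product$bp5, tpos5)
  k3 <- match(product$bp3, tpos3)
  if (is.na(j5) || is.na(k3)) stop("breakpoints must fall in exons to design primers")
  f_from <- j5 - gap - primer_len + 1L
  if (f_from < 1L || j5 - gap > length(cdna5))
    stop("no room for the forward primer upstream of the junction")
  fwd5 <- as.character(cdna5[f_from:(j5 - gap)])
  r_to <- k3 + gap + primer_len - 1L
  if (r_to > length(cdna3)) stop("no room for the reverse primer downstream of the junction")
  rev3 <- as.character(Biostrings::reverseComplement(cdna3[(k3 + gap):r_to]))
  rev5 <- as.character(Biostrings::reverseComplement(
    cdna5[(length(cdna5) - primer_len + 1L):length(cdna5)]))
  fwd3 <- as.character(cdna3[1:primer_len])
  primers <- c(fwd5 = fwd5, rev5 = rev5, fwd3 = fwd3, rev3 = rev3)
  if (anyDuplicated(primers)) stop("identical primer windows; redesign with other offsets")

  fused <- Biostrings::xscat(cdna5[1:j5], cdna3[k3:length(cdna3)])
  amp <- function(template, fwd, rev) {
    f <- Biostrings::matchPattern(Biostrings::DNAString(fwd), template)
    r <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(rev)), template)
    if (length(f) == 0L || length(r) == 0L) return(NA_integer_)
    len <- max(BiocGenerics::end(r)) - min(BiocGenerics::start(f)) + 1L
    if (len < primer_len) NA_integer_ else as.integer(len)
  }
  amplicons <- data.frame(
    name = c("wildtype_5prime", "wildtype_3prime", "fusion",
             "fusion_pair_on_wt5", "fusion_pair_on_wt3"),
    template = c("wt5", "wt3", "fused", "wt5", "wt3"),
    length = c(amp(cdna5, fwd5, rev5), amp(cdna3, fwd3, rev3),
               amp(fused, fwd5, rev3), amp(cdna5, fwd5, rev3),
               amp(cdna3, fwd5, rev3)),
    stringsAsFactors = FALSE
  )
  three <- amplicons$length[1:3]
  if (anyNA(three)) stop("a designed primer pair yields no product on its template")
  if (anyDuplicated(three))
    stop("amplicon lengths are not pairwise distinct; adjust primer offsets")
  list(primers = primers, amplicons = amplicons)
}
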