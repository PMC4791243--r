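#' Transcript gene models
#'
#' A gene model is a transcript: ordered exons, optional CDS bounds, strand and
#' biotype. Internally all coordinates are 1-based inclusive genomic positions;
#' exons are stored sorted in ascending genomic order regardless of strand, and
#' transcription (5' to 3') order is derived from the strand where needed.
#'
#' @param gene gene symbol.
#' @param transcript_id transcript identifier (unique within a set).
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons two-column matrix or data.frame of exon \code{start}, \code{end}
#'   (1-based inclusive), non-overlapping.
#' @param cds_start,cds_end genomic CDS bounds (inclusive, stop codon included);
#'   NA for non-coding transcripts.
#' @param biotype one of \code{protein_coding}, \code{lncRNA}, \code{miRNA},
#'   \code{other}.
#' @return an object of class \code{gene_model}.
#' @export
gene_model <- function(gene, transcript_id, chrom, strand, exons,
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       biotype = "protein_coding") {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (!strand %in% c("+", "-")) stop("unknown strand '", strand, "' for ", transcript_id)
  if (any(exons$end < exons$start)) stop("exon end < start in ", transcript_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in ", transcript_id)
  if (!biotype %in% c("protein_coding", "lncRNA", "miRNA", "other"))
    stop("unknown biotype '", biotype, "'")
  tx <- structure(list(
    gene = gene, transcript_id = transcript_id, chrom = chrom, strand = strand,
    exons = exons, cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    biotype = biotype
  ), class = "gene_model")
  if (!is.na(tx$cds_start)) {
    if (tx$cds_end < tx$cds_start) stop("cds_end < cds_start in ", transcript_id)
    cov <- exon_positions(tx)
    cds <- tx$cds_start:tx$cds_end
    inside <- cds %in% cov
    if (!inside[1L] || !inside[length(inside)])
      stop("CDS bounds outside exons in ", transcript_id)
  }
  tx
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d [%s] %d exon(s), %s\n",
              x$transcript_id, x$gene, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), x$biotype))
  invisible(x)
}

# genomic positions covered by exons, ascending
exon_positions <- function(tx) {
  unlist(mapply(seq.int, tx$exons$start, tx$exons$end, SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Genomic positions of the CDS in transcription (5' to 3') order
#' @param tx a \code{gene_model}; must be coding.
#' @return integer vector of genomic coordinates, first element is the first
#'   base of the start codon.
#' @export
cds_positions <- function(tx) {
  if (is.na(tx$cds_start)) stop("transcript ", tx$transcript_id, " has no CDS")
  pos <- exon_positions(tx)
  pos <- pos[pos >= tx$cds_start & pos <= tx$cds_end]
  if (tx$strand == "-") rev(pos) else pos
}

#' Total CDS length in nucleotides (stop codon included)
#' @param tx a coding \code{gene_model}.
#' @return integer.
#' @export
cds_length <- function(tx) length(cds_positions(tx))

#' Extract a transcript's CDS sequence from a genome
#' @param tx a coding \code{gene_model}.
#' @param genome a named \code{DNAStringSet}.
#' @return a \code{DNAString}, 5' to 3' (reverse-complemented for minus-strand
#'   transcripts).
#' @export
cds_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome)) stop("genome lacks chromosome ", tx$chrom)
  chr_seq <- genome[[tx$chrom]]
  pos <- cds_positions(tx)
  if (tx$strand == "-") {
    Biostrings::reverseComplement(chr_seq[rev(pos)])
  } else {
    chr_seq[pos]
  }
}

#' Spliced transcript (cDNA) sequence
#' @inheritParams cds_sequence
#' @return a \code{DNAString} in transcription order.
#' @export
spliced_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome)) stop("genome lacks chromosome ", tx$chrom)
  chr_seq <- genome[[tx$chrom]]
  pos <- exon_positions(tx)
  if (tx$strand == "-") {
    Biostrings::reverseComplement(chr_seq[rev(pos)])
  } else {
    chr_seq[pos]
  }
}

#' Splice-junction positions of a gene-model set
#'
#' Junctions are the exon edges that abut an intron: the end of every exon but
#' the last and the start of every exon but the first (in genomic order), over
#' all multi-exon transcripts.
#'
#' @param models a list of \code{gene_model}s.
#' @return data.frame with columns \code{chrom}, \code{pos}.
#' @export
splice_junctions <- function(models) {
  out <- lapply(models, function(tx) {
    n <- nrow(tx$exons)
    if (n < 2L) return(NULL)
    data.frame(chrom = tx$chrom,
               pos = c(tx$exons$end[-n], tx$exons$start[-1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(), pos = integer()) else
    unique(out)
}

#' Read gene models from a GTF file
#'
#' Transcripts are assembled from \code{exon} and \code{CDS} feature rows (via
#' \pkg{rtracklayer}); CDS bounds are the min/max of the CDS rows and must fall
#' inside the exon union. Biotype is taken from the \code{gene_biotype}
#' attribute when present, else inferred (\code{protein_coding} if CDS rows
#' exist, \code{other} otherwise).
#'
#' @param path GTF file.
#' @return named list of \code{gene_model} objects (names = transcript ids).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands == "*")) stop("unknown strand '*' in ", path)
  tx_ids <- unique(md$transcript_id[md$type %in% c("exon", "CDS")])
  tx_ids <- tx_ids[!is.na(tx_ids)]
  models <- lapply(tx_ids, function(tid) {
    sel <- !is.na(md$transcript_id) & md$transcript_id == tid
    sub <- gr[sel]
    smd <- S4Vectors::mcols(sub)
    ex <- sub[smd$type == "exon"]
    cds <- sub[smd$type == "CDS"]
    if (length(ex) == 0L) stop("transcript ", tid, " has no exon rows in ", path)
    gene <- smd$gene_name[1L]
    if (is.null(gene) || is.na(gene)) gene <- smd$gene_id[1L]
    bt <- if (!is.null(smd$gene_biotype)) smd$gene_biotype[1L] else NA_character_
    if (is.na(bt)) bt <- if (length(cds)) "protein_coding" else "other"
    cs <- if (length(cds)) min(BiocGenerics::start(cds)) else NA_integer_
    ce <- if (length(cds)) max(BiocGenerics::end(cds)) else NA_integer_
    gene_model(
      gene = gene, transcript_id = tid,
      chrom = as.character(GenomeInfoDb::seqnames(sub))[1L],
      strand = as.character(BiocGenerics::strand(ex))[1L],
      exons = data.frame(start = BiocGenerics::start(ex), end = BiocGenerics::end(ex)),
      cds_start = cs, cds_end = ce, biotype = bt
    )
  })
  names(models) <- tx_ids
  models
}

#' Write gene models to a GTF file
#' @param models named list of \code{gene_model}s.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(tx) {
    ex <- data.frame(chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end,
                     strand = tx$strand, type = "exon", stringsAsFactors = FALSE)
    ex$phase <- NA_integer_
    if (!is.na(tx$cds_start)) {
      keep <- tx$exons$end >= tx$cds_start & tx$exons$start <= tx$cds_end
      ce <- tx$exons[keep, , drop = FALSE]
      cds <- data.frame(chrom = tx$chrom,
                        start = pmax(ce$start, tx$cds_start),
                        end = pmin(ce$end, tx$cds_end),
                        strand = tx$strand, type = "CDS", stringsAsFactors = FALSE)
      # GTF frame: bases to skip before the next codon start, in 5'->3' order
      lens <- cds$end - cds$start + 1L
      if (tx$strand == "-") lens <- rev(lens)
      before <- c(0L, cumsum(lens))[seq_along(lens)]
      phase <- (3L - before %% 3L) %% 3L
      cds$phase <- if (tx$strand == "-") rev(phase) else phase
      ex <- rbind(ex, cds)
    }
    ex$gene_id <- tx$gene
    ex$gene_name <- tx$gene
    ex$transcript_id <- tx$transcript_id
    ex$gene_biotype <- tx$biotype
    ex
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "gbmcharter", type = df$type, phase = df$phase,
    gene_id = df$gene_id, gene_name = df$gene_name,
    transcript_id = df$transcript_id, gene_biotype = df$gene_biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Map variants to overlapping genes
#' @param variants variant-call data.frame.
#' @param models named list of \code{gene_model}s.
#' @return character vector of comma-joined gene symbols whose transcript span
#'   overlaps each variant position (\code{NA} when none).
#' @export
genes_at <- function(variants, models) {
  if (nrow(variants) == 0L) return(character(0))
  spans <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      vapply(models, function(tx) min(tx$exons$start), integer(1)),
      vapply(models, function(tx) max(tx$exons$end), integer(1))
    )
  )
  genes <- vapply(models, `[[`, character(1), "gene")
  q <- GenomicRanges::GRanges(variants$chrom, IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(q, spans)
  out <- rep(NA_character_, nrow(variants))
  if (length(hits)) {
    by_q <- split(genes[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
    idx <- as.integer(names(by_q))
    out[idx] <- vapply(by_q, function(g) paste(unique(g), collapse = ","), character(1))
  }
  out
}
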