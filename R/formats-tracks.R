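#' Read a repeat annotation track
#'
#' Reads a BED file (0-based half-open on disk) whose name column carries the
#' repeat class — \code{Alu}, \code{simple_repeat} or \code{other_repeat} —
#' into a 1-based \code{GRanges}. Point queries resolve overlapping classes by
#' the fixed priority Alu > simple_repeat > other_repeat.
#'
#' @param path BED file with the class in column 4.
#' @return a \code{GRanges} with metadata column \code{class} (a "repeat
#'   track" in the documentation of downstream functions).
#' @export
read_repeat_track <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("repeat BED needs 4 columns (chrom start end class): ", path)
  if (any(raw[[2L]] >= raw[[3L]]))
    stop("BED interval with start >= end at line(s): ",
         paste(which(raw[[2L]] >= raw[[3L]]), collapse = ", "))
  bad <- !raw[[4L]] %in% c("Alu", "simple_repeat", "other_repeat")
  if (any(bad)) stop("unknown repeat class(es): ",
                     paste(unique(raw[[4L]][bad]), collapse = ", "))
  gr <- rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr)$class <- S4Vectors::mcols(gr)$name
  gr
}

#' Write a repeat track back to BED
#' @param track a \code{repeat_track} (1-based \code{GRanges} with a
#'   \code{class} column).
#' @param path output BED path (written 0-based half-open).
#' @return \code{path}, invisibly.
#' @export
write_repeat_track <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(track)),
    start = BiocGenerics::start(track) - 1L,
    end = BiocGenerics::end(track),
    class = S4Vectors::mcols(track)$class,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Repeat class at genomic points
#'
#' @param track a \code{repeat_track}.
#' @param chrom,pos parallel vectors of query points (1-based).
#' @return character vector: \code{"Alu"}, \code{"simple_repeat"},
#'   \code{"other_repeat"} or \code{NA} when the point hits no interval;
#'   overlaps resolved by priority Alu > simple_repeat > other_repeat.
#' @export
repeat_class_at <- function(track, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) == 0L) return(character(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, track, ignore.strand = TRUE)
  out <- rep(NA_character_, length(pos))
  if (length(hits)) {
    prio <- c(Alu = 1L, simple_repeat = 2L, other_repeat = 3L)
    cls <- S4Vectors::mcols(track)$class[S4Vectors::subjectHits(hits)]
    by_q <- split(cls, S4Vectors::queryHits(hits))
    idx <- as.integer(names(by_q))
    out[idx] <- vapply(by_q, function(cl) cl[which.min(prio[cl])], character(1))
  }
  out
}

#' Read target-capture regions from BED
#' @param path BED file (0-based half-open).
#' @return a 1-based \code{GRanges}.
#' @export
read_target_regions <- function(path) {
  rtracklayer::import(path, format = "bed")
}

# ---- annotation site tables -------------------------------------------------

#' Load the site/allele annotation databases
#'
#' Each source is a TSV with columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt} and an optional \code{freq} column (population frequency;
#' membership-only sources such as dbSNP/COSMIC may omit it or leave it NA).
#' Lookups are keyed on the full allele (chrom, pos, ref, alt); an allele
#' absent from a frequency table has frequency 0 by definition, because every
#' cascade rule is of the form "remove if frequency >= cutoff".
#'
#' @param paths named list/vector of file paths; expected names among
#'   \code{dbsnp137}, \code{esp6500}, \code{kg1000}, \code{cosmic},
#'   \code{tcga_gbm}, \code{normal_editome}.
#' @return an \code{annotation_db} object.
#' @export
read_annotation_db <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("annotation paths must be named by source")
  tabs <- lapply(names(paths), function(src) {
    df <- read.delim(paths[[src]], stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("annotation table '", src, "' missing column(s): ",
                           paste(miss, collapse = ", "))
    if (!"freq" %in% names(df)) df$freq <- rep(NA_real_, nrow(df))
    key <- allele_key(df)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conflicting <- vapply(unique(dup), function(k) {
        length(unique(df$freq[key == k])) > 1L
      }, logical(1))
      if (any(conflicting))
        stop("conflicting frequencies for allele(s) in '", src, "': ",
             paste(unique(dup)[conflicting], collapse = ", "))
      df <- df[!duplicated(key), , drop = FALSE]
      key <- key[!duplicated(key)]
    }
    list(table = df, key = key)
  })
  names(tabs) <- names(paths)
  structure(tabs, class = "annotation_db")
}

#' Build an annotation db in memory (no files)
#' @param ... named site tables (data.frames with chrom, pos, ref, alt and
#'   optionally freq), one per source.
#' @return an \code{annotation_db}.
#' @export
annotation_db <- function(...) {
  tabs <- list(...)
  paths <- lapply(tabs, function(df) {
    f <- tempfile(fileext = ".tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })
  db <- read_annotation_db(paths)
  for (f in unlist(paths)) unlink(f)
  db
}

db_source <- function(db, source) {
  if (!source %in% names(db)) stop("annotation db missing source '", source, "'")
  db[[source]]
}

#' Allele frequency lookup
#' @param db an \code{annotation_db}.
#' @param source source name, e.g. \code{"esp6500"}.
#' @param sites table with chrom, pos, ref, alt columns.
#' @return numeric frequencies; 0 for alleles absent from the table (and for
#'   membership-only entries without a frequency).
#' @export
db_frequency <- function(db, source, sites) {
  s <- db_source(db, source)
  i <- match(allele_key(sites), s$key)
  f <- s$table$freq[i]
  f[is.na(f)] <- 0
  f
}

#' Allele membership lookup
#' @inheritParams db_frequency
#' @return logical vector: is the exact allele listed in the source?
#' @export
db_member <- function(db, source, sites) {
  s <- db_source(db, source)
  allele_key(sites) %in% s$key
}

#' Write one annotation site table as TSV
#' @param df data.frame with chrom, pos, ref, alt and optionally freq.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_site_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- per-site read support (pileup) -----------------------------------------

#' Read a per-site read-support table
#'
#' One row per base observation: which base a read carries at a site and where
#' in the read (1-based offset) that base sits. Site-level support counts are
#' always recomputed from the retained observations.
#'
#' @param path TSV with columns \code{sample_id}, \code{chrom}, \code{pos},
#'   \code{base}, \code{read_offset}.
#' @return the validated data.frame.
#' @export
read_support_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_support_table(df)
}

#' @rdname read_support_table
#' @param support a candidate support data.frame.
#' @export
validate_support_table <- function(support) {
  need <- c("sample_id", "chrom", "pos", "base", "read_offset")
  miss <- setdiff(need, names(support))
  if (length(miss)) stop("support table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(support) && any(support$read_offset < 1L))
    stop("read_offset must be >= 1 (1-based position within the read)")
  support
}

#' @rdname read_support_table
#' @export
write_support_table <- function(support, path) {
  write.table(validate_support_table(support), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- fusion caller tables ---------------------------------------------------

fusion_dialects <- list(
  prada = list(
    header = TRUE,
    cols = c(gene5 = "Gene_A", gene3 = "Gene_B", chrom5 = "Chr_A",
             pos5 = "Pos_A", chrom3 = "Chr_B", pos3 = "Pos_B",
             junction_reads = "Junction_spanning_reads")
  ),
  fusionmap = list(
    header = TRUE,
    cols = c(gene5 = "KnownGene1", gene3 = "KnownGene2", chrom5 = "Chromosome1",
             pos5 = "Position1", chrom3 = "Chromosome2", pos3 = "Position2",
             junction_reads = "SeedCount")
  ),
  tophat_fusion = list(
    header = FALSE,
    # positional layout: gene5 chrom5 pos5 gene3 chrom3 pos3 spanning_reads
    cols = c(gene5 = 1L, chrom5 = 2L, pos5 = 3L, gene3 = 4L, chrom3 = 5L,
             pos3 = 6L, junction_reads = 7L)
  )
)

#' Read fusion calls in one of the three supported caller dialects
#'
#' Normalizes the tab-separated outputs of the three fusion callers into one
#' layout: \code{tool}, \code{gene5}, \code{gene3}, breakpoint coordinates
#' (1-based) and \code{junction_reads}. Column layouts per dialect:
#' \describe{
#'   \item{prada}{header row; \code{Gene_A, Gene_B, Chr_A, Pos_A, Chr_B,
#'     Pos_B, Junction_spanning_reads}.}
#'   \item{fusionmap}{header row; \code{KnownGene1, KnownGene2, Chromosome1,
#'     Position1, Chromosome2, Position2, SeedCount}.}
#'   \item{tophat_fusion}{no header; columns \code{gene5 chrom5 pos5 gene3
#'     chrom3 pos3 spanning_reads}.}
#' }
#' Calls with zero junction reads are accepted and flagged in the
#' \code{low_support} column.
#'
#' @param path caller output file (TSV).
#' @param dialect \code{"prada"}, \code{"fusionmap"} or \code{"tophat_fusion"}.
#' @return data.frame of normalized fusion calls.
#' @export
read_fusion_calls <- function(path, dialect) {
  if (!dialect %in% names(fusion_dialects))
    stop("unknown fusion dialect '", dialect, "'")
  d <- fusion_dialects[[dialect]]
  raw <- read.delim(path, header = d$header, stringsAsFactors = FALSE)
  pick <- function(field) {
    sel <- d$cols[[field]]
    if (is.character(sel)) {
      if (!sel %in% names(raw))
        stop("dialect '", dialect, "' file missing column '", sel, "': ", path)
      raw[[sel]]
    } else {
      if (ncol(raw) < sel)
        stop("dialect '", dialect, "' file has too few columns (need ", sel, "): ", path)
      raw[[sel]]
    }
  }
  df <- data.frame(
    tool = dialect,
    gene5 = as.character(pick("gene5")), gene3 = as.character(pick("gene3")),
    chrom5 = as.character(pick("chrom5")), pos5 = as.integer(pick("pos5")),
    chrom3 = as.character(pick("chrom3")), pos3 = as.integer(pick("pos3")),
    junction_reads = as.integer(pick("junction_reads")),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$gene5 == df$gene3)) stop("fusion with identical partners in ", path)
    if (any(df$junction_reads < 0)) stop("negative junction_reads in ", path)
  }
  df$low_support <- df$junction_reads == 0L
  df
}

#' Write fusion calls in a caller dialect
#' @param calls normalized fusion-call data.frame (as from
#'   [read_fusion_calls()]).
#' @param path output file.
#' @param dialect target dialect.
#' @return \code{path}, invisibly.
#' @export
write_fusion_calls <- function(calls, path, dialect) {
  if (!dialect %in% names(fusion_dialects))
    stop("unknown fusion dialect '", dialect, "'")
  d <- fusion_dialects[[dialect]]
  if (is.character(d$cols)) {
    out <- calls[names(d$cols)]
    names(out) <- unname(d$cols)
  } else {
    ord <- names(sort(d$cols))
    out <- calls[ord]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = d$header)
  invisible(path)
}
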