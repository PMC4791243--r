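#' Construct a table of variant calls
#'
#' The package-wide representation of substitution and indel calls is a plain
#' \code{data.frame} with one row per called ALT allele. This constructor
#' validates the invariants every downstream stage relies on.
#'
#' @param sample_id,chrom,pos,ref,alt core call fields; \code{pos} is 1-based.
#' @param zygosity \code{"hom"} or \code{"het"}.
#' @param depth,alt_reads read depth at the site and reads carrying the ALT
#'   allele (\code{alt_reads <= depth}).
#' @param base_qual Phred-scaled base quality of the call.
#' @param esp6500,kg1000 population allele frequencies (NA when unannotated).
#' @param dbsnp137,cosmic,tcga_gbm database membership flags (NA when
#'   unannotated).
#' @return a \code{data.frame} with an additional \code{kind} column in
#'   \code{{"SNV","insertion","deletion"}}.
#' @export
variant_calls <- function(sample_id, chrom, pos, ref, alt, zygosity,
                          depth = NA_integer_, alt_reads = NA_integer_,
                          base_qual = NA_real_,
                          esp6500 = NA_real_, kg1000 = NA_real_,
                          dbsnp137 = NA, cosmic = NA, tcga_gbm = NA) {
  n <- length(pos)
  rl <- function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x
  sample_id <- rl(sample_id); chrom <- rl(chrom); ref <- rl(ref); alt <- rl(alt)
  zygosity <- rl(zygosity); depth <- rl(depth); alt_reads <- rl(alt_reads)
  base_qual <- rl(base_qual); esp6500 <- rl(esp6500); kg1000 <- rl(kg1000)
  dbsnp137 <- rl(dbsnp137); cosmic <- rl(cosmic); tcga_gbm <- rl(tcga_gbm)
  df <- data.frame(
    sample_id = as.character(sample_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    zygosity = as.character(zygosity),
    depth = as.integer(depth), alt_reads = as.integer(alt_reads),
    base_qual = as.numeric(base_qual),
    esp6500 = as.numeric(esp6500), kg1000 = as.numeric(kg1000),
    dbsnp137 = as.logical(dbsnp137), cosmic = as.logical(cosmic),
    tcga_gbm = as.logical(tcga_gbm),
    stringsAsFactors = FALSE
  )
  df$kind <- variant_kind(df$ref, df$alt)
  validate_variant_calls(df)
}

variant_kind <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  kind <- rep(NA_character_, length(ref))
  kind[nr == 1L & na == 1L] <- "SNV"
  kind[na > nr] <- "insertion"
  kind[na < nr] <- "deletion"
  if (anyNA(kind)) {
    stop("unsupported allele pair (equal-length multi-base substitution): ",
         paste(ref[is.na(kind)], alt[is.na(kind)], sep = ">", collapse = ", "))
  }
  kind
}

#' Signed indel size (insertions positive, deletions negative)
#' @param variants a variant-call data.frame.
#' @return integer vector, 0 for SNVs.
#' @export
indel_size <- function(variants) {
  as.integer(nchar(variants$alt) - nchar(variants$ref))
}

#' @rdname variant_calls
#' @param variants a candidate variant-call data.frame.
#' @export
validate_variant_calls <- function(variants) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "zygosity", "kind")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants) == 0L) return(variants)
  if (any(variants$pos < 1L)) stop("variant pos must be >= 1 (1-based)")
  bad <- !variants$zygosity %in% c("hom", "het")
  if (any(bad)) stop("zygosity must be 'hom' or 'het'")
  if (!all(grepl("^[ACGTN]+$", variants$ref)) || !all(grepl("^[ACGTN]+$", variants$alt)))
    stop("alleles must be non-empty A/C/G/T/N strings")
  ok <- is.na(variants$alt_reads) | is.na(variants$depth) |
    variants$alt_reads <= variants$depth
  if (!all(ok)) stop("alt_reads exceeds depth at row(s): ",
                     paste(which(!ok), collapse = ", "))
  stopifnot(identical(variants$kind, variant_kind(variants$ref, variants$alt)))
  variants
}

#' Key identifying an allele
#' @param variants a variant-call data.frame (or any table with chrom, pos,
#'   ref, alt columns).
#' @return character vector \code{"chrom:pos:ref:alt"}.
#' @export
allele_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "(;|$|=)"), info)
}

info_value <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_, character(1))
}

#' Read variant calls from a VCF file
#'
#' Reads a VCF 4.x file through \pkg{vcfR} and normalizes it into the package's
#' per-allele variant table: multi-allelic records are split into one row per
#' ALT allele before any downstream step, genotypes become a hom/het zygosity,
#' and database annotations are picked up from the INFO keys \code{ESP6500},
#' \code{KG1000} (frequencies) and \code{DBSNP}, \code{COSMIC}, \code{TCGA_GBM}
#' (flags) when present.
#'
#' @param path VCF file.
#' @param sample_id sample label to stamp on every returned row; defaults to
#'   the (single) genotype column name in the file.
#' @return a validated variant-call data.frame (see [variant_calls()]).
#' @export
read_vcf <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("malformed VCF record (", length(f), " fields, need >= 10) at line ", i,
           " of ", path)
    if (is.na(suppressWarnings(as.integer(f[2L]))))
      stop("malformed VCF record (non-integer POS) at line ", i, " of ", path)
    if (!grepl("GT", strsplit(f[9L], ":")[[1]][1]))
      stop("missing GT genotype field at line ", i, " of ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- v@gt
  if (ncol(gt_mat) < 2L) stop("VCF has no genotype column: ", path)
  if (is.null(sample_id)) sample_id <- colnames(gt_mat)[2L]

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt_mat[i, 1L], ":", fixed = TRUE)[[1]]
    val <- strsplit(gt_mat[i, 2L], ":", fixed = TRUE)[[1]]
    gt <- val[match("GT", fmt)]
    if (is.na(gt)) stop("missing genotype for record ", i, " of ", path)
    gt_alleles <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
    dp <- suppressWarnings(as.integer(val[match("DP", fmt)]))
    ad <- suppressWarnings(as.integer(strsplit(val[match("AD", fmt)], ",", fixed = TRUE)[[1]]))
    info <- fix[i, "INFO"]
    esp <- suppressWarnings(as.numeric(info_value(info, "ESP6500")))
    kg <- suppressWarnings(as.numeric(info_value(info, "KG1000")))
    has_info <- !is.na(info) && nzchar(info) && info != "."
    rows <- lapply(seq_along(alts), function(a) {
      ncopy <- sum(gt_alleles == a, na.rm = TRUE)
      data.frame(
        sample_id = sample_id, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = ref, alt = alts[a],
        zygosity = if (ncopy >= 2L) "hom" else "het",
        depth = if (length(dp)) dp else NA_integer_,
        alt_reads = if (length(ad) > a) ad[a + 1L] else NA_integer_,
        base_qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        esp6500 = esp, kg1000 = kg,
        dbsnp137 = if (has_info) info_flag(info, "DBSNP") else NA,
        cosmic = if (has_info) info_flag(info, "COSMIC") else NA,
        tcga_gbm = if (has_info) info_flag(info, "TCGA_GBM") else NA,
        stringsAsFactors = FALSE
      )
    })
    out[[i]] <- do.call(rbind, rows)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- variant_calls(character(), character(), integer(), character(),
                        character(), character())
  } else {
    df$kind <- variant_kind(df$ref, df$alt)
    rownames(df) <- NULL
  }
  validate_variant_calls(df)
}

#' Write a single-sample variant table as VCF 4.2
#'
#' Inverse of [read_vcf()] for the fields this package uses: genotype (hom ->
#' 1/1, het -> 0/1), DP/AD support, QUAL from \code{base_qual}, and the INFO
#' annotation keys \code{ESP6500}/\code{KG1000}/\code{DBSNP}/\code{COSMIC}/
#' \code{TCGA_GBM}. The output is plain text.
#'
#' @param variants variant-call data.frame for one sample.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(variants, path) {
  variants <- validate_variant_calls(variants)
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L) stop("write_vcf() writes one sample per file; got ",
                             length(sid), " samples")
  if (length(sid) == 0L) sid <- "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ESP6500,Number=1,Type=Float,Description=\"ESP6500 allele frequency\">",
    "##INFO=<ID=KG1000,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
    "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"Present in dbSNP build 137\">",
    "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"Present in COSMIC\">",
    "##INFO=<ID=TCGA_GBM,Number=0,Type=Flag,Description=\"Present in TCGA GBM calls\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)
  )
  recs <- character(0)
  if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    info <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      parts <- character(0)
      if (!is.na(v$esp6500)) parts <- c(parts, sprintf("ESP6500=%g", v$esp6500))
      if (!is.na(v$kg1000)) parts <- c(parts, sprintf("KG1000=%g", v$kg1000))
      if (isTRUE(v$dbsnp137)) parts <- c(parts, "DBSNP")
      if (isTRUE(v$cosmic)) parts <- c(parts, "COSMIC")
      if (isTRUE(v$tcga_gbm)) parts <- c(parts, "TCGA_GBM")
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, character(1))
    gt <- ifelse(variants$zygosity == "hom", "1/1", "0/1")
    ad <- ifelse(is.na(variants$depth) | is.na(variants$alt_reads), ".",
                 paste(variants$depth - variants$alt_reads, variants$alt_reads, sep = ","))
    dp <- ifelse(is.na(variants$depth), ".", as.character(variants$depth))
    qual <- ifelse(is.na(variants$base_qual), ".", format(variants$base_qual))
    recs <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                  qual, "PASS", info, "GT:DP:AD",
                  paste(gt, dp, ad, sep = ":"), sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
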