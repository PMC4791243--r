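test_that("call-level filters apply target, quality and support cutoffs inclusively", {
  targets <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 1000L))
  v <- variant_calls("S1", "chr1", c(10L, 20L, 30L, 2000L),
                     ref = "A", alt = "G", zygosity = "het",
                     depth = 60L, alt_reads = c(5L, 6L, 40L, 40L),
                     base_qual = c(35, 30, 29.9, 35))
  res <- suppressMessages(apply_call_filters(v, targets))
  # alt_reads = 5 removed; alt_reads = 6 at qual 30 retained (inclusive)
  expect_identical(res$retained$pos, 20L)
  expect_identical(res$attrition$count[res$attrition$reason == "off_target"], 1L)
  expect_identical(res$attrition$count[res$attrition$reason == "low_qual"], 1L)
  expect_identical(res$attrition$count[res$attrition$reason == "low_support"], 1L)
  # all-failing input: empty output, every reason counted
  bad <- variant_calls("S1", "chr1", c(2000L, 10L, 11L), "A", "G", "het",
                       depth = 60L, alt_reads = c(40L, 40L, 3L),
                       base_qual = c(35, 10, 35))
  res2 <- suppressMessages(apply_call_filters(bad, targets))
  expect_identical(nrow(res2$retained), 0L)
  expect_identical(res2$attrition$count, c(1L, 1L, 1L))
  expect_error(apply_call_filters(v, GenomicRanges::GRanges()), "empty")
})

test_that("Ti/Tv counts and ratio follow the transition definition", {
  v <- snvs(ref = c("A", "G", "C", "A"), alt = c("G", "A", "T", "C"))
  tt <- titv_ratio(v)
  expect_equal(tt$ratio, 3)
  expect_identical(tt$ti, 3L)
  expect_identical(tt$tv, 1L)
  expect_equal(titv_ratio(snvs(ref = "A", alt = "T"))$ratio, 0)
  expect_true(is.na(titv_ratio(snvs(ref = "A", alt = "G"))$ratio))
  expect_error(titv_ratio(snvs(ref = "AT", alt = "A")), "SNVs only")
  # property: six change-type counts partition the SNV set
  set.seed(3)
  for (k in 1:20) {
    ref <- sample(c("A", "C", "G", "T"), 40, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    tt <- titv_ratio(snvs(ref = ref, alt = alt))
    expect_identical(tt$ti + tt$tv, 40L)
    expect_identical(sum(tt$counts), 40L)
  }
})

test_that("zygosity split reports counts, percentages and the hom:het ratio", {
  v <- snvs(ref = rep("A", 18), alt = rep("G", 18),
            zygosity = c(rep("hom", 2), rep("het", 16)))
  z <- zygosity_split(v)
  expect_equal(z$ratio, 1 / 8)
  expect_equal(z$pct_hom + z$pct_het, 100)
  expect_true(is.na(zygosity_split(snvs("A", "G", "hom"))$ratio))
  ze <- zygosity_split(snvs(character(), character(), character()))
  expect_identical(c(ze$hom, ze$het), c(0L, 0L))
})

test_that("coding SNV classification matches the brute-force translation oracle", {
  w <- toy_cds_world(random_cds(30L))
  L <- nchar(random_cds(30L))
  results <- character(0)
  for (i in seq_len(L)) {
    gpos <- w$cds_start + i - 1L
    ref <- as.character(w$genome[["chrT"]][gpos])
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- classify_functional(snvs(ref, alt, pos = gpos, chrom = "chrT"),
                                 w$models, w$genome)
      want <- oracle_coding_class(random_cds(30L), i, alt)
      expect_identical(got, want, info = sprintf("pos %d %s>%s", i, ref, alt))
      results <- c(results, got)
    }
  }
  expect_length(results, 270L)
  expect_true(all(c("missense", "silent", "nonsense") %in% results))
})

test_that("minus-strand coding SNVs translate through the reverse complement", {
  cds <- random_cds(20L, seed = 9)
  set.seed(10)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # place the reverse complement of the CDS on the genome; gene on minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  seq <- paste0(pad(40), rc, pad(40))
  genome <- Biostrings::DNAStringSet(c(chrM = seq))
  tx <- gene_model("MIN", "MIN.1", "chrM", "-",
                   data.frame(start = 1L, end = nchar(seq)),
                   41L, 40L + nchar(cds), "protein_coding")
  models <- list(MIN.1 = tx)
  for (i in c(2L, 5L, 17L, nchar(cds) - 1L)) {     # spot-check CDS offsets
    gpos <- 40L + nchar(cds) - i + 1L              # genomic position of CDS base i
    ref <- as.character(genome[["chrM"]][gpos])
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    got <- classify_functional(snvs(ref, alt, pos = gpos, chrom = "chrM"),
                               models, genome)
    alt_sense <- chartr("ACGT", "TGCA", alt)
    want <- oracle_coding_class(cds, i, alt_sense)
    expect_identical(got, want, info = paste("cds base", i))
  }
})

test_that("location classes cover UTR, splice site, flank, intron, rna and intergenic", {
  b <- planted_bundle()
  m <- models_by_gene(b)
  fusa <- m[["FUSA"]]
  g <- b$genome
  mk <- function(pos, chrom = "chr1") {
    ref <- as.character(g[[chrom]][pos])
    snvs(ref, setdiff(c("A", "C", "G", "T"), ref)[1], pos = pos, chrom = chrom)
  }
  cls <- function(pos, chrom = "chr1")
    classify_functional(mk(pos, chrom), b$models, g)
  expect_identical(cls(fusa$exons$start[1] + 10L), "five_utr")      # in 5' UTR
  expect_identical(cls(fusa$exons$end[20] - 10L), "three_utr")
  expect_identical(cls(fusa$exons$end[1] + 2L), "splice_site")      # 2 bp into intron
  expect_identical(cls(fusa$exons$end[1] + 3L), "intron")
  expect_identical(cls(fusa$exons$start[1] - 100L), "five_flank")
  expect_identical(cls(40000L), "intergenic")
  lnc <- m[["LNC1"]]
  expect_identical(cls(lnc$exons$start[1] + 5L, "chr3"), "rna")
  # 3-base deletion fully inside a CDS is an in-frame indel
  p <- fusa$exons$start[2] + 5L
  del_ref <- as.character(g[["chr1"]][p:(p + 3L)])
  anchor <- substr(del_ref, 1L, 1L)
  del <- variant_calls("S1", "chr1", p, del_ref, anchor, "het")
  expect_identical(classify_functional(del, b$models, g), "inframe_indel")
  ins <- variant_calls("S1", "chr1", p, anchor, paste0(anchor, "GT"), "het")
  expect_identical(classify_functional(ins, b$models, g), "frameshift_indel")
})

test_that("indel spectrum histograms signed sizes and the coding in-frame fraction", {
  b <- planted_bundle()
  v <- variant_calls("S1", "chr1", c(10L, 20L, 30L, 40L),
                     ref = c("ATTT", "AT", "A", "C"),
                     alt = c("A", "A", "AGGG", "CAAATTG"), zygosity = "het")
  sp <- indel_spectrum(v)
  expect_identical(sp$sizes, c("-3" = 1L, "-1" = 1L, "3" = 1L, "6" = 1L))
  expect_equal(sp$inframe_fraction, 0.75)
  expect_error(indel_spectrum(snvs("A", "G")), "insertions/deletions")
  empty <- indel_spectrum(variant_calls(character(), character(), integer(),
                                        character(), character(), character()))
  expect_length(empty$sizes, 0L)
  # planted spectrum: histogram equals the generator truth table exactly
  tr <- b$cohort$truth$indel
  sp2 <- indel_spectrum(b$cohort$indels, b$models)
  expect_identical(sp2$sizes[order(as.integer(names(sp2$sizes)))],
                   {
                     t <- table(tr$size)
                     stats::setNames(as.integer(t), names(t))
                   })
  coding_truth <- table(tr$size[tr$coding])
  expect_identical(sp2$coding_sizes[order(as.integer(names(sp2$coding_sizes)))],
                   stats::setNames(as.integer(coding_truth), names(coding_truth)))
  expect_equal(sp2$inframe_fraction, mean(tr$size[tr$coding] %% 3 == 0))
})

test_that("direction concordance filters both tables and compares fold-change signs", {
  th <- default_thresholds()
  a <- data.frame(gene = c("g1", "g2"), log2fc = c(2, -2), padj = 0.01)
  bb <- data.frame(gene = c("g1", "g2"), log2fc = c(1.5, 1.5), pvalue = 0.01)
  cc <- direction_concordance(a, bb, th)
  expect_identical(cc$n_common, 2L)
  expect_equal(cc$fraction, 0.5)
  disj <- direction_concordance(
    a, data.frame(gene = "g9", log2fc = 1, pvalue = 0.01), th)
  expect_identical(disj$n_common, 0L)
  expect_true(is.na(disj$fraction))
  expect_error(direction_concordance(rbind(a, a), bb, th), "duplicate")
  # sub-threshold rows are excluded before intersecting
  a2 <- rbind(a, data.frame(gene = "g3", log2fc = 0.5, padj = 0.001))
  b2 <- rbind(bb, data.frame(gene = "g3", log2fc = 0.5, pvalue = 0.001))
  expect_identical(direction_concordance(a2, b2, th)$n_common, 2L)
  # planted tables recover the planted fraction exactly
  de <- plant_de_tables(1L)
  got <- direction_concordance(de$de_a, de$de_b, th)
  expect_identical(got$n_common, de$truth$n_common)
  expect_equal(got$fraction, de$truth$fraction)
})
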