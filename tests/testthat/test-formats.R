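test_that("VCF round trip preserves all fields and genotype semantics", {
  v <- variant_calls(
    sample_id = "S1", chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 250L, 30L), ref = c("A", "ATTT", "C"),
    alt = c("G", "A", "CTG"), zygosity = c("hom", "het", "het"),
    depth = c(60L, 40L, 55L), alt_reads = c(58L, 12L, 20L),
    base_qual = c(35, 31, 40),
    esp6500 = c(0, 0.001, 0), kg1000 = c(0.01, 0, 0),
    dbsnp137 = c(TRUE, FALSE, FALSE), cosmic = c(FALSE, TRUE, FALSE),
    tcga_gbm = c(FALSE, FALSE, TRUE)
  )
  expect_identical(v$kind, c("SNV", "deletion", "insertion"))
  expect_identical(indel_size(v), c(0L, -3L, 2L))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f)
  back <- read_vcf(f)
  ord <- order(v$chrom, v$pos, v$alt)
  expect_equal(back, `rownames<-`(v[ord, ], NULL))
  expect_identical(back$zygosity, c("hom", "het", "het"))
})

test_that("multi-allelic VCF records split per ALT allele like a hand-split copy", {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  multi <- c(hdr, "chr1\t500\t.\tA\tG,T\t33\tPASS\t.\tGT:DP:AD\t1/2:50:2,30,18")
  split2 <- c(hdr,
              "chr1\t500\t.\tA\tG\t33\tPASS\t.\tGT:DP:AD\t0/1:50:2,30",
              "chr1\t500\t.\tA\tT\t33\tPASS\t.\tGT:DP:AD\t0/1:50:2,18")
  fm <- withr::local_tempfile(fileext = ".vcf")
  fs <- withr::local_tempfile(fileext = ".vcf")
  writeLines(multi, fm); writeLines(split2, fs)
  vm <- read_vcf(fm, "S1")
  vs <- read_vcf(fs, "S1")
  expect_equal(nrow(vm), 2L)
  expect_equal(vm[c("chrom", "pos", "ref", "alt", "zygosity", "alt_reads")],
               vs[c("chrom", "pos", "ref", "alt", "zygosity", "alt_reads")])
})

test_that("malformed VCF records and missing genotypes error with the line number", {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  bad_pos <- c(hdr, "chr1\tnotanumber\t.\tA\tG\t30\tPASS\t.\tGT\t0/1")
  no_gt <- c(hdr, "chr1\t100\t.\tA\tG\t30\tPASS\t.\tDP\t50")
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(bad_pos, f1); writeLines(no_gt, f2)
  expect_error(read_vcf(f1), "line 3")
  expect_error(read_vcf(f2), "GT")
})

test_that("BED repeat intervals convert 0-based half-open to 1-based points", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tAlu", f)
  track <- read_repeat_track(f)
  expect_identical(repeat_class_at(track, "chr1", 100L), "Alu")
  expect_identical(repeat_class_at(track, "chr1", 99L), NA_character_)
  expect_identical(repeat_class_at(track, "chr1", 200L), "Alu")
  expect_identical(repeat_class_at(track, "chr1", 201L), NA_character_)
  # property: for random intervals [s, e), contained points are s+1..e exactly
  set.seed(11)
  for (k in 1:20) {
    s <- sample(1000L, 1L); w <- sample(50L, 1L)
    f2 <- withr::local_tempfile(fileext = ".bed")
    writeLines(sprintf("chr9\t%d\t%d\tAlu", s, s + w), f2)
    tr <- read_repeat_track(f2)
    pts <- (s - 1L):(s + w + 2L)
    hit <- !is.na(repeat_class_at(tr, rep("chr9", length(pts)), pts))
    expect_identical(pts[hit], (s + 1L):(s + w))
  }
})

test_that("overlapping repeat classes resolve by Alu > simple > other priority", {
  # exhaustive over two overlapping intervals of every class pair
  classes <- c("Alu", "simple_repeat", "other_repeat")
  prio <- c(Alu = 1L, simple_repeat = 2L, other_repeat = 3L)
  for (c1 in classes) for (c2 in classes) {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(c(sprintf("chr1\t10\t30\t%s", c1),
                 sprintf("chr1\t20\t40\t%s", c2)), f)
    track <- read_repeat_track(f)
    expect_identical(repeat_class_at(track, "chr1", 25L),
                     classes[min(prio[c1], prio[c2])],
                     info = paste(c1, c2))
  }
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t50\tAlu", f)
  expect_error(read_repeat_track(f), "start >= end")
})

test_that("gene models survive a GTF write/read round trip", {
  b <- planted_bundle()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models(b$models, f)
  back <- read_gene_models(f)
  expect_setequal(names(back), names(b$models))
  for (id in names(b$models)) {
    a <- b$models[[id]]; r <- back[[id]]
    expect_identical(r$gene, a$gene)
    expect_identical(r$strand, a$strand)
    expect_equal(r$exons, a$exons)
    expect_identical(r$cds_start, a$cds_start)
    expect_identical(r$cds_end, a$cds_end)
    expect_identical(r$biotype, a$biotype)
  }
  # minus-strand transcript keeps plus-strand coordinates
  gfc <- back[["GFC.1"]]
  expect_identical(gfc$strand, "-")
  expect_true(all(diff(gfc$exons$start) > 0))
  # exon-only transcript is inferred non-coding
  expect_true(back[["LNC1.1"]]$biotype != "protein_coding")
  expect_true(is.na(back[["LNC1.1"]]$cds_start))
})

test_that("gene-model invariants are enforced", {
  expect_error(gene_model("G", "G.1", "chr1", "*",
                          data.frame(start = 1L, end = 10L)), "strand")
  expect_error(gene_model("G", "G.1", "chr1", "+",
                          data.frame(start = c(1L, 5L), end = c(10L, 20L))),
               "overlapping")
  expect_error(gene_model("G", "G.1", "chr1", "+",
                          data.frame(start = 10L, end = 30L),
                          cds_start = 5L, cds_end = 20L), "outside exons")
})

test_that("fusion dialects parse, write and normalize identically", {
  b <- planted_bundle()
  for (tool in names(b$fusions$calls_by_tool)) {
    calls <- b$fusions$calls_by_tool[[tool]]
    f <- withr::local_tempfile(fileext = ".tsv")
    write_fusion_calls(calls, f, tool)
    back <- read_fusion_calls(f, tool)
    expect_equal(back, `rownames<-`(calls[names(back)], NULL))
  }
  # the example fusion carries 19 junction-spanning reads in the PRADA table
  pr <- b$fusions$calls_by_tool$prada
  expect_identical(pr$junction_reads[pr$gene5 == "FUSA"], 19L)
  # the consensus pair is reported with identical gene symbols by all tools
  for (tool in names(b$fusions$calls_by_tool)) {
    ct <- b$fusions$calls_by_tool[[tool]]
    expect_true(any(ct$gene5 == "FUSA" & ct$gene3 == "FUSB"))
  }
  expect_error(read_fusion_calls(f, "defuse"), "unknown fusion dialect")
})

test_that("zero-support fusion rows are kept but flagged", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene_A\tGene_B\tChr_A\tPos_A\tChr_B\tPos_B\tJunction_spanning_reads",
               "AAA\tBBB\tchr1\t100\tchr2\t200\t0"), f)
  calls <- read_fusion_calls(f, "prada")
  expect_identical(nrow(calls), 1L)
  expect_true(calls$low_support)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene_A\tGene_B\tChr_A\tPos_A",
               "AAA\tBBB\tchr1\t100"), f2)
  expect_error(read_fusion_calls(f2, "prada"), "missing column")
})

test_that("annotation store answers allele-keyed membership and frequency", {
  db <- annotation_db(
    esp6500 = data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                         freq = 0.0001),
    dbsnp137 = data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G")
  )
  q <- function(alt) data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = alt)
  expect_equal(db_frequency(db, "esp6500", q("G")), 0.0001)
  expect_equal(db_frequency(db, "esp6500", q("T")), 0)   # absent => 0
  # keying over enumerated alternate alleles is independent per allele
  db2 <- annotation_db(kg1000 = data.frame(
    chrom = "chr1", pos = 10L, ref = "A", alt = c("C", "G", "T"),
    freq = c(0.1, 0.2, 0.3)))
  expect_equal(db_frequency(db2, "kg1000",
                            data.frame(chrom = "chr1", pos = 10L, ref = "A",
                                       alt = c("T", "C", "G"))),
               c(0.3, 0.1, 0.2))
  expect_true(db_member(db, "dbsnp137", q("G")))
  expect_false(db_member(db, "dbsnp137", q("T")))
  expect_error(
    annotation_db(esp6500 = data.frame(chrom = "chr1", pos = 10L, ref = "A",
                                       alt = "G", freq = c(0.1, 0.2))),
    "conflicting")
  expect_error(db_frequency(db, "cosmic", q("G")), "missing source")
})

test_that("support tables validate read offsets and thresholds read from YAML", {
  expect_error(validate_support_table(
    data.frame(sample_id = "S1", chrom = "chr1", pos = 1L, base = "A",
               read_offset = 0L)), "read_offset")
  th <- default_thresholds()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(th, f)
  expect_equal(unclass(read_thresholds(f)), unclass(th))
  writeLines("min_alt_reads_rna: 5", f)
  expect_equal(read_thresholds(f)$min_alt_reads_rna, 5)
  expect_error(default_thresholds(esp_cut = 0), "strictly positive")
  expect_error(default_thresholds(padj_cut = 2), "frequency")
  expect_error(default_thresholds(bogus = 1), "unknown threshold")
})
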