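support_row <- function(sample, chrom, pos, base, offset) {
  data.frame(sample_id = sample, chrom = chrom, pos = pos, base = base,
             read_offset = offset, stringsAsFactors = FALSE)
}

test_that("read-start trimming removes offsets <= 6 and support recounts agree", {
  sup <- rbind(support_row("S1", "chr1", 100L, "G", c(2L, 4L, 5L)),
               support_row("S1", "chr1", 200L, "G", c(6L, 7L)))
  tr <- trim_read_start_support(sup)
  # a site supported only at offsets {2,4,5} loses all support
  expect_identical(nrow(tr[tr$pos == 100L, ]), 0L)
  # offsets {6,7}: the first six bases are discarded, offset 7 survives
  expect_identical(tr$read_offset[tr$pos == 200L], 7L)
  # brute-force recount oracle on a random mixed table
  set.seed(5)
  big <- support_row("S1", "chr1", sample(1:20, 300, TRUE),
                     sample(c("A", "G"), 300, TRUE), sample(1:40, 300, TRUE))
  tr2 <- trim_read_start_support(big)
  sites <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:20, alt = "G")
  got <- site_support(sites, tr2)
  for (p in 1:20) {
    keep <- big$pos == p & big$read_offset > 6L
    expect_identical(got$alt_reads[p], sum(keep & big$base == "G"))
    expect_identical(got$total_reads[p], sum(keep))
  }
})

test_that("support, splice and homopolymer filters apply their printed boundaries", {
  b <- planted_bundle()
  th <- default_thresholds()
  junc <- splice_junctions(b$models)
  j1 <- junc[1, ]
  far_chrom <- "chr3"
  mk_site <- function(chrom, pos, alt_reads, total) {
    data.frame(sample_id = "S1", chrom = chrom, pos = pos, ref = "A", alt = "G",
               alt_reads = alt_reads, total_reads = total,
               edit_freq = ifelse(total > 0, alt_reads / total, NA_real_),
               stringsAsFactors = FALSE)
  }
  # exactly 3 alt reads of 30 sits on both stated boundaries and passes
  clean_pos <- 290000L  # outside genes/repeats on chr1
  v <- site_filters(mk_site("chr1", clean_pos, 3L, 30L), b$genome, junc,
                    b$repeats, th)
  expect_true(v$support)
  expect_false(site_filters(mk_site("chr1", clean_pos, 2L, 30L), b$genome,
                            junc, b$repeats, th)$support)
  expect_false(site_filters(mk_site("chr1", clean_pos, 3L, 31L), b$genome,
                            junc, b$repeats, th)$support)
  # within 4 bp of a junction fails, 5 bp away passes
  expect_false(site_filters(mk_site(j1$chrom, j1$pos + 4L, 6L, 20L), b$genome,
                            junc, b$repeats, th)$splice)
  expect_true(site_filters(mk_site(j1$chrom, j1$pos + 5L, 6L, 20L), b$genome,
                           junc, b$repeats, th)$splice)
  # planted AAAAAAA run fails; a 4-run passes
  hp_pos <- b$homopolymer$start + 3L
  expect_false(site_filters(mk_site("chr1", hp_pos, 6L, 20L), b$genome, junc,
                            b$repeats, th)$homopolymer)
  # build an exact 4-run to check the >= 5 boundary
  g2 <- Biostrings::DNAStringSet(c(chrX = "CCGTAAAATGCCGTAGGCTA"))
  v4 <- site_filters(
    data.frame(sample_id = "S1", chrom = "chrX", pos = 7L, ref = "A", alt = "G",
               alt_reads = 6L, total_reads = 20L, edit_freq = 0.3),
    g2, junc[0, ], b$repeats[0], th)
  expect_true(v4$homopolymer)
  # duplicated-segment site fails the uniqueness (multimap) filter
  dup_pos <- b$dup$src$start + 100L
  expect_false(site_filters(mk_site("chr1", dup_pos, 6L, 20L), b$genome, junc,
                            b$repeats, th)$multimap)
  expect_true(site_filters(mk_site("chr1", clean_pos, 6L, 20L), b$genome, junc,
                           b$repeats, th)$multimap)
  # simple-repeat membership fails its filter
  sr <- b$repeats[S4Vectors::mcols(b$repeats)$class == "simple_repeat"][1]
  srp <- BiocGenerics::start(sr) + 5L
  expect_false(site_filters(mk_site(as.character(GenomeInfoDb::seqnames(sr)),
                                    srp, 6L, 20L), b$genome, junc, b$repeats,
                            th)$simple_repeat)
})

test_that("homopolymer run lengths agree with a brute-force run-length scan", {
  set.seed(12)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE, prob = c(.4, .1, .1, .4)),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrR = seq))
  r <- rle(strsplit(seq, "")[[1]])
  brute <- rep(r$lengths, r$lengths)
  for (pos in sample(500L, 60L)) {
    expect_identical(homopolymer_run_length(genome, "chrR", pos),
                     as.integer(brute[pos]), info = paste("pos", pos))
  }
})

test_that("editing type is read off the reference-strand base change", {
  expect_identical(edit_type("A", "G"), "ADAR")
  expect_identical(edit_type("T", "C"), "ADAR")
  expect_identical(edit_type("C", "T"), "APOBEC")
  expect_identical(edit_type("G", "A"), "APOBEC")
  expect_identical(edit_type("A", "C"), "other")
  expect_identical(edit_type(c("A", "G", "T"), c("G", "A", "G")),
                   c("ADAR", "APOBEC", "other"))
})

test_that("known-editome and matched-WES subtraction remove exactly their hits", {
  sites <- data.frame(sample_id = "S1", chrom = "chr1", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  editome <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G")
  wes <- list(S1 = variant_calls("S1", "chr1", 20L, "A", "T", "het"))
  res <- subtract_known(sites, editome, wes)
  expect_identical(res$retained$pos, 30L)
  expect_identical(res$n_editome, 1L)
  expect_identical(res$n_wes, 1L)
  expect_error(subtract_known(sites, editome, list(S9 = wes$S1)),
               "no matched WES")
})

test_that("recurrence counts samples sharing an identical allele", {
  sites <- data.frame(
    sample_id = c("S1", "S2", "S3", "S3"),
    chrom = "chr1", pos = c(10L, 10L, 50L, 50L), ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  r <- recurrence(sites, n_samples = 6L)
  expect_identical(r$per_site$n_samples[r$per_site$pos == 10L], 2L)
  expect_identical(r$per_site$n_samples[r$per_site$pos == 50L], 1L)
  expect_identical(sum(r$distribution), nrow(r$per_site))
})

test_that("the editing pipeline recovers planted truth with per-stage attrition", {
  b <- planted_bundle()
  ed <- b$editing
  res <- suppressMessages(run_editing_pipeline(
    ed$rna_variants, ed$db, ed$support, b$models, b$repeats, b$genome,
    ed$normal_editome, ed$wes_by_sample))
  out_key <- sort(paste(res$sites$sample_id, allele_key(res$sites)))
  truth_key <- sort(paste(ed$truth$sites$sample_id, allele_key(ed$truth$sites)))
  expect_identical(out_key, truth_key)
  # every artifact is removed at exactly its intended stage
  planted_stage <- table(ed$truth$artifacts$stage)
  for (st in res$attrition$stage) {
    expect_identical(res$attrition$count[res$attrition$stage == st],
                     if (st %in% names(planted_stage))
                       as.integer(planted_stage[[st]]) else 0L,
                     info = st)
  }
  expect_identical(sum(res$attrition$count),
                   nrow(ed$rna_variants) - nrow(res$sites))
  # fractions partition the output
  expect_equal(sum(res$breakdowns$region), 1)
  expect_equal(sum(res$breakdowns$genic), 1)
  # recurrence distribution matches the planted sharing profile
  expect_identical(sum(res$breakdowns$recurrence * as.integer(names(res$breakdowns$recurrence))),
                   nrow(unique(ed$truth$sites[c("sample_id", "chrom", "pos",
                                                "ref", "alt")])))
})

test_that("Alu sites bypass the five artifact filters but not the subtractions", {
  b <- planted_bundle()
  alu <- b$repeats[S4Vectors::mcols(b$repeats)$class == "Alu"][1]
  chrom <- as.character(GenomeInfoDb::seqnames(alu))
  pos <- BiocGenerics::start(alu) + c(10L, 20L)
  ref <- vapply(pos, function(p) as.character(b$genome[[chrom]][p]), character(1))
  alt <- ifelse(ref == "A", "G", ifelse(ref == "T", "C",
                ifelse(ref == "C", "T", "A")))
  rna <- variant_calls("S1", chrom, pos, ref, alt, "het", depth = 20L,
                       alt_reads = 1L, base_qual = 35)
  # terrible support (1 read, all at offset <= 6): would fail every support
  # rule, but both sites are inside an Alu and must survive the five filters
  sup <- do.call(rbind, lapply(seq_along(pos), function(i)
    support_row("S1", chrom, pos[i], alt[i], 3L)))
  editome <- data.frame(chrom = chrom, pos = pos[2], ref = ref[2], alt = alt[2])
  db <- annotation_db(
    dbsnp137 = data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character()),
    kg1000 = data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(), freq = numeric()),
    esp6500 = data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(), freq = numeric())
  )
  res <- suppressMessages(run_editing_pipeline(
    rna, db, sup, b$models, b$repeats, b$genome, editome,
    list(S1 = rna[0, ])))
  # only the editome hit is removed; the Alu site with hopeless support stays
  expect_identical(res$sites$pos, pos[1])
  expect_identical(res$attrition$count[res$attrition$stage == "editome"], 1L)
  expect_identical(sum(res$attrition$count), 1L)
})
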