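test_that("consensus keeps only pairs called by every tool, with majority breakpoints", {
  b <- planted_bundle()
  calls <- b$fusions$calls_by_tool
  res <- consensus_fusions(calls)
  tr <- b$fusions$truth
  expect_identical(nrow(res$consensus), nrow(tr))
  expect_setequal(paste(res$consensus$gene5, res$consensus$gene3),
                  paste(tr$gene5, tr$gene3))
  # pairs in 2/3 tools are excluded from the consensus, kept pairwise
  expect_true(all(paste0("SHA", 1:3) %in% res$pairwise$gene5))
  expect_false(any(paste0("SHA", 1:3) %in% res$consensus$gene5))
  # one tool reports a discordant breakpoint: the majority tuple wins
  i <- which(res$consensus$gene5 == "GFD")
  expect_identical(res$consensus$pos5[i], tr$pos5[tr$gene5 == "GFD"])
  expect_error(consensus_fusions(calls["prada"]), "at least two tools")
})

test_that("breakpoints map to exon index, cumulative CDS offset and boundary flag", {
  b <- planted_bundle()
  m <- models_by_gene(b)
  fusa <- m[["FUSA"]]
  mb <- map_breakpoint(fusa, fusa$exons$end[3])
  expect_identical(mb$exon, 3L)
  expect_true(mb$boundary)
  expect_identical(mb$cds_offset, 489L)
  # a position before the CDS start has offset 0
  expect_identical(map_breakpoint(fusa, fusa$exons$start[1] + 2L)$cds_offset, 0L)
  # an intronic position is flagged and attributed to the upstream exon
  mi <- map_breakpoint(fusa, fusa$exons$end[3] + 50L)
  expect_true(mi$intronic)
  expect_identical(mi$exon, 3L)
  expect_identical(mi$cds_offset, 489L)
  expect_error(map_breakpoint(fusa, 1L), "outside span")
  # minus-strand transcript: hand-computed expectations
  # GFC genomic exons (ascending) have lengths 150/130/170/220; transcription
  # order reverses them, 5' UTR is 70 nt, so CDS offsets accumulate 150,
  # 150+170, ... in transcription order
  gfc <- m[["GFC"]]
  n <- nrow(gfc$exons)
  mb1 <- map_breakpoint(gfc, gfc$exons$start[n])   # transcription exon 1 end
  expect_identical(mb1$exon, 1L)
  expect_true(mb1$boundary)
  expect_identical(mb1$cds_offset, 220L - 70L)
  mb2 <- map_breakpoint(gfc, gfc$exons$start[n - 1L])
  expect_identical(mb2$exon, 2L)
  expect_identical(mb2$cds_offset, 220L - 70L + 170L)
  mb3 <- map_breakpoint(gfc, gfc$exons$end[n])     # transcription exon 1 START
  expect_identical(mb3$exon, 1L)
  expect_identical(mb3$cds_offset, 0L)             # first base is 5' UTR
})

test_that("fusion ORF assembly translates the worked junction to 222 residues", {
  b <- planted_bundle()
  m <- models_by_gene(b)
  pr <- assemble_fusion_orf(m[["FUSA"]], m[["FUSA"]]$exons$end[3],
                            m[["FUSB"]], m[["FUSB"]]$exons$start[2], b$genome)
  expect_true(pr$in_frame)
  expect_identical(pr$cds_len5, 489L)
  expect_identical(pr$protein_length, 222L)
  expect_identical(pr$retained_exons5, 1:3)
  expect_identical(pr$retained_exons3, 2:5)
  expect_identical(pr$entry_phase3, 0L)
  expect_false(pr$truncated)
  # 488 retained nt against the same phase-0 entry is out of frame
  pr2 <- assemble_fusion_orf(m[["FUSA"]], m[["FUSA"]]$exons$end[3] - 1L,
                             m[["FUSB"]], m[["FUSB"]]$exons$start[2], b$genome)
  expect_identical(pr2$cds_len5, 488L)
  expect_false(pr2$in_frame)
  expect_error(assemble_fusion_orf(m[["FUSA"]], m[["FUSA"]]$exons$end[3],
                                   m[["LNC1"]], m[["LNC1"]]$exons$start[2],
                                   b$genome),
               "not protein coding")
})

test_that("translation stops at the first in-frame stop and never reads past it", {
  b <- planted_bundle()
  m <- models_by_gene(b)
  tr <- b$fusions$truth
  for (i in seq_len(nrow(tr))) {
    pr <- assemble_fusion_orf(m[[tr$gene5[i]]], tr$pos5[i],
                              m[[tr$gene3[i]]], tr$pos3[i], b$genome)
    expect_identical(pr$in_frame, tr$in_frame[i],
                     info = paste(tr$gene5[i], tr$gene3[i]))
    expect_lte(pr$protein_length * 3L, pr$cds_len5 + pr$cds_len3)
    expect_false(grepl("[*]", pr$protein, fixed = FALSE))
  }
})

test_that("assembly is invariant to strand representation", {
  b <- planted_bundle()
  m <- models_by_gene(b)
  # minus-strand 5' partner as planted
  tr <- b$fusions$truth
  i <- which(tr$gene5 == "GFC")
  p_minus <- assemble_fusion_orf(m[["GFC"]], tr$pos5[i], m[["GFD"]],
                                 tr$pos3[i], b$genome)
  # rebuild chr3 reverse-complemented with GFC re-expressed on the plus strand
  L <- length(b$genome[["chr3"]])
  rc_genome <- b$genome
  rc_genome[["chr3"]] <- Biostrings::reverseComplement(b$genome[["chr3"]])
  gfc <- m[["GFC"]]
  flip <- function(x) L - x + 1L
  gfc_rc <- gene_model("GFC", "GFC.rc", "chr3", "+",
                       data.frame(start = flip(gfc$exons$end),
                                  end = flip(gfc$exons$start)),
                       flip(gfc$cds_end), flip(gfc$cds_start),
                       "protein_coding")
  p_plus <- assemble_fusion_orf(gfc_rc, flip(tr$pos5[i]), m[["GFD"]],
                                tr$pos3[i], rc_genome)
  expect_identical(p_plus$protein, p_minus$protein)
  expect_identical(p_plus$in_frame, p_minus$in_frame)
  expect_identical(p_plus$cds_len5, p_minus$cds_len5)
})

test_that("the primer scheme yields three distinct amplicons, none from cross pairs", {
  b <- planted_bundle()
  m <- models_by_gene(b)
  pr <- assemble_fusion_orf(m[["FUSA"]], m[["FUSA"]]$exons$end[3],
                            m[["FUSB"]], m[["FUSB"]]$exons$start[2], b$genome)
  jp <- junction_primers(pr, m[["FUSA"]], m[["FUSB"]], b$genome)
  amp <- jp$amplicons
  three <- amp$length[match(c("wildtype_5prime", "wildtype_3prime", "fusion"),
                            amp$name)]
  expect_false(anyNA(three))
  expect_identical(anyDuplicated(three), 0L)
  # fusion primer pair yields no product on either wild-type template
  expect_true(all(is.na(amp$length[grep("fusion_pair_on", amp$name)])))
  # independent string-search oracle for the fusion amplicon length
  cdna5 <- as.character(spliced_sequence(m[["FUSA"]], b$genome))
  cdna3 <- as.character(spliced_sequence(m[["FUSB"]], b$genome))
  # junction index = position of bp5 within the spliced 5' transcript:
  # exons 1..3 are fully retained
  ex <- m[["FUSA"]]$exons
  j5 <- sum(ex$end[1:3] - ex$start[1:3] + 1L)
  fused <- paste0(substr(cdna5, 1, j5), substr(cdna3, 181, nchar(cdna3)))
  fstart <- regexpr(jp$primers[["fwd5"]], fused, fixed = TRUE)
  rc_rev3 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(jp$primers[["rev3"]])))
  rend <- regexpr(rc_rev3, fused, fixed = TRUE) + nchar(rc_rev3) - 1L
  expect_identical(amp$length[amp$name == "fusion"],
                   as.integer(rend - fstart + 1L))
  expect_error(junction_primers(pr, m[["FUSA"]], m[["FUSB"]], b$genome,
                                gap = -1L), "overlaps the junction")
})

test_that("identical primer windows are rejected", {
  # two transcripts with byte-identical sequence on twin chromosomes force the
  # junction-side forward primer to equal the 3' partner's start primer when
  # the junction sits exactly gap + primer_len into the transcript
  set.seed(33)
  cds <- random_cds(40L, seed = 33)
  pad <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  seqs <- paste0(pad, cds, pad)
  genome <- Biostrings::DNAStringSet(c(twinA = seqs, twinB = seqs))
  mk <- function(chrom, gene) gene_model(gene, paste0(gene, ".1"), chrom, "+",
                                         data.frame(start = 1L,
                                                    end = nchar(seqs)),
                                         31L, 30L + nchar(cds))
  txA <- mk("twinA", "TWA"); txB <- mk("twinB", "TWB")
  pr <- assemble_fusion_orf(txA, 50L, txB, 51L, genome)
  expect_error(junction_primers(pr, txA, txB, genome, primer_len = 20L,
                                gap = 30L), "identical primer windows")
})
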