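test_that("scaffold length and GC follow the ambiguity-aware definitions", {
  fa <- writeTempFasta(list(s1 = "ATGC", s2 = "AAAA", s3 = "ATGNNC"))
  st <- computeScaffoldStats(fa)
  expect_equal(st$scaffold_id, c("s1", "s2", "s3"))
  expect_equal(st$length, c(4, 4, 6))          # N counts toward length
  expect_equal(st$gc, c(0.5, 0, 2 / 4))        # N excluded from GC
  expect_true(all(st$gc_defined))

  # lower-case and multi-line records parse identically
  fa2 <- writeTempFasta(list(s1 = c("at", "gc")))
  expect_equal(computeScaffoldStats(fa2)$gc, 0.5)
})

test_that("degenerate FASTA inputs error or flag as specified", {
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(computeScaffoldStats(empty), "no sequences")

  zerolen <- tempfile(fileext = ".fasta")
  writeLines(c(">good", "ACGT", ">bad", ""), zerolen)
  expect_error(computeScaffoldStats(zerolen), "bad")

  allN <- writeTempFasta(list(nn = "NNNN"))
  expect_warning(st <- computeScaffoldStats(allN), "nn")
  expect_equal(st$gc, 0)
  expect_false(st$gc_defined)

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(computeScaffoldStats(dup), "duplicate")
})

test_that("SAM depth, breadth and read GC match hand-counted values", {
  fa <- writeTempFasta(list(s1 = "ACGTACGT", s2 = "ACGT"))
  st <- computeScaffoldStats(fa)
  sam <- writeTempSam(list(s1 = 8L, s2 = 4L), list(
    list(qname = "r1", rname = "s1", pos = 1L, cigar = "4M", seq = "ATAT"),
    list(qname = "r2", rname = "s1", pos = 1L, cigar = "4M", seq = "GCGC")))
  al <- summarizeAlignments(sam, st)
  s1 <- al[al$scaffold_id == "s1", ]
  # depth vector (2,2,2,2,0,0,0,0)
  expect_equal(s1$mean_depth, 1.0)
  expect_equal(s1$breadth, 0.5)
  expect_equal(s1$aligned_read_gc, 0.5)
  expect_false(s1$no_data)
  # scaffold with no reads: zero evidence, flagged
  s2 <- al[al$scaffold_id == "s2", ]
  expect_equal(unlist(s2[, c("mean_depth", "breadth", "aligned_read_gc")]),
               c(mean_depth = 0, breadth = 0, aligned_read_gc = 0))
  expect_true(s2$no_data)
})

test_that("alignment filters honor FLAG bits and CIGAR reference consumption", {
  fa <- writeTempFasta(list(s1 = "ACGTACGTAC"))
  st <- computeScaffoldStats(fa)
  # secondary (0x100) and non-proper-pair records are excluded; a 2M2D2M
  # alignment consumes 6 reference positions (deletion covered)
  sam <- writeTempSam(list(s1 = 10L), list(
    list(qname = "p", rname = "s1", pos = 1L, cigar = "2M2D2M", seq = "ACGT"),
    list(qname = "sec", flag = 355L, rname = "s1", pos = 5L, cigar = "4M",
         seq = "GGGG"),
    list(qname = "unpaired", flag = 0L, rname = "s1", pos = 7L, cigar = "4M",
         seq = "CCCC")))
  al <- summarizeAlignments(sam, st)
  expect_equal(al$mean_depth, 6 / 10)   # only the proper-paired primary read
  expect_equal(al$breadth, 6 / 10)
  expect_equal(al$aligned_read_gc, 0.5) # full read bases ACGT
  # soft clips contribute read bases in "read" mode but not in "aligned"
  sam2 <- writeTempSam(list(s1 = 10L), list(
    list(qname = "sc", rname = "s1", pos = 1L, cigar = "2S2M", seq = "GGAT")))
  expect_equal(summarizeAlignments(sam2, st)$aligned_read_gc, 0.5)
  expect_equal(summarizeAlignments(sam2, st, readGcMode = "aligned")$aligned_read_gc, 0)
  # unknown reference errors
  sam3 <- writeTempSam(list(s1 = 10L, ghost = 5L), list(
    list(qname = "g", rname = "ghost", pos = 1L, cigar = "4M", seq = "ACGT")))
  expect_error(summarizeAlignments(sam3, st), "ghost")
})

test_that("doubling every alignment doubles depth but not breadth or read GC", {
  fa <- writeTempFasta(list(s1 = "ACGTACGT"))
  st <- computeScaffoldStats(fa)
  one <- list(list(qname = "r1", rname = "s1", pos = 2L, cigar = "4M",
                   seq = "ATGC"))
  two <- c(one, list(list(qname = "r1b", rname = "s1", pos = 2L, cigar = "4M",
                          seq = "ATGC")))
  a1 <- summarizeAlignments(writeTempSam(list(s1 = 8L), one), st)
  a2 <- summarizeAlignments(writeTempSam(list(s1 = 8L), two), st)
  expect_equal(a2$mean_depth, 2 * a1$mean_depth)
  expect_equal(a2$breadth, a1$breadth)
  expect_equal(a2$aligned_read_gc, a1$aligned_read_gc)
  expect_true(a1$mean_depth >= a1$breadth)
})

test_that("TSV alignment inputs round-trip summaries and validate positions", {
  fa <- writeTempFasta(list(s1 = "ACGTACGT", s2 = "ACGT"))
  st <- computeScaffoldStats(fa)
  # summary dialect passes through
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(scaffold_id = "s1", mean_depth = 2.5, breadth = 0.75,
                         aligned_read_gc = 0.4),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  al <- summarizeAlignments(tsv, st)
  expect_equal(al$mean_depth, c(2.5, 0))
  expect_equal(al$breadth, c(0.75, 0))
  expect_true(al$no_data[2])
  # per-base dialect computes mean and breadth and validates positions
  pb <- tempfile(fileext = ".tsv")
  write.table(data.frame(scaffold_id = "s1", pos = 1:4, depth = c(2, 2, 2, 2)),
              pb, sep = "\t", quote = FALSE, row.names = FALSE)
  al2 <- summarizeAlignments(pb, st)
  expect_equal(al2$mean_depth[1], 1.0)
  expect_equal(al2$breadth[1], 0.5)
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(scaffold_id = "s2", pos = 9, depth = 1),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(summarizeAlignments(bad, st), "outside")
  # excluded libraries (e.g. mate pair) are skipped entirely
  al3 <- summarizeAlignments(tsv, st, exclude = TRUE)
  expect_true(all(al3$mean_depth == 0) && all(al3$no_data))
})

test_that("predictor table has the canonical shape and zero-fills RNA evidence", {
  fa <- writeTempFasta(list(a = "ACGT", b = "GGCC", c = "ATAT"))
  st <- computeScaffoldStats(fa)
  dna <- data.frame(scaffold_id = c("a", "b", "c"), mean_depth = c(2, 3, 1),
                    breadth = c(1, 1, 0.5), aligned_read_gc = c(0.5, 1, 0))
  rna <- data.frame(scaffold_id = "a", mean_depth = 4, breadth = 0.9,
                    aligned_read_gc = 0.55)
  pt <- buildPredictorTable(st, dna, rna)
  tb <- as.data.frame(pt)
  expect_equal(colnames(tb),
               c("scaffold_id", "length", "gc", "dna_mean_depth",
                 "rna_mean_depth", "dna_breadth", "rna_breadth",
                 "dna_read_gc", "rna_read_gc"))
  expect_equal(nrow(tb), 3)
  # scaffolds without RNA alignments: rna_* all 0 (a valid signal)
  expect_equal(tb$rna_mean_depth, c(4, 0, 0))
  expect_equal(tb$rna_breadth, c(0.9, 0, 0))
  # pass-through identity of provided values
  expect_equal(tb$dna_mean_depth, dna$mean_depth)
  expect_equal(tb$dna_read_gc, dna$aligned_read_gc)
  # duplicates and unknown ids error
  expect_error(buildPredictorTable(st, rbind(dna, dna[1, ]), rna), "duplicate")
  expect_error(buildPredictorTable(st, transform(dna, scaffold_id = c("a", "b", "zzz")), rna),
               "unknown")
  expect_equal(scaffoldIds(pt), c("a", "b", "c"))
  expect_equal(rownames(predictorMatrix(pt)), c("a", "b", "c"))
})

test_that("scaffold stats survive a FASTA write/read round trip", {
  sim <- simulateToyAssembly("separable", seed = 5, nTarget = 5, nContam = 5,
                             maxLength = 500)
  st1 <- computeScaffoldStats(sim$fasta)
  seqs <- Biostrings::readDNAStringSet(sim$fasta)
  out2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(seqs, out2)
  st2 <- computeScaffoldStats(out2)
  expect_equal(st1, st2)
})

test_that("predictor table TSV round trip is lossless", {
  sim <- simulatePredictorTable("separable", seed = 3, nTarget = 10, nContam = 5)
  p <- tempfile(fileext = ".tsv")
  writePredictorTable(sim$table, p)
  back <- readPredictorTable(p)
  expect_equal(as.data.frame(back), as.data.frame(sim$table))
})
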