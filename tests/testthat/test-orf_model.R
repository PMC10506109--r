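test_that("GTF coordinates convert to 0-based half-open with stop appended", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, list(
    list(chrom = "chr1", type = "exon", start = 100, end = 200, strand = "+",
         gene = "g1", tx = "tx1", biotype = "protein_coding"),
    list(chrom = "chr1", type = "CDS", start = 130, end = 159, strand = "+",
         gene = "g1", tx = "tx1", biotype = "protein_coding"),
    list(chrom = "chr1", type = "stop_codon", start = 160, end = 162,
         strand = "+", gene = "g1", tx = "tx1", biotype = "protein_coding")))
  txs <- read_transcript_models(gtf)
  expect_equal(txs$tx1$exons, data.frame(start = 99L, end = 200L))
  expect_identical(txs$tx1$cds_tx, c(30L, 63L))
  expect_equal((txs$tx1$cds_tx[2] - txs$tx1$cds_tx[1]) %% 3, 0)
  expect_identical(txs$tx1$biotype, "protein_coding")
})

test_that("GTF reader rejects malformed lines, empty exons, CDS outside exons", {
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\ttest\texon\t100\t200", "short line"), bad)
  expect_error(read_transcript_models(bad), "line 1")

  noexon <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(noexon, list(
    list(chrom = "chr1", type = "CDS", start = 130, end = 162, strand = "+",
         gene = "g1", tx = "txX", biotype = "protein_coding")))
  expect_error(read_transcript_models(noexon), "zero exon")

  outside <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(outside, list(
    list(chrom = "chr1", type = "exon", start = 100, end = 200, strand = "+",
         gene = "g1", tx = "txY", biotype = "protein_coding"),
    list(chrom = "chr1", type = "CDS", start = 250, end = 300, strand = "+",
         gene = "g1", tx = "txY", biotype = "protein_coding")))
  expect_error(read_transcript_models(outside), "txY")
})

test_that("minus-strand transcript coordinate 0 is the rightmost base", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, list(
    list(chrom = "chr1", type = "exon", start = 301, end = 380, strand = "-",
         gene = "g2", tx = "tx2", biotype = "lncRNA"),
    list(chrom = "chr1", type = "exon", start = 501, end = 580, strand = "-",
         gene = "g2", tx = "tx2", biotype = "lncRNA")))
  txs <- read_transcript_models(gtf)
  tx <- txs$tx2
  orf <- tx_orf(tx, 0L, 30L)
  # the 5'-most ORF base sits at the right end of the right exon
  expect_equal(max(orf$blocks$end), 580L)
  expect_identical(to_transcript_coords(orf, tx), c(0L, 30L))
})

test_that("to_transcript_coords maps blocks across exons and rejects introns", {
  tx <- transcript_model("t2", "g", "chr1", "+",
                         data.frame(start = c(0L, 200L), end = c(100L, 300L)))
  orf <- orf_record("o", "t2", "chr1", "+",
                    data.frame(start = c(90L, 200L), end = c(100L, 223L)))
  expect_identical(to_transcript_coords(orf, tx), c(90L, 123L))

  single <- simple_tx("t3", tx_len = 300L, cds = NULL)
  ident <- orf_record("oi", "t3", "chr1", "+",
                      data.frame(start = 30L, end = 63L))
  expect_identical(to_transcript_coords(ident, single), c(30L, 63L))

  intronic <- orf_record("ox", "t2", "chr1", "+",
                         data.frame(start = 150L, end = 180L))
  expect_error(to_transcript_coords(intronic, tx), "outside the exons")
})

test_that("to_transcript_coords is length-preserving and monotone on both strands", {
  for (strand in c("+", "-")) {
    tx <- transcript_model("t", "g", "chr1", strand,
                           data.frame(start = c(0L, 150L, 400L),
                                      end = c(100L, 250L, 520L)))
    set.seed(42)
    prev_start <- -1L
    for (s in sort(sample(0:(tx$tx_length - 30L), 20L))) {
      orf <- tx_orf(tx, s, s + 30L, orf_id = paste0("p", s))
      iv <- to_transcript_coords(orf, tx)
      expect_identical(iv, c(s, s + 30L))
      expect_gt(iv[1], prev_start)
      prev_start <- iv[1]
    }
  }
})

test_that("orf_nt_length excludes the stop codon", {
  expect_identical(orf_nt_length(ivl_orf("a", 0, 36)), 33L)
  # minimal ORF: start codon followed directly by a stop codon
  expect_identical(orf_nt_length(ivl_orf("b", 0, 6)), 3L)
  # 51 nt total = 48 nt = 16 codons, the inclusion-filter boundary
  expect_identical(orf_nt_length(ivl_orf("c", 0, 51)), 48L)
  expect_identical(orf_nt_length(ivl_orf("c", 0, 51)) %/% 3L, 16L)
})

test_that("record-level invariant violations reject with reasons; bad strand aborts", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(orf_id = c("good", "notmod3", "overlap"),
                   transcript_id = "t", chrom = "chr1", strand = "+",
                   block_starts = c("0", "0", "0,10"),
                   block_sizes = c("36", "35", "18,18"),
                   start_codon = "ATG", dataset = "d", caller = "c",
                   replicate = "1", sample = "s")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  orfs <- read_orf_calls(tsv)
  expect_named(orfs, "good")
  rej <- attr(orfs, "rejections")
  expect_setequal(rej$orf_id, c("notmod3", "overlap"))
  expect_match(rej$reason[rej$orf_id == "overlap"], "overlapping blocks")
  expect_match(rej$reason[rej$orf_id == "notmod3"], "divisible by 3")

  df$strand[1] <- "?"
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_orf_calls(tsv), "strand")
})

test_that("TSV round trip is bit-exact for blocks and provenance", {
  set.seed(7)
  orfs <- lapply(1:10, function(i) {
    s <- sample(1000, 1)
    ivl_orf(sprintf("o%02d", i), s, s + 3 * sample(4:30, 1),
            strand = sample(c("+", "-"), 1), dataset = "ds1",
            caller = sample(c("price", "orfquant"), 1),
            replicate = sample(3, 1), sample = "hESC")
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_orf_calls(orfs, f)
  back <- read_orf_calls(f)
  expect_length(back, 10L)
  for (o in orfs) {
    expect_identical(back[[o$orf_id]]$blocks, o$blocks)
    expect_identical(back[[o$orf_id]]$source, o$source)
    expect_identical(back[[o$orf_id]]$stop_codon_pos, o$stop_codon_pos)
  }
})

test_that("BED12 blocks parse into stop-inclusive records", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 100, 160, "borf", 0, "+", 100, 160, "0",
                   2, "18,18", "0,42", sep = "\t"), bed)
  orfs <- read_orf_calls(bed)
  expect_identical(orfs$borf$blocks,
                   data.frame(start = c(100L, 142L), end = c(118L, 160L)))
  expect_identical(orf_nt_length(orfs$borf), 33L)
})

test_that("orf_nt_length is >= 3 and 0 mod 3 for generated records", {
  orfs <- random_orf_set(40, seed = 99)
  lens <- vapply(orfs, orf_nt_length, integer(1))
  expect_true(all(lens >= 3L))
  expect_true(all(lens %% 3L == 0L))
})
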