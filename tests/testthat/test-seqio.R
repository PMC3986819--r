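test_that("fasta parsing normalizes case and U, and round-trips", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1 some description", "acgt", ">t2", "ACGU", "GGN"), p)
  ts <- read_fasta(p)
  expect_equal(ts$id, c("t1", "t2"))
  expect_equal(ts$bases, c("ACGT", "ACGTGGN"))
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(ts, out)
  back <- read_fasta(out)
  expect_equal(back$id, ts$id)
  expect_equal(back$bases, ts$bases)
})

test_that("fasta errors: duplicate ids, empty sequence, bad header", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGT", ">t1", "ACGT"), p)
  expect_error(read_fasta(p), "duplicate")
  writeLines(c(">t1", "", ">t2", "ACGT"), p)
  expect_error(read_fasta(p), "line 1")
  writeLines(c("ACGT"), p)
  expect_error(read_fasta(p), "line 1")
})

test_that("fastq decodes Sanger Phred+33 and flags malformed blocks", {
  p <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "/.II"), p)
  rs <- read_fastq(p, sex = "male", source = "genomic")
  expect_equal(decode_quals(rs$qual)[[1]], c(14L, 13L, 40L, 40L))
  # length mismatch names the quality line's record
  writeLines(c("@r1", "ACGT", "+", "III"), p)
  expect_error(read_fastq(p, "male", "genomic"), "length mismatch at line 2")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), p)
  expect_error(read_fastq(p, "male", "genomic"), "multiple of 4")
  writeLines(c("r1", "ACGT", "+", "IIII"), p)
  expect_error(read_fastq(p, "male", "genomic"), "'@'")
})

test_that("fastq round-trips through write_fastq", {
  rs <- read_set(c("a", "b"), c("ACGTAC", "GGTTAA"),
                 c("IIIIII", "##IIII"), sex = "female", source = "rna")
  p <- withr::local_tempfile(fileext = ".fq")
  write_fastq(rs, p)
  back <- read_fastq(p, "female", "rna")
  expect_equal(back$bases, rs$bases)
  expect_equal(back$qual, rs$qual)
  expect_equal(nrow(back), nrow(rs)) # no silent record drop
})

test_that("write_table is deterministic: sorted rows, fixed decimals", {
  df <- data.frame(id = c("b", "a"), x = c(1 / 3, 2),
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, p)
  lines <- readLines(p)
  expect_equal(lines[1], "id\tx")
  expect_equal(lines[2], "a\t2.000000")
  expect_equal(lines[3], "b\t0.333333")
  # empty input still writes the header
  write_table(df[0, ], p)
  expect_equal(readLines(p), "id\tx")
})

test_that("transcript_set enforces its invariants", {
  expect_error(transcript_set(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(transcript_set("a", ""), "empty")
  expect_error(transcript_set("a", "ACXT"), "non-ACGTN")
  ts <- transcript_set("a", "acgu")
  expect_equal(ts$bases, "ACGT")
  expect_equal(ts$chrom_class, "unknown")
})
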