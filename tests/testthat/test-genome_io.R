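test_that("FASTA parsing normalizes case, maps U to T and odd symbols to N", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGT"), path)
  asm <- read_fasta(path)
  expect_length(asm$records, 1L)
  expect_equal(asm$records[[1L]]$identifier, "chr1")
  expect_equal(asm$records[[1L]]$sequence, "ACGT")
  expect_equal(asm$records[[1L]]$length, 4L)
  expect_equal(asm$total_bases, 4)

  writeLines(c(">a", "acgt", ">b", "TTTT"), path)
  asm <- read_fasta(path)
  expect_equal(vapply(asm$records, `[[`, character(1L), "identifier"),
               c("a", "b"))
  expect_equal(asm$records[[1L]]$sequence, "ACGT")

  writeLines(c(">x", "ACRGT"), path)
  expect_equal(read_fasta(path)$records[[1L]]$sequence, "ACNGT")

  writeLines(c(">rna", "acgu"), path)
  expect_equal(read_fasta(path)$records[[1L]]$sequence, "ACGT")
})

test_that("FASTA parse failures raise distinct named errors", {
  expect_error(read_fasta(file.path(tempdir(), "no-such-file.fa")),
               class = "fasta_missing_file")
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines("ACGT", path)
  expect_error(read_fasta(path), class = "fasta_no_records")
  writeLines(character(0L), path)
  expect_error(read_fasta(path), class = "fasta_no_records")
  writeLines(c(">a", "ACGT", ">empty"), path)
  expect_error(read_fasta(path), class = "fasta_empty_record")
  expect_error(genome_assembly(list(sequence_record("a", "AC"),
                                    sequence_record("a", "GT"))),
               "duplicate")
})

test_that("FASTA round trip preserves identifiers, order and sequences", {
  set.seed(11)
  recs <- lapply(1:5, function(i) {
    sequence_record(paste0("rec", i), random_sequence(sample(40:300, 1L),
                                                      c(BASES, "N")))
  })
  asm <- genome_assembly(recs)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(asm, path, width = 37L)
  back <- read_fasta(path)
  expect_equal(vapply(back$records, `[[`, character(1L), "identifier"),
               vapply(recs, `[[`, character(1L), "identifier"))
  expect_equal(vapply(back$records, `[[`, character(1L), "sequence"),
               vapply(recs, `[[`, character(1L), "sequence"))
})

test_that("gzip-compressed FASTA is detected by magic bytes", {
  plain <- withr::local_tempfile(fileext = ".fasta")
  gz <- withr::local_tempfile(fileext = ".dat")  # extension is irrelevant
  writeLines(c(">z", "ACGTACGT"), plain)
  con <- gzfile(gz, "wb")
  writeChar(">z\nACGTACGT\n", con, eos = NULL)
  close(con)
  expect_equal(read_fasta(gz)$records[[1L]]$sequence,
               read_fasta(plain)$records[[1L]]$sequence)
})

test_that("chunk plans follow the strict 50 MB threshold and cover exactly", {
  p <- plan_chunked_fetch(10485760, 52428800)
  expect_equal(nrow(p$ranges), 1L)
  expect_equal(unname(p$ranges[1L, ]), c(0, 10485760))

  p <- plan_chunked_fetch(125829120, 52428800)
  expect_equal(unname(p$ranges[, "start"]), c(0, 52428800, 104857600))
  expect_equal(unname(p$ranges[, "end"]), c(52428800, 104857600, 125829120))

  # a file of exactly one chunk is NOT split ("larger than" is strict)
  p <- plan_chunked_fetch(52428800, 52428800)
  expect_equal(nrow(p$ranges), 1L)

  expect_error(plan_chunked_fetch(0), "positive")
  expect_error(plan_chunked_fetch(10, 0), "positive")
})

test_that("chunk plans partition [0, total) for random size pairs", {
  set.seed(21)
  for (i in 1:300) {
    total <- sample.int(10^6, 1L)
    chunk <- sample.int(10^5, 1L)
    p <- plan_chunked_fetch(total, chunk)
    r <- p$ranges
    expect_equal(unname(r[1L, "start"]), 0)
    expect_equal(unname(r[nrow(r), "end"]), total)
    if (nrow(r) > 1L) {
      expect_equal(unname(r[-1L, "start"]), unname(r[-nrow(r), "end"]))
      expect_true(all(r[-nrow(r), "end"] - r[-nrow(r), "start"] == chunk))
    }
    expect_true(all(r[, "end"] > r[, "start"]))
  }
})

test_that("merge reassembles portions regardless of arrival order", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample.int(5000, 1L)
    chunk <- sample.int(1200, 1L)
    bytes <- as.raw(sample.int(256, n, replace = TRUE) - 1L)
    plan <- plan_chunked_fetch(n, chunk)
    portions <- split_portions(bytes, plan)
    expect_identical(merge_portions(plan, sample(portions)), bytes)
  }
})

test_that("merge rejects missing, duplicate and short portions", {
  bytes <- as.raw(1:100)
  plan <- plan_chunked_fetch(100, 40)
  portions <- split_portions(bytes, plan)
  expect_error(merge_portions(plan, portions[-2L]), class = "portion_missing")
  expect_error(merge_portions(plan, c(portions, portions[2L])),
               class = "portion_duplicate")
  bad <- portions
  bad[[1L]]$bytes <- bad[[1L]]$bytes[-1L]
  expect_error(merge_portions(plan, bad), class = "portion_length_mismatch")
})

test_that("fetch plans serialize to and from start<TAB>end text", {
  plan <- plan_chunked_fetch(1000, 300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fetch_plan(plan, path)
  expect_equal(readLines(path),
               c("0\t300", "300\t600", "600\t900", "900\t1000"))
  back <- read_fetch_plan(path)
  expect_equal(back$ranges, plan$ranges)
})

test_that("the local file fetcher serves byte ranges and fails loudly", {
  path <- withr::local_tempfile()
  writeBin(as.raw(0:99), path)
  f <- local_file_fetcher(path)
  expect_identical(f("x", 10, 20), as.raw(10:19))
  expect_identical(f("x", 0, 100), as.raw(0:99))
  g <- local_file_fetcher(file.path(tempdir(), "gone.bin"))
  expect_error(g("x", 0, 1), class = "fetch_error")
})
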