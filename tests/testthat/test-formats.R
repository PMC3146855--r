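test_that("paired FASTA/QUAL parsing matches qualities to bases", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  qu <- withr::local_tempfile(fileext = ".qual")
  writeLines(c(">r1 some description", "ACGT"), fa)
  writeLines(c(">r1 some description", "30 30 40 40"), qu)
  reads <- read_fasta_qual(fa, qu)
  expect_equal(reads$read_id, "r1")
  expect_equal(reads$sequence, "ACGT")
  expect_equal(reads$qualities[[1]], c(30L, 30L, 40L, 40L))
})

test_that("quality/sequence length mismatch is a hard error naming the read", {
  fa <- withr::local_tempfile()
  qu <- withr::local_tempfile()
  writeLines(c(">r1", "ACGT"), fa)
  writeLines(c(">r1", "30 30 40"), qu)
  expect_error(read_fasta_qual(fa, qu), "quality length mismatch for r1")
  writeLines(c(">r2", "30 30 40 40"), qu)
  expect_error(read_fasta_qual(fa, qu), "identifier mismatch")
})

test_that("wrapped records round-trip losslessly", {
  set.seed(11)
  seqs <- vapply(c(150, 201), random_dna, character(1))
  reads <- read_set(c("a1", "a2"), seqs,
                    lapply(nchar(seqs), function(n)
                      sample(0:40, n, replace = TRUE)))
  fa <- withr::local_tempfile()
  qu <- withr::local_tempfile()
  write_fasta_qual(reads, fa, qu, width = 60)
  # wrapped at 60 columns
  expect_true(all(nchar(readLines(fa)) <= 61))
  back <- read_fasta_qual(fa, qu)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$qualities, reads$qualities)
})

test_that("primer & barcode file parsing aggregates and validates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("amplicon_id", "sample_id", "barcode", "forward_primer",
               "reverse_primer", "adapter_b", "min_len", "max_len",
               sep = "\t")
  writeLines(c(hdr,
               "amp1\ts1\tACGT\tGGCA\tTTGC\tCTGAG\t100\t400",
               "amp1\ts2\tTGCA\tGGCA\tTTGC\tCTGAG\t100\t400"), tsv)
  specs <- parse_primer_barcode_file(tsv)
  expect_length(specs, 1)
  expect_equal(specs[[1]]$barcode_map, c(s1 = "ACGT", s2 = "TGCA"))
  expect_equal(specs[[1]]$min_len, 100L)

  writeLines(c(hdr,
               "amp1\ts1\tAC\tGGCA\tTTGC\tCTGAG\t100\t400",
               "amp1\ts2\tACGT\tGGCA\tTTGC\tCTGAG\t100\t400"), tsv)
  expect_error(parse_primer_barcode_file(tsv), "prefix conflict")

  writeLines(c(hdr, "amp1\ts1\tACGT\tGGCA\tTTGC\tCTGAG\t500\t400"), tsv)
  expect_error(parse_primer_barcode_file(tsv), "min_len > max_len at row 1")

  writeLines(c(hdr,
               "amp1\ts1\tACGT\tGGCA\tTTGC\tCTGAG\t100\t400",
               "amp1\ts1\tTGCA\tGGCA\tTTGC\tCTGAG\t100\t400"), tsv)
  expect_error(parse_primer_barcode_file(tsv), "duplicate")
})

test_that("sample info typing: numeric columns, categorical fallback, NA", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttemperature\tpH\tdepth_class",
               "s1\t15\t7.2\t10-20",
               "s2\t8\t\t0-10"), tsv)
  si <- parse_sample_info_file(tsv)
  expect_equal(si$temperature, c(15, 8))
  expect_equal(si$pH, c(7.2, NA))
  expect_identical(si$depth_class, c("10-20", "0-10"))

  writeLines(c("sample_id\tx", "s1\t1", "s1\t2"), tsv)
  expect_error(parse_sample_info_file(tsv), "duplicate sample_id")
})

test_that("frequency FASTA dialect and round trip", {
  uniq <- data.frame(sequence = c("ACGT", "ACGA"), frequency = c(5L, 1L))
  fa <- withr::local_tempfile()
  write_fasta_with_frequency(uniq, fa)
  expect_equal(readLines(fa),
               c(">seq1_freq=5", "ACGT", ">seq2_freq=1", "ACGA"))
  back <- read_fasta_with_frequency(fa)
  expect_equal(back$sequence, uniq$sequence)
  expect_equal(back$frequency, uniq$frequency)

  write_fasta_with_frequency(uniq[0, ], fa)
  expect_equal(readLines(fa), character(0))
})

test_that("log file is chained, greppable, and parseable", {
  sim <- generate_dataset(n_reads = 120, n_samples = 3, n_templates = 8,
                          seed = 3)
  res <- run_pipeline(sim$reads, sim$specs, sim$sample_info)
  log <- withr::local_tempfile(fileext = ".log")
  write_log(res$logs, unclass(res$config), log)
  lines <- readLines(log)
  expect_true(any(grepl("^TIMESTAMP: ", lines)))
  expect_true(any(grepl("^PARAM quality_threshold: 25$", lines)))
  parsed <- read_log(log)
  expect_equal(nrow(parsed), 7)
  # counts chain and match the in-memory logs, including discarded ids
  for (i in seq_len(7)) {
    expect_equal(parsed$n_in[i], res$logs[[i]]$n_in)
    expect_equal(parsed$n_discarded[i], res$logs[[i]]$n_discarded)
    expect_setequal(parsed$discarded_ids[[i]], res$logs[[i]]$discarded_ids)
    if (i > 1) expect_equal(parsed$n_in[i], parsed$n_kept[i - 1])
  }
  # recount oracle: kept count of last step equals emitted read count
  expect_equal(parsed$n_kept[7], nrow(res$reads))
})
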