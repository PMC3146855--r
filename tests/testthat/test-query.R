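test_that("metadata range filter selects exactly the qualifying samples", {
  fx <- mk_store_fixture(seed = 41)
  on.exit(ads_disconnect(fx$store))
  # generator plants temperatures 8, 15, 25 for s1..s3
  sel <- select_sequences(fx$store,
    query_filter(datasets = fx$d1, ranges = list(temperature = c(10, 20))))
  expect_gt(nrow(sel), 0)
  expect_true(all(sel$sample_id == "s2"))
  # bounds are inclusive
  sel15 <- select_sequences(fx$store,
    query_filter(datasets = fx$d1, ranges = list(temperature = c(15, 15))))
  expect_equal(sort(unique(sel15$sample_id)), "s2")
  # categorical equality
  selc <- select_sequences(fx$store,
    query_filter(datasets = fx$d1, ranges = list(site = "lake")))
  expect_true(all(selc$sample_id %in%
                    fx$sim1$sample_info$sample_id[
                      fx$sim1$sample_info$site == "lake"]))
  # range on a categorical variable errors, naming it
  expect_error(select_sequences(fx$store,
    query_filter(ranges = list(site = c(1, 2)))), "site")
})

test_that("empty filter returns every stored non-redundant row", {
  fx <- mk_store_fixture(seed = 42)
  on.exit(ads_disconnect(fx$store))
  sel <- select_sequences(fx$store)
  n_expected <- DBI::dbGetQuery(fx$store$con,
    "SELECT COUNT(*) AS n FROM nonredundant_sample")$n
  expect_equal(nrow(sel), n_expected)
  # deterministic ordering: dataset, frequency desc, sequence
  for (d in unique(sel$dataset_id)) {
    sub <- sel[sel$dataset_id == d, ]
    expect_true(all(diff(sub$frequency) <= 0 |
                      diff(sub$frequency) == 0))
    o <- order(-sub$frequency, sub$sequence)
    expect_equal(sub$sequence, sub$sequence[o])
  }
})

test_that("filters are AND-monotone", {
  fx <- mk_store_fixture(seed = 43)
  on.exit(ads_disconnect(fx$store))
  base <- select_sequences(fx$store)
  narrower <- list(
    query_filter(datasets = fx$d1),
    query_filter(datasets = fx$d1, samples = "s1"),
    query_filter(datasets = fx$d1, samples = "s1",
                 ranges = list(temperature = c(0, 100))),
    query_filter(datasets = fx$d1, samples = "s1", primers = "amp1"))
  prev <- nrow(base)
  for (f in narrower) {
    n <- nrow(select_sequences(fx$store, f))
    expect_lte(n, prev)
  }
  # each filtered result is a subset of the unfiltered one
  sub <- select_sequences(fx$store, narrower[[2]])
  key <- function(x) paste(x$dataset_id, x$sample_id, x$sequence)
  expect_true(all(key(sub) %in% key(base)))
})

test_that("taxon filter matches effective path case-insensitively", {
  fx <- mk_store_fixture(seed = 44)
  on.exit(ads_disconnect(fx$store))
  seqs <- fx$res1$derep$pooled$sequence
  set_assigned_taxonomy(fx$store, fx$d1,
    data.frame(sequence = seqs[1], path = "Eukaryota;Chlorophyta;X"))
  set_assigned_taxonomy(fx$store, fx$d1,
    data.frame(sequence = seqs[2], path = "Eukaryota;Ciliophora;Y"))
  sel <- select_sequences(fx$store,
                          query_filter(datasets = fx$d1,
                                       taxon = "chlorophyta"))
  expect_true(all(sel$sequence == seqs[1]))
  expect_gt(nrow(sel), 0)
  # substring-scan oracle over the full selection
  all_rows <- select_sequences(fx$store, query_filter(datasets = fx$d1))
  expect_equal(nrow(sel),
               sum(grepl("chlorophyta", tolower(all_rows$taxonomy))))
  # the edited path takes precedence when present
  set_edited_taxonomy(fx$store, fx$d1, seqs[1], "Bacteria;Z", "e")
  sel2 <- select_sequences(fx$store,
                           query_filter(datasets = fx$d1,
                                        taxon = "chlorophyta"))
  expect_equal(nrow(sel2), 0)
})

test_that("random subsampling is seeded, bounded, without replacement", {
  fx <- mk_store_fixture(seed = 45)
  on.exit(ads_disconnect(fx$store))
  filt <- query_filter(datasets = fx$d1)
  pool <- ampliconDB:::read_pool(fx$store, filt)
  N <- nrow(pool)
  expect_equal(nrow(random_subsample(fx$store, filt, 0, seed = 1)), 0)
  # n = pool size returns the whole pool as a multiset
  all_draw <- random_subsample(fx$store, filt, N, seed = 1)
  expect_setequal(all_draw$read_id, pool$read_id)
  # reproducible under a fixed seed, different under another
  a <- random_subsample(fx$store, filt, 10, seed = 99)
  b <- random_subsample(fx$store, filt, 10, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$read_id %in% pool$read_id))
  expect_equal(anyDuplicated(a$read_id), 0)
  expect_error(random_subsample(fx$store, filt, N + 1, seed = 1),
               "only")
})

test_that("sequence abundance reconciles with dereplication links", {
  fx <- mk_store_fixture(seed = 46)
  on.exit(ads_disconnect(fx$store))
  pooled <- fx$res1$derep$pooled
  top <- pooled$sequence[1]
  ab <- sequence_abundance(fx$store, top, query_filter(datasets = fx$d1))
  expect_equal(sum(ab$count), pooled$frequency[1])
  links <- fx$res1$derep$links
  want <- links[links$rank == 1, ]
  expect_equal(ab$count[match(want$sample_id, ab$sample_id)],
               want$frequency)
  # filter restricted to one sample
  s <- ab$sample_id[1]
  ab1 <- sequence_abundance(fx$store, top,
                            query_filter(datasets = fx$d1, samples = s))
  expect_equal(ab1$sample_id, s)
  expect_equal(ab1$count, ab$count[ab$sample_id == s])
  # unknown sequence: empty mapping, not an error
  expect_equal(nrow(sequence_abundance(fx$store, "TTTTTTTT")), 0)
})

test_that("export round-trips and stays byte-stable", {
  fx <- mk_store_fixture(seed = 47)
  on.exit(ads_disconnect(fx$store))
  sel <- select_sequences(fx$store, query_filter(datasets = fx$d1,
                                                 samples = "s1"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  export_results(sel, fa, "fasta")
  back <- read_fasta_with_frequency(fa)
  expect_equal(sort(paste(back$sequence, back$frequency)),
               sort(paste(sel$sequence, sel$frequency)))
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  export_results(sel, fa2, "fasta")
  expect_identical(readLines(fa), readLines(fa2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_results(sel, tsv, "tsv")
  lines <- readLines(tsv)
  expect_equal(length(lines), nrow(sel) + 1)
  expect_equal(length(unique(lengths(strsplit(lines, "\t")))), 1)
  # empty selection still yields a valid (empty) FASTA
  export_results(sel[0, ], fa, "fasta")
  expect_equal(readLines(fa), character(0))
  expect_error(export_results(sel, fa, "xlsx"), "unknown export format")
})
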