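test_that("upload persists statistics that match the in-memory run", {
  fx <- mk_store_fixture(seed = 31)
  on.exit(ads_disconnect(fx$store))
  st <- summary_statistics(fx$store, fx$d1)
  logs <- fx$res1$logs
  expect_equal(nrow(st), 8)   # 7 steps + totals row
  expect_equal(st$n_considered[1:7],
               vapply(logs, `[[`, numeric(1), "n_in"))
  expect_equal(st$n_discarded[1:7],
               vapply(logs, `[[`, numeric(1), "n_discarded"))
  expect_equal(st$n_considered[8], logs[[1]]$n_in)
  expect_equal(st$n_discarded[8],
               sum(vapply(logs, `[[`, numeric(1), "n_discarded")))
  expect_equal(attr(st, "retained"), logs[[7]]$n_kept)
  # stored step logs reproduce the discarded identities
  slog <- get_step_logs(fx$store, fx$d1)
  for (i in 1:7)
    expect_setequal(slog[[i]]$discarded_ids, logs[[i]]$discarded_ids)
  audit_store(fx$store)
})

test_that("datasets are isolated and raw reads round-trip", {
  fx <- mk_store_fixture(seed = 32)
  on.exit(ads_disconnect(fx$store))
  r1 <- get_raw_reads(fx$store, fx$d1)
  expect_equal(r1$read_id, fx$sim1$reads$read_id)
  expect_equal(r1$sequence, fx$sim1$reads$sequence)
  expect_equal(r1$qualities, fx$sim1$reads$qualities)
  sel1 <- select_sequences(fx$store, query_filter(datasets = fx$d1))
  expect_true(all(sel1$dataset_id == fx$d1))
  # no cross-dataset leakage
  sel2 <- select_sequences(fx$store, query_filter(datasets = fx$d2))
  expect_true(all(sel2$dataset_id == fx$d2))
})

test_that("failed upload persists nothing (atomicity)", {
  store <- ads_connect(":memory:")
  on.exit(ads_disconnect(store))
  sim <- generate_dataset(n_reads = 50, n_samples = 3, n_templates = 6,
                          seed = 33)
  before <- DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM data_upload_summary")$n
  bad_si <- sim$sample_info[-1, ]
  class(bad_si) <- c("sample_info", "data.frame")
  expect_error(upload_dataset(store, sim$reads, sim$specs, bad_si))
  after <- DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM data_upload_summary")$n
  expect_equal(before, after)
  for (tab in c("raw_reads", "statistics", "nonredundant_pooled"))
    expect_equal(DBI::dbGetQuery(store$con,
      paste0("SELECT COUNT(*) AS n FROM ", tab))$n, 0)
})

test_that("delete_dataset restores the pre-upload state, twice errors", {
  fx <- mk_store_fixture(seed = 34)
  on.exit(ads_disconnect(fx$store))
  counts <- function() vapply(ampliconDB:::per_dataset_tables(),
    function(t) DBI::dbGetQuery(fx$store$con,
      paste0("SELECT COUNT(*) AS n FROM ", t))$n, numeric(1))
  before <- counts()
  sim <- generate_dataset(n_reads = 60, n_samples = 3, n_templates = 6,
                          seed = 35)
  d3 <- upload_dataset(fx$store, sim$reads, sim$specs, sim$sample_info)
  expect_gt(sum(counts()), sum(before))
  delete_dataset(fx$store, d3)
  expect_equal(counts(), before)
  expect_error(delete_dataset(fx$store, d3), "unknown dataset_id")
  # the sibling dataset is fully intact
  expect_equal(nrow(get_raw_reads(fx$store, fx$d1)), 150)
  audit_store(fx$store)
})

test_that("combining runs rescues variants split across datasets", {
  store <- ads_connect(":memory:")
  on.exit(ads_disconnect(store))
  spec <- mk_spec(forward_primer = "ACGTC", reverse_primer = "TGGCA",
                  adapter_b = "CTGAG", min_len = 5, max_len = 500,
                  barcode_map = c(s1 = "AACC", s2 = "GGTT"))
  si <- mk_sample_info(c("s1", "s2"), temperature = c(10, 20))
  core <- function(bc, insert) paste0(bc, "ACGTC", insert,
                                      revcomp("TGGCA"), "CTGAG")
  insX <- "CATCATCATCAT"
  filler <- "GATTACAGATTACA"
  # run A: X once in s1 (singleton there); run B: X once in s2
  mk <- function(bc1, ids) mk_reads(c(core(bc1, insX),
                                      core("AACC", filler),
                                      core("GGTT", filler)), ids = ids)
  cfg <- pipeline_config(quality_threshold = 0)
  dA <- upload_dataset(store, mk("AACC", c("x1", "f1", "f2")),
                       list(spec), si, cfg, "runA")
  dB <- upload_dataset(store, mk("GGTT", c("x2", "f3", "f4")),
                       list(spec), si, cfg, "runB")
  # X is a single-sample singleton in each run alone
  expect_false(insX %in% attr(dA, "result")$derep$pooled$sequence)
  expect_false(insX %in% attr(dB, "result")$derep$pooled$sequence)
  dC <- combine_and_reprocess(store, c(dA, dB), list(spec), cfg)
  res <- attr(dC, "result")
  expect_true(insX %in% res$derep$pooled$sequence)
  # sources untouched
  expect_equal(nrow(get_raw_reads(store, dA)), 3)
  # combining a dataset with an identical second upload doubles frequencies
  dA2 <- upload_dataset(store, mk("AACC", c("x1", "f1", "f2")),
                        list(spec), si, cfg, "runA-copy")
  dD <- combine_and_reprocess(store, c(dA, dA2), list(spec), cfg)
  resD <- attr(dD, "result")
  fX <- resD$derep$pooled
  expect_equal(fX$frequency[fX$sequence == filler], 4L)
  # combine([d]) reproduces d's non-redundant set
  dE <- combine_and_reprocess(store, dA, list(spec), cfg)
  expect_equal(attr(dE, "result")$derep$pooled[c("sequence", "frequency")],
               attr(dA, "result")$derep$pooled[c("sequence", "frequency")])
  expect_error(combine_and_reprocess(store, 999, list(spec), cfg),
               "unknown dataset_id")
})

test_that("sample metadata edits are visible to range queries", {
  fx <- mk_store_fixture(seed = 36)
  on.exit(ads_disconnect(fx$store))
  update_sample_info(fx$store, fx$d1, "s1", "temperature", 12)
  sel <- select_sequences(fx$store,
    query_filter(datasets = fx$d1, ranges = list(temperature = c(10, 20))))
  expect_true("s1" %in% sel$sample_id)
  update_sample_info(fx$store, fx$d1, "s1", "temperature", NULL)
  sel <- select_sequences(fx$store,
    query_filter(datasets = fx$d1, ranges = list(temperature = c(10, 20))))
  expect_false("s1" %in% sel$sample_id)
  expect_error(update_sample_info(fx$store, fx$d1, "nope", "x", 1),
               "unknown sample")
})

test_that("taxonomy edits never overwrite the automatic assignment", {
  fx <- mk_store_fixture(seed = 37)
  on.exit(ads_disconnect(fx$store))
  seq1 <- fx$res1$derep$pooled$sequence[1]
  set_assigned_taxonomy(fx$store, fx$d1,
                        data.frame(sequence = seq1,
                                   path = "Eukaryota;Chlorophyta;Chlorella"))
  set_edited_taxonomy(fx$store, fx$d1, seq1,
                      "Eukaryota;Chlorophyta;Parachlorella", "expert1")
  tx <- get_taxonomy(fx$store, fx$d1, seq1)
  expect_equal(tx$assigned_path, "Eukaryota;Chlorophyta;Chlorella")
  expect_equal(tx$edited_path, "Eukaryota;Chlorophyta;Parachlorella")
  expect_equal(tx$edit_editor, "expert1")
  # a second edit replaces only the edited path
  set_edited_taxonomy(fx$store, fx$d1, seq1, "Eukaryota;unknown", "expert2")
  tx <- get_taxonomy(fx$store, fx$d1, seq1)
  expect_equal(tx$assigned_path, "Eukaryota;Chlorophyta;Chlorella")
  expect_equal(tx$edited_path, "Eukaryota;unknown")
  # automatic re-assignment leaves the edit alone
  set_assigned_taxonomy(fx$store, fx$d1,
                        data.frame(sequence = seq1, path = "Bacteria"))
  tx <- get_taxonomy(fx$store, fx$d1, seq1)
  expect_equal(tx$assigned_path, "Bacteria")
  expect_equal(tx$edited_path, "Eukaryota;unknown")
  expect_error(set_edited_taxonomy(fx$store, fx$d1, "NOTASEQ", "x"),
               "unknown sequence")
})

test_that("an empty dataset still yields a well-formed report", {
  store <- ads_connect(":memory:")
  on.exit(ads_disconnect(store))
  sim <- generate_dataset(n_reads = 30, n_samples = 2, n_templates = 5,
                          defect_rates = list(adapter_missing = 1,
                                              adapter_mutated = 0,
                                              adapter_truncated = 0),
                          seed = 38)
  d <- upload_dataset(store, sim$reads, sim$specs, sim$sample_info)
  st <- summary_statistics(store, d)
  expect_equal(attr(st, "retained"), 0L)
  expect_equal(st$n_discarded[8], 30)
  expect_equal(nrow(select_sequences(store)), 0)
})
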