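mk_hits <- function(...) {
  rows <- list(...)
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- ampliconDB:::hit_columns
  for (col in names(tab)[-(1:2)]) tab[[col]] <- as.numeric(tab[[col]])
  tab
}

hit_row <- function(q, s, evalue, bits, ident = 97) {
  c(q, s, ident, 150, 3, 0, 1, 150, 1, 150, evalue, bits)
}

test_that("best hit wins by e-value, then bit score, then subject id", {
  lm <- c(sub1 = "Eukaryota;A", sub2 = "Eukaryota;B", sub3 = "Eukaryota;C")
  queries <- data.frame(query_id = c("q1", "q2", "q3"),
                        sequence = c("AAAA", "CCCC", "GGGG"))
  hits <- mk_hits(hit_row("q1", "sub2", 1e-10, 180),
                  hit_row("q1", "sub1", 1e-50, 120),
                  hit_row("q2", "sub1", 1e-30, 180),
                  hit_row("q2", "sub2", 1e-30, 200),
                  hit_row("q3", "sub3", 1e-5, 100),
                  hit_row("q3", "sub2", 1e-5, 100))
  out <- assign_taxonomic_path(hits, lm, queries)
  expect_equal(names(out), c("query_id", "query_sequence", "path"))
  expect_equal(out$path, c("Eukaryota;A",   # lowest e-value
                           "Eukaryota;B",   # tie: highest bit score
                           "Eukaryota;B"))  # tie: lexicographic subject
})

test_that("assignment is invariant to hit-file row order", {
  set.seed(1)
  lm <- setNames(paste0("path;", letters[1:6]), paste0("s", 1:6))
  queries <- data.frame(query_id = paste0("q", 1:4),
                        sequence = replicate(4, random_dna(8)))
  rows <- list()
  for (q in queries$query_id)
    for (s in sample(names(lm), 4))
      rows[[length(rows) + 1]] <-
        hit_row(q, s, 10^-sample(5:40, 1), sample(80:200, 1))
  hits <- do.call(mk_hits, rows)
  ref <- assign_taxonomic_path(hits, lm, queries)
  for (i in 1:5) {
    perm <- hits[sample(nrow(hits)), ]
    expect_equal(assign_taxonomic_path(perm, lm, queries), ref)
  }
  expect_equal(nrow(ref), nrow(queries))
})

test_that("no-hit and unknown-subject queries are labeled", {
  lm <- c(sub1 = "Eukaryota;A")
  queries <- data.frame(query_id = c("q1", "q2", "q3"),
                        sequence = c("AAAA", "CCCC", "GGGG"))
  hits <- mk_hits(hit_row("q1", "sub1", 1e-20, 100),
                  hit_row("q3", "subX", 1e-20, 100))
  out <- assign_taxonomic_path(hits, lm, queries)
  expect_equal(out$path, c("Eukaryota;A", "no_hit", "unknown"))
})

test_that("optional cutoffs drop weak hits before selection", {
  lm <- c(sub1 = "A", sub2 = "B")
  queries <- data.frame(query_id = "q1", sequence = "AAAA")
  hits <- mk_hits(hit_row("q1", "sub1", 1e-50, 200, ident = 80),
                  hit_row("q1", "sub2", 1e-10, 100, ident = 99))
  expect_equal(assign_taxonomic_path(hits, lm, queries)$path, "A")
  expect_equal(assign_taxonomic_path(hits, lm, queries,
                                     min_identity = 90)$path, "B")
  expect_equal(assign_taxonomic_path(hits, lm, queries,
                                     max_evalue = 1e-60)$path, "no_hit")
})

test_that("hit table and lineage map readers validate input", {
  f <- withr::local_tempfile()
  writeLines(c("q1\tsub1\t97.5\t150\t3\t0\t1\t150\t1\t150\t1e-50\t200",
               "q2\tsub2\t99.0\t120\t1\t0\t1\t120\t1\t120\t1e-20\t180"), f)
  hits <- read_hit_table(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$evalue, c(1e-50, 1e-20))
  writeLines("q1\tsub1\tbroken", f)
  expect_error(read_hit_table(f), "line 1")
  writeLines(c("q1\tsub1\t97.5\t150\t3\t0\t1\t150\t1\t150\t1e-50\t200",
               "q2\tsub2\tNOTNUM\t120\t1\t0\t1\t120\t1\t120\t1e-20\t180"),
             f)
  expect_error(read_hit_table(f), "line 2")

  lm_file <- withr::local_tempfile()
  writeLines(c("sub1\tEukaryota;A", "sub2\tEukaryota;B"), lm_file)
  lm <- read_lineage_map(lm_file)
  expect_equal(lm[["sub1"]], "Eukaryota;A")
  writeLines(c("sub1\t"), lm_file)
  expect_error(read_lineage_map(lm_file), "empty taxonomic path")
})

test_that("three-column report writes and is stable", {
  lm <- c(sub1 = "Eukaryota;A")
  queries <- data.frame(query_id = "q1", sequence = "ACGT")
  out <- assign_taxonomic_path(mk_hits(hit_row("q1", "sub1", 1e-9, 50)),
                               lm, queries)
  f <- withr::local_tempfile()
  write_taxonomy_table(out, f)
  expect_equal(readLines(f),
               c("query_id\tquery_sequence\tpath",
                 "q1\tACGT\tEukaryota;A"))
})
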