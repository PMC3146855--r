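# in-code fixture builders shared across test files

mk_reads <- function(seqs, ids = sprintf("r%02d", seq_along(seqs)),
                     qual = 30L, samples = NA_character_) {
  quals <- lapply(nchar(seqs), function(n) rep(as.integer(qual), n))
  read_set(ids, seqs, quals, sample_id = samples)
}

mk_spec <- function(amplicon_id = "amp1",
                    forward_primer = "GGCAA",
                    reverse_primer = "TTGC",
                    adapter_b = "CTGAG",
                    min_len = 1L, max_len = 10000L,
                    barcode_map = c(s1 = "ACGT", s2 = "TGCA")) {
  structure(list(amplicon_id = amplicon_id,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 adapter_b = adapter_b,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 barcode_map = barcode_map,
                 sample_ids = if (length(barcode_map))
                   names(barcode_map) else "s1"),
            class = "primer_barcode_spec")
}

mk_sample_info <- function(sample_ids, temperature = NULL, ...) {
  df <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(temperature)) df$temperature <- temperature
  extra <- list(...)
  for (v in names(extra)) df[[v]] <- extra[[v]]
  class(df) <- c("sample_info", "data.frame")
  df
}

# a small stored two-dataset fixture used by datastore/query tests
mk_store_fixture <- function(seed = 7L) {
  store <- ads_connect(":memory:")
  sim1 <- generate_dataset(n_reads = 150, n_samples = 3,
                           n_templates = 8, seed = seed)
  sim2 <- generate_dataset(n_reads = 120, n_samples = 3,
                           n_templates = 8, seed = seed + 1L)
  d1 <- upload_dataset(store, sim1$reads, sim1$specs, sim1$sample_info,
                       name = "run1")
  d2 <- upload_dataset(store, sim2$reads, sim2$specs, sim2$sample_info,
                       name = "run2")
  list(store = store, d1 = as.integer(d1), d2 = as.integer(d2),
       sim1 = sim1, sim2 = sim2,
       res1 = attr(d1, "result"), res2 = attr(d2, "result"))
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
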