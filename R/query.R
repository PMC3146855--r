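#' Build a six-axis query filter
#'
#' Sequences can be retrieved by any combination of (1) datasets,
#' (2) PCR primer / amplicon ids, (3) sample ids, (4) ranges or values of
#' the external sample variables, (5) taxonomic group, and (6) a random
#' sample size. Axes combine by AND; within `ranges` a sample qualifies
#' only if it satisfies every listed constraint.
#'
#' @param datasets integer vector of dataset ids (`NULL` = all).
#' @param primers character vector of amplicon ids (`NULL` = all).
#' @param samples character vector of sample ids (`NULL` = all).
#' @param ranges named list: a numeric length-2 element `c(min, max)`
#'   restricts a numeric variable to the inclusive range; a length-1
#'   element requires equality (used for categorical variables).
#' @param taxon case-insensitive substring matched against the effective
#'   taxonomic path (the edited path when present, else the assigned one).
#' @param sample_size,seed optional random-subsample request, used by
#'   [random_subsample()].
#' @return a list of class `query_filter`.
#' @export
query_filter <- function(datasets = NULL, primers = NULL, samples = NULL,
                         ranges = list(), taxon = NULL,
                         sample_size = NULL, seed = NULL) {
  for (v in names(ranges)) {
    r <- ranges[[v]]
    if (is.numeric(r) && length(r) == 2 && r[1] > r[2])
      stop("min > max in range for variable '", v, "'")
  }
  if (!is.null(sample_size) && sample_size < 0)
    stop("sample_size must be >= 0")
  structure(list(datasets = datasets, primers = primers,
                 samples = samples, ranges = ranges, taxon = taxon,
                 sample_size = sample_size, seed = seed),
            class = "query_filter")
}

# sample ids (per dataset) admitted by the metadata-range axis
samples_matching_ranges <- function(store, dataset_ids, ranges) {
  si <- DBI::dbGetQuery(store$con, paste0(
    "SELECT dataset_id, sample_id, variable, value_num, value_chr
     FROM sample_info WHERE dataset_id IN (",
    paste(dataset_ids, collapse = ","), ")"))
  all_pairs <- unique(DBI::dbGetQuery(store$con, paste0(
    "SELECT dataset_id, sample_id FROM primer_barcode_info
     WHERE dataset_id IN (", paste(dataset_ids, collapse = ","), ")")))
  ok <- rep(TRUE, nrow(all_pairs))
  for (v in names(ranges)) {
    r <- ranges[[v]]
    sub <- si[si$variable == v, ]
    key <- paste(all_pairs$dataset_id, all_pairs$sample_id)
    skey <- paste(sub$dataset_id, sub$sample_id)
    m <- match(key, skey)
    if (is.numeric(r) && length(r) == 2) {
      if (nrow(sub) && any(!is.na(sub$value_chr)))
        stop("range filter on categorical variable '", v, "'")
      val <- sub$value_num[m]
      ok <- ok & !is.na(val) & val >= r[1] & val <= r[2]
    } else {
      val_chr <- sub$value_chr[m]
      val_num <- sub$value_num[m]
      want <- as.character(r[1])
      want_num <- suppressWarnings(as.numeric(want))
      ok <- ok & ((!is.na(val_chr) & val_chr == want) |
                    (!is.na(val_num) & !is.na(want_num) &
                       val_num == want_num))
    }
  }
  all_pairs[ok, , drop = FALSE]
}

filter_dataset_ids <- function(store, filter) {
  ids <- DBI::dbGetQuery(store$con,
    "SELECT dataset_id FROM data_upload_summary")$dataset_id
  if (!is.null(filter$datasets)) ids <- intersect(ids, filter$datasets)
  ids
}

effective_path_sql <- paste(
  "CASE WHEN p.edited_path IS NOT NULL THEN p.edited_path",
  "ELSE p.assigned_path END")

#' Retrieve stored sequences matching a filter
#'
#' Applies the filter axes conjunctively over the per-sample
#' non-redundant relation and returns one row per (dataset, sample,
#' sequence) with its per-sample frequency and effective taxonomy, in the
#' deterministic order (dataset, frequency descending, sequence).
#'
#' @param store an `amplicon_store`.
#' @param filter a [query_filter()].
#' @return data frame with columns `dataset_id`, `sample_id`,
#'   `amplicon_id`, `sequence`, `frequency`, `taxonomy`.
#' @export
select_sequences <- function(store, filter = query_filter()) {
  ids <- filter_dataset_ids(store, filter)
  empty <- data.frame(dataset_id = integer(0), sample_id = character(0),
                      amplicon_id = character(0), sequence = character(0),
                      frequency = integer(0), taxonomy = character(0),
                      stringsAsFactors = FALSE)
  if (!length(ids)) return(empty)
  tab <- DBI::dbGetQuery(store$con, paste0(
    "SELECT s.dataset_id, s.sample_id, s.amplicon_id, s.sequence,
            s.frequency, ", effective_path_sql, " AS taxonomy
     FROM nonredundant_sample s
     LEFT JOIN nonredundant_pooled p
       ON p.dataset_id = s.dataset_id AND p.sequence = s.sequence
     WHERE s.dataset_id IN (", paste(ids, collapse = ","), ")"))
  tab <- apply_row_filters(tab, store, ids, filter)
  tab <- tab[order(tab$dataset_id, -tab$frequency, tab$sequence), ]
  rownames(tab) <- NULL
  tab
}

apply_row_filters <- function(tab, store, ids, filter) {
  if (!is.null(filter$primers))
    tab <- tab[tab$amplicon_id %in% filter$primers, , drop = FALSE]
  if (!is.null(filter$samples))
    tab <- tab[tab$sample_id %in% filter$samples, , drop = FALSE]
  if (length(filter$ranges)) {
    adm <- samples_matching_ranges(store, ids, filter$ranges)
    tab <- tab[paste(tab$dataset_id, tab$sample_id) %in%
                 paste(adm$dataset_id, adm$sample_id), , drop = FALSE]
  }
  if (!is.null(filter$taxon)) {
    path <- tab$taxonomy
    hit <- !is.na(path) &
      grepl(tolower(filter$taxon), tolower(path), fixed = TRUE)
    tab <- tab[hit, , drop = FALSE]
  }
  tab
}

#' Draw a reproducible random subsample of reads
#'
#' Draws `n` reads without replacement from the redundant (per-read) pool
#' matching the filter -- i.e. frequencies are expanded so that an
#' abundant variant is proportionally more likely to be drawn, as
#' rarefaction-style analyses require. The same seed yields the identical
#' draw.
#'
#' @param store an `amplicon_store`.
#' @param filter a [query_filter()].
#' @param n number of reads to draw; larger than the matching pool is an
#'   error, not a truncation.
#' @param seed integer seed (defaults to the filter's).
#' @return data frame with one row per drawn read: `dataset_id`,
#'   `read_id`, `sample_id`, `amplicon_id`, `sequence`.
#' @export
random_subsample <- function(store, filter = query_filter(), n,
                             seed = filter$seed) {
  stopifnot(n >= 0)
  pool <- read_pool(store, filter)
  if (n > nrow(pool))
    stop("requested subsample of ", n, " reads but only ", nrow(pool),
         " match the filter")
  idx <- if (is.null(seed)) sample.int(nrow(pool), n)
         else run_with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-read pool matching a filter, in deterministic order
read_pool <- function(store, filter) {
  ids <- filter_dataset_ids(store, filter)
  if (!length(ids))
    return(data.frame(dataset_id = integer(0), read_id = character(0),
                      sample_id = character(0), amplicon_id = character(0),
                      sequence = character(0)))
  tab <- DBI::dbGetQuery(store$con, paste0(
    "SELECT r.dataset_id, r.read_id, r.sample_id, r.amplicon_id,
            r.sequence, ", effective_path_sql, " AS taxonomy
     FROM redundant_sequences r
     LEFT JOIN nonredundant_pooled p
       ON p.dataset_id = r.dataset_id AND p.sequence = r.sequence
     WHERE r.dataset_id IN (", paste(ids, collapse = ","), ")
     ORDER BY r.dataset_id, r.read_id"))
  tab <- apply_row_filters(tab, store, ids, filter)
  tab$taxonomy <- NULL
  rownames(tab) <- NULL
  tab
}

#' Per-sample abundance of one sequence
#'
#' Reports how often an exact sequence string occurs in each (dataset,
#' sample) within the filtered scope -- the abundance-of-hits view that
#' reveals abundance and turnover of a variant among samples. Absent
#' combinations mean zero.
#'
#' @param store an `amplicon_store`.
#' @param sequence exact (trimmed) sequence string.
#' @param filter a [query_filter()].
#' @return data frame `dataset_id`, `sample_id`, `count`.
#' @export
sequence_abundance <- function(store, sequence,
                               filter = query_filter()) {
  ids <- filter_dataset_ids(store, filter)
  if (!length(ids))
    return(data.frame(dataset_id = integer(0), sample_id = character(0),
                      count = integer(0)))
  tab <- DBI::dbGetQuery(store$con, paste0(
    "SELECT s.dataset_id, s.sample_id, s.amplicon_id, s.sequence,
            s.frequency, NULL AS taxonomy
     FROM nonredundant_sample s
     WHERE s.dataset_id IN (", paste(ids, collapse = ","), ")
       AND s.sequence = ?"), params = list(sequence))
  ftab <- filter
  ftab$taxon <- NULL   # taxonomy axis not meaningful for a literal lookup
  tab <- apply_row_filters(tab, store, ids, ftab)
  if (nrow(tab) == 0L)
    return(data.frame(dataset_id = integer(0), sample_id = character(0),
                      count = integer(0)))
  out <- stats::aggregate(list(count = tab$frequency),
                          by = list(dataset_id = tab$dataset_id,
                                    sample_id = tab$sample_id),
                          FUN = sum)
  out[order(out$dataset_id, out$sample_id), , drop = FALSE]
}

#' Export a query result to FASTA or TSV
#'
#' FASTA output uses the frequency-annotated header dialect
#' (`>seq<rank>_freq=<count>`); read-level selections (from
#' [random_subsample()]) are exported with frequency 1 per read. TSV
#' output carries all columns. Output is byte-stable for a fixed
#' selection.
#'
#' @param selection data frame from [select_sequences()] or
#'   [random_subsample()].
#' @param path output path.
#' @param format `"fasta"` or `"tsv"`.
#' @export
export_results <- function(selection, path, format = c("fasta", "tsv")) {
  if (!is.character(format) ||
      !format[1] %in% c("fasta", "tsv"))
    stop("unknown export format: ", format[1])
  format <- format[1]
  if (format == "tsv") {
    utils::write.table(selection, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    freq <- if ("frequency" %in% names(selection))
      selection$frequency else rep(1L, nrow(selection))
    write_fasta_with_frequency(
      data.frame(rank = seq_len(nrow(selection)),
                 sequence = selection$sequence, frequency = freq),
      path)
  }
  invisible(path)
}
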