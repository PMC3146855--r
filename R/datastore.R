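# Embedded relational store. Two run-level relations
# (data_upload_summary, statistics) plus seven per-dataset relations --
# sample_info, primer_barcode_info, raw_reads, redundant_sequences,
# nonredundant_pooled, nonredundant_sample, pooled2sample -- all scoped by
# a dataset_id foreign key rather than created per dataset at runtime,
# which keeps the schema static and auditable while preserving the same
# per-dataset semantics. discarded_reads backs the reproducibility log.

SCHEMA_VERSION <- 1L

store_schema <- c(
  "CREATE TABLE IF NOT EXISTS meta (
     key TEXT PRIMARY KEY, value TEXT)",
  "CREATE TABLE IF NOT EXISTS data_upload_summary (
     dataset_id INTEGER PRIMARY KEY AUTOINCREMENT,
     name TEXT NOT NULL,
     upload_timestamp TEXT NOT NULL,
     parameters TEXT NOT NULL)",
  "CREATE TABLE IF NOT EXISTS statistics (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     step_order INTEGER NOT NULL,
     step_name TEXT NOT NULL,
     n_in INTEGER NOT NULL,
     n_kept INTEGER NOT NULL,
     n_discarded INTEGER NOT NULL,
     PRIMARY KEY (dataset_id, step_order))",
  "CREATE TABLE IF NOT EXISTS sample_info (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     sample_id TEXT NOT NULL,
     variable TEXT NOT NULL,
     value_num REAL,
     value_chr TEXT,
     PRIMARY KEY (dataset_id, sample_id, variable))",
  "CREATE TABLE IF NOT EXISTS primer_barcode_info (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     amplicon_id TEXT NOT NULL,
     sample_id TEXT NOT NULL,
     barcode TEXT,
     forward_primer TEXT NOT NULL,
     reverse_primer TEXT NOT NULL,
     adapter_b TEXT NOT NULL,
     min_len INTEGER NOT NULL,
     max_len INTEGER NOT NULL,
     PRIMARY KEY (dataset_id, amplicon_id, sample_id))",
  "CREATE TABLE IF NOT EXISTS raw_reads (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     read_id TEXT NOT NULL,
     sequence TEXT NOT NULL,
     qualities TEXT NOT NULL,
     PRIMARY KEY (dataset_id, read_id))",
  "CREATE TABLE IF NOT EXISTS redundant_sequences (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     read_id TEXT NOT NULL,
     sample_id TEXT NOT NULL,
     amplicon_id TEXT,
     sequence TEXT NOT NULL,
     qualities TEXT NOT NULL,
     PRIMARY KEY (dataset_id, read_id))",
  "CREATE TABLE IF NOT EXISTS nonredundant_pooled (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     seq_rank INTEGER NOT NULL,
     sequence TEXT NOT NULL,
     frequency INTEGER NOT NULL,
     assigned_path TEXT,
     edited_path TEXT,
     edit_editor TEXT,
     edit_timestamp TEXT,
     PRIMARY KEY (dataset_id, seq_rank))",
  "CREATE TABLE IF NOT EXISTS nonredundant_sample (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     sample_id TEXT NOT NULL,
     amplicon_id TEXT,
     sequence TEXT NOT NULL,
     frequency INTEGER NOT NULL,
     PRIMARY KEY (dataset_id, sample_id, amplicon_id, sequence))",
  "CREATE TABLE IF NOT EXISTS pooled2sample (
     dataset_id INTEGER NOT NULL,
     seq_rank INTEGER NOT NULL,
     sample_id TEXT NOT NULL,
     frequency INTEGER NOT NULL,
     PRIMARY KEY (dataset_id, seq_rank, sample_id),
     FOREIGN KEY (dataset_id, seq_rank)
       REFERENCES nonredundant_pooled(dataset_id, seq_rank))",
  "CREATE TABLE IF NOT EXISTS discarded_reads (
     dataset_id INTEGER NOT NULL REFERENCES data_upload_summary(dataset_id),
     step_order INTEGER NOT NULL,
     read_id TEXT NOT NULL,
     PRIMARY KEY (dataset_id, step_order, read_id))")

# in FK-safe deletion order (children before parents)
per_dataset_tables <- function() {
  c("statistics", "sample_info", "primer_barcode_info", "raw_reads",
    "redundant_sequences", "pooled2sample", "nonredundant_pooled",
    "nonredundant_sample", "discarded_reads", "data_upload_summary")
}

#' Open (or create) an amplicon datastore
#'
#' @param path path to the single-file SQLite database, or `":memory:"`
#'   for a transient store.
#' @return an object of class `amplicon_store`.
#' @export
ads_connect <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  for (ddl in store_schema) DBI::dbExecute(con, ddl)
  DBI::dbExecute(con,
    "INSERT OR IGNORE INTO meta (key, value) VALUES ('schema_version', ?)",
    params = list(as.character(SCHEMA_VERSION)))
  structure(list(con = con, path = path), class = "amplicon_store")
}

#' Close a datastore
#' @param store an `amplicon_store`.
#' @export
ads_disconnect <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.amplicon_store <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con,
                       "SELECT COUNT(*) AS n FROM data_upload_summary")$n
  cat("amplicon_store at", x$path, "with", n, "dataset(s)\n")
  invisible(x)
}

qual_to_text <- function(q) vapply(q, paste, character(1), collapse = " ")
text_to_qual <- function(x) lapply(strsplit(x, " ", fixed = TRUE),
                                   as.integer)

#' Upload a dataset: run the pipeline and persist everything
#'
#' Runs [run_pipeline()] on the raw reads and, in a single transaction,
#' stores the raw reads, the trimmed (redundant) per-sample reads, the
#' pooled and per-sample non-redundant sets, the pooled-to-sample
#' frequency links, the primer/barcode and sample information, the
#' per-step statistics and the discarded-read identities. If anything
#' fails nothing is persisted.
#'
#' @param store an `amplicon_store`.
#' @param reads a [read_set()] of raw reads.
#' @param specs list of `primer_barcode_spec` objects.
#' @param sample_info a `sample_info` data frame.
#' @param config a [pipeline_config()].
#' @param name human-readable dataset name.
#' @return the new integer `dataset_id`, with the `pipeline_result`
#'   attached as attribute `"result"`.
#' @export
upload_dataset <- function(store, reads, specs, sample_info,
                           config = pipeline_config(), name = "dataset") {
  res <- run_pipeline(reads, specs, sample_info, config)
  con <- store$con
  DBI::dbBegin(con)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbRollback(con))

  DBI::dbExecute(con,
    "INSERT INTO data_upload_summary (name, upload_timestamp, parameters)
     VALUES (?, ?, ?)",
    params = list(name, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))
  did <- DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS id")$id

  stats_df <- data.frame(
    dataset_id = did,
    step_order = seq_along(res$logs),
    step_name = vapply(res$logs, `[[`, character(1), "step_name"),
    n_in = vapply(res$logs, `[[`, numeric(1), "n_in"),
    n_kept = vapply(res$logs, `[[`, numeric(1), "n_kept"),
    n_discarded = vapply(res$logs, `[[`, numeric(1), "n_discarded"))
  DBI::dbAppendTable(con, "statistics", stats_df)

  disc <- do.call(rbind, lapply(seq_along(res$logs), function(i) {
    ids <- res$logs[[i]]$discarded_ids
    if (!length(ids)) return(NULL)
    data.frame(dataset_id = did, step_order = i, read_id = ids)
  }))
  if (!is.null(disc)) DBI::dbAppendTable(con, "discarded_reads", disc)

  si_rows <- sample_info_long(sample_info)
  if (nrow(si_rows)) {
    si_rows$dataset_id <- did
    DBI::dbAppendTable(con, "sample_info", si_rows)
  }

  pb <- do.call(rbind, lapply(specs, function(s) {
    sid <- s$sample_ids
    data.frame(dataset_id = did, amplicon_id = s$amplicon_id,
               sample_id = sid,
               barcode = ifelse(sid %in% names(s$barcode_map),
                                s$barcode_map[sid], NA_character_),
               forward_primer = s$forward_primer,
               reverse_primer = s$reverse_primer,
               adapter_b = s$adapter_b,
               min_len = s$min_len, max_len = s$max_len)
  }))
  DBI::dbAppendTable(con, "primer_barcode_info", pb)

  DBI::dbAppendTable(con, "raw_reads",
    data.frame(dataset_id = did, read_id = reads$read_id,
               sequence = reads$sequence,
               qualities = qual_to_text(reads$qualities)))

  if (nrow(res$reads))
    DBI::dbAppendTable(con, "redundant_sequences",
      data.frame(dataset_id = did, read_id = res$reads$read_id,
                 sample_id = ifelse(is.na(res$reads$sample_id),
                                    "(unassigned)", res$reads$sample_id),
                 amplicon_id = res$reads$amplicon_id,
                 sequence = res$reads$sequence,
                 qualities = qual_to_text(res$reads$qualities)))

  d <- res$derep
  if (nrow(d$pooled))
    DBI::dbAppendTable(con, "nonredundant_pooled",
      data.frame(dataset_id = did, seq_rank = d$pooled$rank,
                 sequence = d$pooled$sequence,
                 frequency = d$pooled$frequency))
  if (nrow(d$per_sample))
    DBI::dbAppendTable(con, "nonredundant_sample",
      data.frame(dataset_id = did, sample_id = d$per_sample$sample_id,
                 amplicon_id = d$per_sample$amplicon_id,
                 sequence = d$per_sample$sequence,
                 frequency = d$per_sample$frequency))
  if (nrow(d$links))
    DBI::dbAppendTable(con, "pooled2sample",
      data.frame(dataset_id = did, seq_rank = d$links$rank,
                 sample_id = d$links$sample_id,
                 frequency = d$links$frequency))

  DBI::dbCommit(con)
  ok <- TRUE
  structure(as.integer(did), result = res)
}

sample_info_long <- function(si) {
  vars <- setdiff(names(si), "sample_id")
  rows <- lapply(vars, function(v) {
    val <- si[[v]]
    keep <- !is.na(val)
    if (!any(keep)) return(NULL)
    data.frame(sample_id = si$sample_id[keep], variable = v,
               value_num = if (is.numeric(val)) val[keep] else NA_real_,
               value_chr = if (is.numeric(val)) NA_character_
                           else as.character(val[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), variable = character(0),
                      value_num = numeric(0), value_chr = character(0))
  out
}

check_dataset <- function(store, dataset_id) {
  n <- DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM data_upload_summary WHERE dataset_id = ?",
    params = list(dataset_id))$n
  if (n != 1L) stop("unknown dataset_id: ", dataset_id)
  invisible(TRUE)
}

#' Delete a dataset and every row belonging to it
#'
#' @param store an `amplicon_store`.
#' @param dataset_id integer id returned by [upload_dataset()].
#' @export
delete_dataset <- function(store, dataset_id) {
  check_dataset(store, dataset_id)
  con <- store$con
  DBI::dbBegin(con)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbRollback(con))
  for (tab in setdiff(per_dataset_tables(), "data_upload_summary"))
    DBI::dbExecute(con,
      paste0("DELETE FROM ", tab, " WHERE dataset_id = ?"),
      params = list(dataset_id))
  DBI::dbExecute(con,
    "DELETE FROM data_upload_summary WHERE dataset_id = ?",
    params = list(dataset_id))
  DBI::dbCommit(con)
  ok <- TRUE
  invisible(NULL)
}

#' Retrieve the raw reads of a dataset
#'
#' @param store an `amplicon_store`.
#' @param dataset_id dataset to fetch.
#' @return a [read_set()] identical to the uploaded one.
#' @export
get_raw_reads <- function(store, dataset_id) {
  check_dataset(store, dataset_id)
  tab <- DBI::dbGetQuery(store$con,
    "SELECT read_id, sequence, qualities FROM raw_reads
     WHERE dataset_id = ? ORDER BY rowid",
    params = list(dataset_id))
  read_set(tab$read_id, tab$sequence, text_to_qual(tab$qualities))
}

#' Reconstruct the per-step logs of a stored dataset
#'
#' @param store an `amplicon_store`.
#' @param dataset_id dataset to report.
#' @return list of step logs (same shape as `run_pipeline()$logs`).
#' @export
get_step_logs <- function(store, dataset_id) {
  check_dataset(store, dataset_id)
  st <- DBI::dbGetQuery(store$con,
    "SELECT step_order, step_name, n_in, n_kept, n_discarded
     FROM statistics WHERE dataset_id = ? ORDER BY step_order",
    params = list(dataset_id))
  disc <- DBI::dbGetQuery(store$con,
    "SELECT step_order, read_id FROM discarded_reads
     WHERE dataset_id = ? ORDER BY step_order, read_id",
    params = list(dataset_id))
  lapply(seq_len(nrow(st)), function(i) {
    ids <- disc$read_id[disc$step_order == st$step_order[i]]
    list(step_name = st$step_name[i], n_in = st$n_in[i],
         n_kept = st$n_kept[i], n_discarded = st$n_discarded[i],
         discarded_ids = ids, parameters = list())
  })
}

#' Per-step summary statistics of a stored dataset
#'
#' Returns the classic per-step elimination report: for each pipeline
#' step the number of reads considered and the number discarded, plus a
#' totals row.
#'
#' @param store an `amplicon_store`.
#' @param dataset_id dataset to report.
#' @return data frame with columns `step_order`, `step_name`,
#'   `n_considered`, `n_discarded`; the last row (`step_order` `NA`,
#'   `step_name` `"total"`) carries raw total and final retained count.
#' @export
summary_statistics <- function(store, dataset_id) {
  check_dataset(store, dataset_id)
  st <- DBI::dbGetQuery(store$con,
    "SELECT step_order, step_name, n_in, n_kept, n_discarded
     FROM statistics WHERE dataset_id = ? ORDER BY step_order",
    params = list(dataset_id))
  out <- data.frame(step_order = st$step_order, step_name = st$step_name,
                    n_considered = st$n_in, n_discarded = st$n_discarded,
                    stringsAsFactors = FALSE)
  total <- data.frame(step_order = NA_integer_, step_name = "total",
                      n_considered = if (nrow(st)) st$n_in[1] else 0L,
                      n_discarded = sum(st$n_discarded))
  out <- rbind(out, total)
  attr(out, "retained") <- if (nrow(st)) st$n_kept[nrow(st)] else 0L
  out
}

#' Combine stored raw reads and re-process them as a new dataset
#'
#' Pools the raw 454 reads of the listed datasets (read identifiers are
#' prefixed `d<id>_` to disambiguate), re-runs the pipeline with the
#' supplied specs and configuration, and stores the result as a new
#' dataset; the sources are untouched. Combining runs lets true
#' low-frequency variants that were single-sample singletons in each run
#' alone survive the cross-sample criterion.
#'
#' @param store an `amplicon_store`.
#' @param dataset_ids integer vector of existing dataset ids.
#' @param specs list of `primer_barcode_spec` objects for the combined run.
#' @param config a [pipeline_config()].
#' @param name name of the new dataset.
#' @return the new `dataset_id`.
#' @export
combine_and_reprocess <- function(store, dataset_ids, specs,
                                  config = pipeline_config(),
                                  name = "combined") {
  stopifnot(length(dataset_ids) >= 1)
  for (d in dataset_ids) check_dataset(store, d)
  pools <- lapply(dataset_ids, function(d) {
    r <- get_raw_reads(store, d)
    r$read_id <- paste0("d", d, "_", r$read_id)
    r
  })
  pooled <- do.call(rbind, pools)
  class(pooled) <- c("read_set", "data.frame")
  si <- DBI::dbGetQuery(store$con, paste0(
    "SELECT DISTINCT sample_id, variable, value_num, value_chr
     FROM sample_info WHERE dataset_id IN (",
    paste(dataset_ids, collapse = ","), ")"))
  sample_info <- sample_info_wide(si)
  upload_dataset(store, pooled, specs, sample_info, config, name)
}

sample_info_wide <- function(long) {
  ids <- unique(long$sample_id)
  vars <- unique(long$variable)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (v in vars) {
    sub <- long[long$variable == v, ]
    sub <- sub[!duplicated(sub$sample_id), ]
    numeric_v <- all(is.na(sub$value_chr))
    col <- if (numeric_v) rep(NA_real_, length(ids))
           else rep(NA_character_, length(ids))
    col[match(sub$sample_id, ids)] <-
      if (numeric_v) sub$value_num else sub$value_chr
    out[[v]] <- col
  }
  class(out) <- c("sample_info", "data.frame")
  out
}

#' Update, add or remove a sample-information variable
#'
#' @param store an `amplicon_store`.
#' @param dataset_id,sample_id which sample to edit.
#' @param variable variable name.
#' @param value new value (numeric or character); `NULL` removes the
#'   variable for this sample.
#' @export
update_sample_info <- function(store, dataset_id, sample_id, variable,
                               value) {
  check_dataset(store, dataset_id)
  known <- DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM (
       SELECT sample_id FROM sample_info
         WHERE dataset_id = ? AND sample_id = ?
       UNION
       SELECT sample_id FROM primer_barcode_info
         WHERE dataset_id = ? AND sample_id = ?)",
    params = list(dataset_id, sample_id, dataset_id, sample_id))$n
  if (known == 0L)
    stop("unknown sample '", sample_id, "' in dataset ", dataset_id)
  DBI::dbExecute(store$con,
    "DELETE FROM sample_info
     WHERE dataset_id = ? AND sample_id = ? AND variable = ?",
    params = list(dataset_id, sample_id, variable))
  if (!is.null(value)) {
    num <- suppressWarnings(as.numeric(value))
    DBI::dbExecute(store$con,
      "INSERT INTO sample_info
         (dataset_id, sample_id, variable, value_num, value_chr)
       VALUES (?, ?, ?, ?, ?)",
      params = list(dataset_id, sample_id, variable,
                    if (is.na(num)) NA_real_ else num,
                    if (is.na(num)) as.character(value)
                    else NA_character_))
  }
  invisible(NULL)
}

#' Set the automatically assigned taxonomic path of stored sequences
#'
#' Writes `assigned_path` for pooled non-redundant sequences from an
#' assignment table; any manually edited path is left untouched.
#'
#' @param store an `amplicon_store`.
#' @param dataset_id dataset whose sequences were classified.
#' @param assignment data frame with columns `sequence` and `path` (or
#'   the output of [assign_taxonomic_path()], whose `query_sequence`
#'   column is used).
#' @export
set_assigned_taxonomy <- function(store, dataset_id, assignment) {
  check_dataset(store, dataset_id)
  seqcol <- if ("sequence" %in% names(assignment)) "sequence"
            else "query_sequence"
  for (i in seq_len(nrow(assignment)))
    DBI::dbExecute(store$con,
      "UPDATE nonredundant_pooled SET assigned_path = ?
       WHERE dataset_id = ? AND sequence = ?",
      params = list(assignment$path[i], dataset_id,
                    assignment[[seqcol]][i]))
  invisible(NULL)
}

#' Record a manually edited taxonomic path
#'
#' The automatic assignment is never overwritten: the edit lives in its
#' own column together with the editor tag and a timestamp, so expert
#' corrections stay traceable.
#'
#' @param store an `amplicon_store`.
#' @param dataset_id dataset containing the sequence.
#' @param sequence exact sequence string of the pooled non-redundant
#'   entry to edit.
#' @param new_path the corrected taxonomic path.
#' @param editor free-form editor tag.
#' @export
set_edited_taxonomy <- function(store, dataset_id, sequence, new_path,
                                editor = "unknown") {
  check_dataset(store, dataset_id)
  n <- DBI::dbExecute(store$con,
    "UPDATE nonredundant_pooled
     SET edited_path = ?, edit_editor = ?, edit_timestamp = ?
     WHERE dataset_id = ? AND sequence = ?",
    params = list(new_path, editor,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  dataset_id, sequence))
  if (n == 0L)
    stop("unknown sequence in dataset ", dataset_id)
  invisible(NULL)
}

#' Fetch taxonomy annotation of a stored sequence
#'
#' @param store an `amplicon_store`.
#' @param dataset_id dataset containing the sequence.
#' @param sequence exact sequence string.
#' @return one-row data frame with `assigned_path`, `edited_path`,
#'   `edit_editor`, `edit_timestamp`.
#' @export
get_taxonomy <- function(store, dataset_id, sequence) {
  check_dataset(store, dataset_id)
  out <- DBI::dbGetQuery(store$con,
    "SELECT assigned_path, edited_path, edit_editor, edit_timestamp
     FROM nonredundant_pooled WHERE dataset_id = ? AND sequence = ?",
    params = list(dataset_id, sequence))
  if (nrow(out) == 0L)
    stop("unknown sequence in dataset ", dataset_id)
  out
}

#' Audit referential integrity of the store
#'
#' Checks the foreign-key relations across the per-dataset tables and the
#' frequency bookkeeping (pooled frequency equals the sum over its
#' pooled-to-sample link rows).
#'
#' @param store an `amplicon_store`.
#' @return `TRUE` invisibly; stops with a description on violation.
#' @export
audit_store <- function(store) {
  con <- store$con
  fk <- DBI::dbGetQuery(con, "PRAGMA foreign_key_check")
  if (nrow(fk)) stop("foreign key violations in: ",
                     paste(unique(fk$table), collapse = ", "))
  bad <- DBI::dbGetQuery(con,
    "SELECT p.dataset_id, p.seq_rank FROM nonredundant_pooled p
     LEFT JOIN (SELECT dataset_id, seq_rank, SUM(frequency) AS f
                FROM pooled2sample GROUP BY dataset_id, seq_rank) l
     ON p.dataset_id = l.dataset_id AND p.seq_rank = l.seq_rank
     WHERE p.frequency != IFNULL(l.f, 0)")
  if (nrow(bad))
    stop("pooled frequency != sum of link rows for ", nrow(bad),
         " sequence(s)")
  invisible(TRUE)
}
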