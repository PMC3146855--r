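#' Read paired FASTA + QUAL files
#'
#' Parses the 454 toolchain's paired representation of reads: a FASTA file
#' with the base calls and a companion `.qual` file holding one integer
#' phred-style score per base, records wrapped at arbitrary widths.
#' Identifiers are the token before the first whitespace in each header and
#' must appear in the same order in both files.
#'
#' @param fasta_path path to the FASTA file.
#' @param qual_path path to the companion QUAL file.
#' @return a [read_set()].
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  qual <- parse_qual_file(qual_path)
  if (length(ids) != length(qual$id))
    stop("FASTA has ", length(ids), " records but QUAL has ",
         length(qual$id))
  mism <- which(ids != qual$id)
  if (length(mism))
    stop("identifier mismatch between FASTA and QUAL at record ",
         mism[1], ": '", ids[mism[1]], "' vs '", qual$id[mism[1]], "'")
  seqc <- toupper(as.character(seqs))
  bad <- which(nchar(seqc) != lengths(qual$values))
  if (length(bad))
    stop("quality length mismatch for ", ids[bad[1]])
  read_set(ids, seqc, qual$values)
}

# QUAL is FASTA-shaped but its "sequence" lines are whitespace-separated
# integers; no installed parser reads this dialect, so it is parsed here.
parse_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1]) stop("QUAL file does not start with '>'")
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  body <- split(lines[!hdr], rec[!hdr])
  values <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    b <- body[[as.character(i)]]
    if (is.null(b)) b <- character(0)
    toks <- unlist(strsplit(paste(b, collapse = " "), "\\s+"))
    toks <- toks[nzchar(toks)]
    v <- suppressWarnings(as.integer(toks))
    if (anyNA(v)) stop("non-numeric quality value for ", ids[i])
    values[[i]] <- v
  }
  list(id = ids, values = values)
}

#' Write paired FASTA + QUAL files
#'
#' Inverse of [read_fasta_qual()]; used for export and for the lossless
#' round-trip contract.
#'
#' @param reads a [read_set()].
#' @param fasta_path,qual_path output paths.
#' @param width line-wrap width for sequence and quality lines.
#' @export
write_fasta_qual <- function(reads, fasta_path, qual_path, width = 60L) {
  fa <- character(0)
  qu <- character(0)
  for (i in seq_len(nrow(reads))) {
    fa <- c(fa, paste0(">", reads$read_id[i]),
            wrap_string(reads$sequence[i], width))
    q <- reads$qualities[[i]]
    qlines <- if (length(q)) {
      starts <- seq(1L, length(q), by = width)
      vapply(starts, function(s)
        paste(q[s:min(s + width - 1L, length(q))], collapse = " "),
        character(1))
    } else character(0)
    qu <- c(qu, paste0(">", reads$read_id[i]), qlines)
  }
  writeLines(fa, fasta_path)
  writeLines(qu, qual_path)
  invisible(NULL)
}

wrap_string <- function(s, width) {
  if (nchar(s) == 0L) return(character(0))
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

#' Parse the primer & barcode specification file
#'
#' The file is a TSV with header
#' `amplicon_id, sample_id, barcode, forward_primer, reverse_primer,
#' adapter_b, min_len, max_len`; one row per (amplicon, sample). Rows
#' sharing an `amplicon_id` are aggregated into one amplicon spec whose
#' `barcode_map` collects the per-sample barcodes. Barcodes across the whole
#' file must be distinct and prefix-free so that demultiplexing of
#' variable-length barcodes is unambiguous; the barcode cell may be empty
#' for a single-sample run (the demultiplexing step then passes reads
#' through tagged with that sample).
#'
#' @param path path to the TSV file.
#' @return a list of `primer_barcode_spec` objects, each a list with fields
#'   `amplicon_id`, `forward_primer`, `reverse_primer`, `adapter_b`,
#'   `min_len`, `max_len` and `barcode_map` (named character vector,
#'   sample_id -> barcode).
#' @export
parse_primer_barcode_file <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("amplicon_id", "sample_id", "barcode", "forward_primer",
            "reverse_primer", "adapter_b", "min_len", "max_len")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("primer & barcode file is missing column(s): ",
         paste(miss, collapse = ", "))
  tab$min_len <- as.integer(tab$min_len)
  tab$max_len <- as.integer(tab$max_len)
  tab$barcode <- toupper(trimws(tab$barcode))
  tab$forward_primer <- toupper(tab$forward_primer)
  tab$reverse_primer <- toupper(tab$reverse_primer)
  tab$adapter_b <- toupper(tab$adapter_b)

  dup <- duplicated(tab[c("amplicon_id", "sample_id")])
  if (any(dup))
    stop("duplicate (amplicon_id, sample_id) pair at row ", which(dup)[1])
  bad <- which(tab$min_len > tab$max_len)
  if (length(bad))
    stop("min_len > max_len at row ", bad[1])
  if (any(!nzchar(tab$forward_primer)) || any(!nzchar(tab$reverse_primer)) ||
      any(!nzchar(tab$adapter_b)))
    stop("primers and adapter B must be non-empty")

  bcs <- tab$barcode[nzchar(tab$barcode)]
  rows <- which(nzchar(tab$barcode))
  if (length(bcs) > 1) {
    for (i in seq_along(bcs)) for (j in seq_along(bcs)) {
      if (i != j && startsWith(bcs[j], bcs[i]))
        stop("barcode prefix conflict: '", bcs[i], "' (row ", rows[i],
             ") is a prefix of '", bcs[j], "' (row ", rows[j], ")")
    }
  }

  specs <- lapply(split(tab, tab$amplicon_id), function(g) {
    for (col in c("forward_primer", "reverse_primer", "adapter_b",
                  "min_len", "max_len"))
      if (length(unique(g[[col]])) != 1L)
        stop("inconsistent ", col, " within amplicon ", g$amplicon_id[1])
    bm <- g$barcode[nzchar(g$barcode)]
    names(bm) <- g$sample_id[nzchar(g$barcode)]
    structure(list(amplicon_id = g$amplicon_id[1],
                   forward_primer = g$forward_primer[1],
                   reverse_primer = g$reverse_primer[1],
                   adapter_b = g$adapter_b[1],
                   min_len = g$min_len[1], max_len = g$max_len[1],
                   barcode_map = bm,
                   sample_ids = unique(g$sample_id)),
              class = "primer_barcode_spec")
  })
  names(specs) <- NULL
  specs
}

#' Write a primer & barcode specification file
#'
#' @param specs list of `primer_barcode_spec` objects.
#' @param path output TSV path.
#' @export
write_primer_barcode_file <- function(specs, path) {
  rows <- do.call(rbind, lapply(specs, function(s) {
    sid <- s$sample_ids
    bc <- ifelse(sid %in% names(s$barcode_map), s$barcode_map[sid], "")
    data.frame(amplicon_id = s$amplicon_id, sample_id = sid, barcode = bc,
               forward_primer = s$forward_primer,
               reverse_primer = s$reverse_primer, adapter_b = s$adapter_b,
               min_len = s$min_len, max_len = s$max_len,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Parse the sample-information table
#'
#' A TSV whose first column is `sample_id` and whose remaining columns are
#' arbitrary per-sample variables (temperature, pH, depth, collection date,
#' tissue type, ...). A column is numeric if every non-missing value parses
#' as a number; otherwise it is kept as categorical strings. Empty cells
#' become `NA` (absent).
#'
#' @param path path to the TSV file.
#' @return a data frame of class `sample_info` with one row per sample.
#' @export
parse_sample_info_file <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (names(tab)[1] != "sample_id")
    stop("first column of the sample-information file must be 'sample_id'")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ",
         tab$sample_id[duplicated(tab$sample_id)][1])
  for (v in names(tab)[-1]) {
    col <- tab[[v]]
    col[!nzchar(trimws(col))] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    tab[[v]] <- if (all(is.na(num) == is.na(col))) num else col
  }
  class(tab) <- c("sample_info", "data.frame")
  tab
}

#' Write frequency-annotated FASTA
#'
#' Emits the non-redundant sequence set with headers of the form
#' `>seq<rank>_freq=<count>`, records in input order (the dereplication
#' contract already orders them by descending copy number).
#'
#' @param unique_sequences data frame with columns `sequence` and
#'   `frequency` (a `rank` column is used for the header number when
#'   present, otherwise the row number).
#' @param path output path.
#' @export
write_fasta_with_frequency <- function(unique_sequences, path, width = 60L) {
  n <- nrow(unique_sequences)
  rank <- if ("rank" %in% names(unique_sequences))
    unique_sequences$rank else seq_len(n)
  out <- character(0)
  for (i in seq_len(n)) {
    out <- c(out,
             sprintf(">seq%d_freq=%d", rank[i],
                     as.integer(unique_sequences$frequency[i])),
             wrap_string(unique_sequences$sequence[i], width))
  }
  writeLines(out, path)
  invisible(NULL)
}

#' Read frequency-annotated FASTA
#'
#' Inverse of [write_fasta_with_frequency()].
#'
#' @param path path to a FASTA file with `>seq<rank>_freq=<count>` headers.
#' @return data frame with columns `rank`, `sequence`, `frequency`.
#' @export
read_fasta_with_frequency <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  m <- regmatches(hdr, regexec("^seq([0-9]+)_freq=([0-9]+)$", hdr))
  bad <- which(lengths(m) != 3L)
  if (length(bad))
    stop("malformed frequency header: '", hdr[bad[1]], "'")
  data.frame(rank = as.integer(vapply(m, `[`, character(1), 2)),
             sequence = as.character(seqs),
             frequency = as.integer(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Write the reproducibility log
#'
#' One section per pipeline step with machine-greppable `KEY: value` lines:
#' the step name, its parameters, the read counts in/kept/discarded, and
#' the identifiers of discarded reads; preceded by a header block with the
#' global run parameters and a timestamp.
#'
#' @param step_logs list of step logs as produced by [run_pipeline()]
#'   (each a list with `step_name`, `n_in`, `n_kept`, `n_discarded`,
#'   `discarded_ids`, `parameters`).
#' @param parameters named list of global run parameters.
#' @param path output path.
#' @export
write_log <- function(step_logs, parameters, path) {
  fmt1 <- function(v) paste(vapply(v, format_param, character(1)),
                            collapse = ",")
  out <- c("RUN LOG",
           paste0("TIMESTAMP: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           vapply(names(parameters), function(k)
             paste0("PARAM ", k, ": ", fmt1(parameters[[k]])), character(1)))
  for (i in seq_along(step_logs)) {
    s <- step_logs[[i]]
    stopifnot(s$n_in == s$n_kept + s$n_discarded,
              length(s$discarded_ids) == s$n_discarded)
    out <- c(out, "",
             paste0("STEP ", i, ": ", s$step_name),
             if (length(s$parameters))
               vapply(names(s$parameters), function(k)
                 paste0("PARAM ", k, ": ", fmt1(s$parameters[[k]])),
                 character(1)),
             paste0("IN: ", s$n_in),
             paste0("KEPT: ", s$n_kept),
             paste0("DISCARDED: ", s$n_discarded),
             paste0("DISCARDED_IDS: ",
                    paste(s$discarded_ids, collapse = ",")))
  }
  writeLines(out, path)
  invisible(NULL)
}

format_param <- function(v) {
  if (is.logical(v)) return(ifelse(v, "true", "false"))
  as.character(v)
}

#' Parse a reproducibility log back into per-step counts
#'
#' Used to audit that the log, the statistics report and the stored
#' statistics rows agree.
#'
#' @param path path to a log written by [write_log()].
#' @return data frame with columns `step_order`, `step_name`, `n_in`,
#'   `n_kept`, `n_discarded`, and a list column `discarded_ids`.
#' @export
read_log <- function(path) {
  lines <- readLines(path)
  idx <- grep("^STEP [0-9]+: ", lines)
  grab <- function(block, key) {
    ln <- grep(paste0("^", key, ": "), block, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", ln)
  }
  res <- lapply(seq_along(idx), function(i) {
    to <- if (i < length(idx)) idx[i + 1] - 1L else length(lines)
    block <- lines[idx[i]:to]
    ids <- grab(block, "DISCARDED_IDS")
    ids <- if (is.na(ids) || !nzchar(ids)) character(0) else
      strsplit(ids, ",", fixed = TRUE)[[1]]
    data.frame(step_order = i,
               step_name = sub("^STEP [0-9]+: ", "", block[1]),
               n_in = as.integer(grab(block, "IN")),
               n_kept = as.integer(grab(block, "KEPT")),
               n_discarded = as.integer(grab(block, "DISCARDED")),
               discarded_ids = I(list(ids)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
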