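# Closest-hit taxonomy: the similarity search itself (e.g. BLAST against
# NCBI nt) is an external tool; this module consumes its standard
# 12-column tabular output plus a subject -> lineage map and reports, per
# query, the taxonomic path of the closest database sequence.

hit_columns <- c("query_id", "subject_id", "identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")

#' Read a tabular similarity-search hit file
#'
#' Standard 12-column tab-separated hit format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, e-value, bit score).
#'
#' @param path path to the hit file.
#' @return data frame with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 12)), hit_columns))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("malformed hit row at line ", bad[1], ": expected 12 columns, got ",
         lengths(parts)[bad[1]])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- hit_columns
  for (col in c("identity", "aln_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end", "evalue",
                "bit_score")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("malformed hit row at line ",
           which(is.na(v))[1], ": non-numeric ", col)
    tab[[col]] <- v
  }
  if (any(tab$identity < 0 | tab$identity > 100))
    stop("percent identity outside [0, 100]")
  if (any(tab$evalue < 0)) stop("negative e-value")
  tab
}

#' Read a subject-to-lineage map
#'
#' Two-column TSV: subject id, semicolon-delimited taxonomic path.
#'
#' @param path path to the TSV (no header).
#' @return named character vector, subject id -> path.
#' @export
read_lineage_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("lineage map needs two columns")
  if (any(!nzchar(tab[[2]]))) stop("empty taxonomic path in lineage map")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Assign each query the taxonomic path of its closest hit
#'
#' The best hit per query is the one with the lowest e-value, ties broken
#' by highest bit score, then lexicographically smallest subject id, so
#' the result is independent of the row order of the hit file. Queries
#' without any hit get the path `"no_hit"`; hits whose subject is missing
#' from the lineage map get `"unknown"`.
#'
#' @param hits data frame from [read_hit_table()].
#' @param lineage_map named character vector from [read_lineage_map()].
#' @param queries data frame with columns `query_id` and `sequence` (one
#'   row per query; all queries are reported, hit or not).
#' @param max_evalue,min_identity optional cutoffs applied before best-hit
#'   selection (`NULL` = no cutoff).
#' @return data frame with the three-column report: `query_id`,
#'   `query_sequence`, `path`.
#' @export
assign_taxonomic_path <- function(hits, lineage_map, queries,
                                  max_evalue = NULL, min_identity = NULL) {
  stopifnot(all(c("query_id", "sequence") %in% names(queries)))
  if (!is.null(max_evalue)) hits <- hits[hits$evalue <= max_evalue, ]
  if (!is.null(min_identity)) hits <- hits[hits$identity >= min_identity, ]
  path <- rep("no_hit", nrow(queries))
  if (nrow(hits)) {
    ord <- order(hits$query_id, hits$evalue, -hits$bit_score,
                 hits$subject_id)
    best <- hits[ord, ][!duplicated(hits$query_id[ord]), ]
    m <- match(queries$query_id, best$query_id)
    has <- !is.na(m)
    subj <- best$subject_id[m[has]]
    p <- unname(lineage_map[subj])
    p[is.na(p)] <- "unknown"
    path[has] <- p
  }
  data.frame(query_id = queries$query_id,
             query_sequence = queries$sequence,
             path = path, stringsAsFactors = FALSE)
}

#' Write the three-column taxonomy report
#'
#' @param assignment output of [assign_taxonomic_path()].
#' @param path output TSV path.
#' @export
write_taxonomy_table <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
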