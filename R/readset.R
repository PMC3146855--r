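#' Construct a set of 454 reads
#'
#' A `read_set` is the package's working container for pyrosequencing reads:
#' a data frame with one row per read, carrying the identifier, the (upper
#' case) nucleotide sequence, a list column of per-base phred-style quality
#' values, and -- once the pipeline has assigned them -- the sample and
#' amplicon a read belongs to.
#'
#' @param read_id character vector of unique, non-empty read identifiers.
#' @param sequence character vector of DNA sequences over `A,C,G,T,N`
#'   (lower case input is normalised to upper case).
#' @param qualities list of integer vectors, one per read, each the same
#'   length as the corresponding sequence.
#' @param sample_id,amplicon_id optional character vectors (default `NA`,
#'   i.e. not yet assigned).
#' @return a data frame of class `read_set`.
#' @export
read_set <- function(read_id, sequence, qualities,
                     sample_id = NA_character_, amplicon_id = NA_character_) {
  read_id <- as.character(read_id)
  sequence <- toupper(as.character(sequence))
  stopifnot(is.list(qualities), length(qualities) == length(read_id),
            length(sequence) == length(read_id))
  qualities <- lapply(qualities, as.integer)
  if (anyDuplicated(read_id))
    stop("duplicate read identifiers: ",
         paste(unique(read_id[duplicated(read_id)]), collapse = ", "))
  if (any(!nzchar(read_id))) stop("empty read identifier")
  bad <- which(nchar(sequence) != lengths(qualities))
  if (length(bad))
    stop("quality length mismatch for ", read_id[bad[1]])
  x <- data.frame(read_id = read_id, sequence = sequence,
                  sample_id = rep_len(as.character(sample_id), length(read_id)),
                  amplicon_id = rep_len(as.character(amplicon_id), length(read_id)),
                  stringsAsFactors = FALSE)
  x$qualities <- qualities
  class(x) <- c("read_set", "data.frame")
  x
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads\n")
  if (nrow(x)) {
    show <- utils::head(x, 5)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s  %s%s  [%d bp, mean Q %.1f]%s\n",
                  show$read_id[i],
                  substr(show$sequence[i], 1, 40),
                  if (nchar(show$sequence[i]) > 40) "..." else "",
                  nchar(show$sequence[i]),
                  mean(show$qualities[[i]]),
                  if (!is.na(show$sample_id[i]))
                    paste0(" sample=", show$sample_id[i]) else ""))
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

# subset rows of a read_set, keeping the class and list column intact
rs_subset <- function(x, keep) {
  y <- x[keep, , drop = FALSE]
  rownames(y) <- NULL
  class(y) <- c("read_set", "data.frame")
  y
}

# trim every read to the half-open 0-based window [from, to) of its current
# sequence; `from`/`to` are vectors recycled across reads. Sequence and
# qualities move in lockstep.
rs_trim <- function(x, from, to) {
  n <- nrow(x)
  from <- rep_len(as.integer(from), n)
  to <- rep_len(as.integer(to), n)
  x$sequence <- substr(x$sequence, from + 1L, to)
  x$qualities <- Map(function(q, f, t) if (t > f) q[(f + 1L):t] else integer(0),
                     x$qualities, from, to)
  x
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# length of the terminal homopolymer run at the 3' end of a string
terminal_run_length <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(0L)
  ch <- substr(s, n, n)
  k <- 1L
  while (n - k >= 1L && substr(s, n - k, n - k) == ch) k <- k + 1L
  k
}

# length of the run of `ch` in `s` starting at 1-based position `at`
run_length_at <- function(s, at, ch) {
  n <- nchar(s)
  k <- 0L
  while (at + k <= n && substr(s, at + k, at + k) == ch) k <- k + 1L
  k
}
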