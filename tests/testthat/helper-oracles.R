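# Brute-force re-implementations of every filter rule, deliberately
# written with different mechanics (regexes, char-vector arithmetic,
# exhaustive enumeration) than both the package and the generator's
# internal bookkeeping. Used read-for-read in the oracle-equivalence
# tests.

oracle_strip_polyN <- function(s) {
  cs <- strsplit(s, "")[[1]]
  n <- length(cs)
  while (n >= 1 && cs[n] == "N") n <- n - 1L
  paste(cs[seq_len(n)], collapse = "")
}

# returns number of bases kept before the best adapter match, or -1
oracle_adapter_cut <- function(s, adapters, mode = "perfect",
                               budget = 1L, min_prefix = 4L) {
  cs <- strsplit(s, "")[[1]]
  n <- length(cs)
  cand <- list()
  for (ad in adapters) {
    ca <- strsplit(ad, "")[[1]]
    la <- length(ca)
    allow <- if (mode == "fuzzy") ceiling(la / 10) * budget else 0L
    if (la <= n)
      for (st in 1:(n - la + 1))
        if (sum(cs[st:(st + la - 1)] != ca) <= allow)
          cand[[length(cand) + 1L]] <- c(st - 1L, la)
    if (la - 1L >= min_prefix)
      for (p in min_prefix:min(la - 1L, n))
        if (identical(cs[(n - p + 1):n], ca[1:p]))
          cand[[length(cand) + 1L]] <- c(n - p, p)
  }
  if (!length(cand)) return(-1L)
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 1], -m[, 2]), , drop = FALSE]
  m[1, 1]
}

oracle_has_ambiguity <- function(s) {
  "N" %in% strsplit(s, "")[[1]]
}

oracle_demux <- function(s, barcode_map) {
  for (i in seq_along(barcode_map)) {
    bc <- barcode_map[[i]]
    if (nchar(s) >= nchar(bc) && substr(s, 1, nchar(bc)) == bc)
      return(list(sample = names(barcode_map)[i],
                  rest = substring(s, nchar(bc) + 1)))
  }
  NULL
}

# read ids kept by the cross-sample singleton rule
oracle_singleton_keep <- function(ids, seqs, samples,
                                  fallback = "min_two_copies") {
  if (length(unique(samples)) <= 1) {
    if (fallback == "skip") return(ids)
    return(ids[ave(seq_along(seqs), seqs, FUN = length) >= 2])
  }
  span <- vapply(seqs, function(x)
    length(unique(samples[seqs == x])), integer(1))
  ids[span >= 2]
}

# regex-based homopolymer-tolerant forward-primer match: number of read
# bases consumed, or -1
oracle_match_fwd <- function(s, primer, slack) {
  cp <- strsplit(primer, "")[[1]]
  np <- length(cp)
  r <- 1L
  while (np - r >= 1 && cp[np - r] == cp[np]) r <- r + 1L
  if (r < 2L || slack == 0L) {
    return(if (startsWith(s, primer)) np else -1L)
  }
  stem <- paste(cp[seq_len(np - r)], collapse = "")
  ch <- cp[np]
  lo <- max(1L, r - slack)
  hi <- r + slack
  # enumerate tolerated run lengths, longest first, capped at hi even if
  # the read run continues
  for (k in hi:lo) {
    pat <- paste0(stem, strrep(ch, k))
    if (startsWith(s, pat)) {
      if (k == hi) return(nchar(pat))
      if (substr(s, nchar(pat) + 1, nchar(pat) + 1) != ch)
        return(nchar(pat))
    }
  }
  -1L
}

# enumeration-based 3' match: the tolerant run is the terminal run of
# revcomp(rev_primer), sitting at the very end of the read, so exactly one
# candidate run length can match a given read suffix
oracle_match_rev <- function(s, rev_primer, slack) {
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", rev_primer),
                           "")[[1]]), collapse = "")
  cp <- strsplit(rc, "")[[1]]
  np <- length(cp)
  r <- 1L
  while (np - r >= 1 && cp[np - r] == cp[np]) r <- r + 1L
  if (r < 2L || slack == 0L) {
    return(if (endsWith(s, rc)) np else -1L)
  }
  stem <- paste(cp[seq_len(np - r)], collapse = "")
  ch <- cp[np]
  for (k in max(1L, r - slack):(r + slack)) {
    pat <- paste0(stem, strrep(ch, k))
    if (endsWith(s, pat)) {
      # the run must be terminal-maximal: nothing to check beyond the
      # read end, but reject if the read actually ends with more ch
      # than tolerated (then a longer k would have matched instead)
      return(nchar(pat))
    }
  }
  -1L
}

oracle_mean_quality_keep <- function(quals, threshold) {
  length(quals) > 0 && sum(quals) / length(quals) >= threshold
}

oracle_derep <- function(seqs, samples) {
  u <- unique(seqs)
  freq <- vapply(u, function(x) sum(seqs == x), integer(1))
  ord <- order(-freq, u)
  data.frame(rank = seq_along(u), sequence = u[ord],
             frequency = unname(freq[ord]), stringsAsFactors = FALSE)
}
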