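#' Pipeline configuration
#'
#' Collects the tunable parameters of the seven-step read-cleaning
#' pipeline. Every step can also be switched off entirely; a disabled step
#' passes all reads through and logs zero discards.
#'
#' @param adapter_mode `"perfect"` requires an exact adapter B occurrence
#'   (or an exact terminal prefix, see [trim_adapter_b()]); `"fuzzy"`
#'   additionally allows mismatches.
#' @param fuzzy_max_mismatch_per_10bp mismatch budget per 10 adapter bases
#'   in fuzzy mode (total budget `ceiling(nchar(adapter)/10) * this`).
#' @param remove_ambiguous drop reads containing one or more `N` bases.
#' @param remove_singletons drop sequences not seen in at least two
#'   distinct samples (the cross-sample singleton / chimera filter).
#' @param quality_threshold minimum arithmetic mean of the remaining
#'   per-base quality values after all trimming; reads strictly below are
#'   discarded. `0` keeps everything.
#' @param homopolymer_slack maximum run-length deviation tolerated in the
#'   primer-terminal homopolymer (454 chemistry misestimates homopolymer
#'   lengths, so the run adjacent to a primer may gain or lose bases).
#' @param single_sample_singleton_fallback what the singleton step does
#'   when the run contains exactly one sample, where "two different
#'   samples" is undefined: `"min_two_copies"` requires at least two copies
#'   in the dataset, `"skip"` disables the step.
#' @param trim_adapter,demultiplex,filter_length,trim_primers,filter_quality
#'   logical switches for the remaining steps.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(adapter_mode = c("perfect", "fuzzy"),
                            fuzzy_max_mismatch_per_10bp = 1L,
                            remove_ambiguous = TRUE,
                            remove_singletons = TRUE,
                            quality_threshold = 25,
                            homopolymer_slack = 3L,
                            single_sample_singleton_fallback =
                              c("min_two_copies", "skip"),
                            trim_adapter = TRUE,
                            demultiplex = TRUE,
                            filter_length = TRUE,
                            trim_primers = TRUE,
                            filter_quality = TRUE) {
  adapter_mode <- match.arg(adapter_mode)
  single_sample_singleton_fallback <-
    match.arg(single_sample_singleton_fallback)
  stopifnot(quality_threshold >= 0, homopolymer_slack >= 0,
            fuzzy_max_mismatch_per_10bp >= 0)
  structure(list(adapter_mode = adapter_mode,
                 fuzzy_max_mismatch_per_10bp =
                   as.integer(fuzzy_max_mismatch_per_10bp),
                 remove_ambiguous = isTRUE(remove_ambiguous),
                 remove_singletons = isTRUE(remove_singletons),
                 quality_threshold = quality_threshold,
                 homopolymer_slack = as.integer(homopolymer_slack),
                 single_sample_singleton_fallback =
                   single_sample_singleton_fallback,
                 trim_adapter = isTRUE(trim_adapter),
                 demultiplex = isTRUE(demultiplex),
                 filter_length = isTRUE(filter_length),
                 trim_primers = isTRUE(trim_primers),
                 filter_quality = isTRUE(filter_quality)),
            class = "pipeline_config")
}

#' Strip 3' poly-N tails
#'
#' Removes the maximal terminal run of `N` bases (and their quality
#' values) from the 3' end of each read; internal `N`s are untouched.
#' Reads that become empty are handed to the adapter step's discard set by
#' the pipeline driver.
#'
#' @param reads a [read_set()].
#' @return the read set with tails removed.
#' @export
strip_polyN <- function(reads) {
  keep_len <- nchar(sub("N+$", "", reads$sequence))
  rs_trim(reads, 0L, keep_len)
}

#' Trim adapter B from the 3' end
#'
#' Finds the rightmost occurrence of any of the supplied adapter B
#' sequences and removes it together with everything 3' of it. A
#' 3'-terminal exact prefix of an adapter (at least 4 bases) at the very
#' end of the read also counts, covering reads that run into but do not
#' span the adapter. In `"fuzzy"` mode a full-adapter occurrence may carry
#' up to `ceiling(nchar(adapter)/10) * fuzzy_budget` mismatches (no
#' indels). When several adapters match at the same position the longest
#' wins. Reads with no match are returned in `unmatched_ids` and are
#' discarded by [run_pipeline()].
#'
#' @param reads a [read_set()] (poly-N tails already stripped).
#' @param adapters character vector of adapter B sequences.
#' @param mode `"perfect"` or `"fuzzy"`.
#' @param fuzzy_budget mismatch budget per 10 adapter bases.
#' @param min_prefix minimum length for the terminal partial-adapter rule.
#' @return list with `kept` (trimmed read set) and `unmatched_ids`.
#' @export
trim_adapter_b <- function(reads, adapters, mode = c("perfect", "fuzzy"),
                           fuzzy_budget = 1L, min_prefix = 4L) {
  mode <- match.arg(mode)
  stopifnot(length(adapters) >= 1)
  adapters <- toupper(adapters)
  cut <- vapply(seq_len(nrow(reads)), function(i)
    adapter_cut_position(reads$sequence[i], adapters, mode, fuzzy_budget,
                         min_prefix), integer(1))
  matched <- cut >= 0L
  kept <- rs_trim(rs_subset(reads, matched), 0L, cut[matched])
  list(kept = kept, unmatched_ids = reads$read_id[!matched])
}

# 0-based cut position (number of bases kept) of the best adapter match in
# `s`, or -1L if none. Rightmost occurrence wins; at equal position the
# longest adapter wins.
adapter_cut_position <- function(s, adapters, mode, fuzzy_budget,
                                 min_prefix) {
  n <- nchar(s)
  best_pos <- -1L
  best_len <- -1L
  consider <- function(pos, len) {
    if (pos > best_pos || (pos == best_pos && len > best_len)) {
      best_pos <<- pos
      best_len <<- len
    }
  }
  for (ad in adapters) {
    la <- nchar(ad)
    # full occurrences
    if (la <= n) {
      if (mode == "perfect") {
        occ <- gregexpr(ad, s, fixed = TRUE)[[1]]
        if (occ[1] != -1L)
          consider(max(occ) - 1L, la)
      } else {
        budget <- ceiling(la / 10) * fuzzy_budget
        for (start in seq_len(n - la + 1L)) {
          mm <- count_mismatches(substr(s, start, start + la - 1L), ad)
          if (mm <= budget) consider(start - 1L, la)
        }
      }
    }
    # exact terminal prefix of the adapter at the very read end
    maxp <- min(la - 1L, n)
    if (maxp >= min_prefix) {
      for (p in maxp:min_prefix) {
        if (substr(s, n - p + 1L, n) == substr(ad, 1L, p)) {
          consider(n - p, p)
          break
        }
      }
    }
  }
  best_pos
}

count_mismatches <- function(a, b) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  sum(av != bv)
}

#' Filter reads containing ambiguous bases
#'
#' @param reads a [read_set()] (adapter already trimmed).
#' @return list with `kept` and `discarded_ids` (reads with >= 1 `N`).
#' @export
filter_ambiguous <- function(reads) {
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  list(kept = rs_subset(reads, !has_n),
       discarded_ids = reads$read_id[has_n])
}

#' Demultiplex reads by 5' barcode
#'
#' The unique barcode that is an exact prefix of the read (the barcode set
#' is prefix-free, so at most one matches) is removed together with its
#' quality values and the read is tagged with that barcode's sample.
#' If the specs define exactly one sample and no barcodes, the step passes
#' reads through tagged with that sample.
#'
#' @param reads a [read_set()].
#' @param specs list of `primer_barcode_spec` objects.
#' @return list with `kept` (tagged, barcode-stripped) and
#'   `unassigned_ids`.
#' @export
demultiplex <- function(reads, specs) {
  bm <- combined_barcode_map(specs)
  if (length(bm) == 0L) {
    samples <- unique(unlist(lapply(specs, `[[`, "sample_ids")))
    if (length(samples) != 1L)
      stop("no barcodes defined but ", length(samples),
           " samples present; demultiplexing is ambiguous")
    kept <- reads
    kept$sample_id <- samples
    return(list(kept = kept, unassigned_ids = character(0)))
  }
  sample <- rep(NA_character_, nrow(reads))
  bclen <- rep(0L, nrow(reads))
  for (i in seq_along(bm)) {
    hit <- is.na(sample) & startsWith(reads$sequence, bm[[i]])
    sample[hit] <- names(bm)[i]
    bclen[hit] <- nchar(bm[[i]])
  }
  assigned <- !is.na(sample)
  kept <- rs_subset(reads, assigned)
  kept <- rs_trim(kept, bclen[assigned], nchar(kept$sequence))
  kept$sample_id <- sample[assigned]
  list(kept = kept, unassigned_ids = reads$read_id[!assigned])
}

combined_barcode_map <- function(specs) {
  bm <- unlist(lapply(specs, `[[`, "barcode_map"))
  if (is.null(bm)) bm <- character(0)
  # parse-time validation guarantees global distinctness/prefix-freeness
  bm
}

#' Remove cross-sample singletons
#'
#' A sequence (compared by exact string identity, before primer trimming)
#' is kept only if it occurs in at least two distinct samples in the whole
#' dataset; sequences seen several times but in a single sample are still
#' removed, which is deliberately stricter than a plain copy-number cutoff
#' because PCR chimeras can be amplified many times within one sample.
#' With exactly one sample in the run the criterion is undefined and
#' `fallback` applies.
#'
#' @param reads a demultiplexed [read_set()].
#' @param fallback `"min_two_copies"` (require >= 2 copies) or `"skip"`.
#' @return list with `kept` and `discarded_ids`.
#' @export
remove_cross_sample_singletons <- function(reads,
                                           fallback = c("min_two_copies",
                                                        "skip")) {
  fallback <- match.arg(fallback)
  n_samples <- length(unique(reads$sample_id[!is.na(reads$sample_id)]))
  if (n_samples <= 1L) {
    if (fallback == "skip")
      return(list(kept = reads, discarded_ids = character(0)))
    cnt <- table(reads$sequence)
    keep <- cnt[reads$sequence] >= 2L
  } else {
    nsamp <- tapply(reads$sample_id, reads$sequence,
                    function(s) length(unique(s)))
    keep <- nsamp[reads$sequence] >= 2L
  }
  keep <- as.vector(keep)
  list(kept = rs_subset(reads, keep),
       discarded_ids = reads$read_id[!keep])
}

#' Per-amplicon length filter
#'
#' Each read is assigned to the amplicon whose forward primer matches its
#' 5' end (homopolymer-tolerantly, see [trim_primers()]); reads matching no
#' forward primer cannot be length-checked and are discarded here. A read
#' is kept iff its current length (after adapter and barcode removal,
#' before primer removal) lies in the amplicon's inclusive
#' `[min_len, max_len]` range.
#'
#' @param reads a [read_set()].
#' @param specs list of `primer_barcode_spec` objects.
#' @param homopolymer_slack passed to the forward-primer matcher.
#' @return list with `kept` (amplicon-tagged) and `discarded_ids`.
#' @export
filter_length <- function(reads, specs, homopolymer_slack = 3L) {
  amp <- assign_amplicon(reads, specs, homopolymer_slack)
  len <- nchar(reads$sequence)
  keep <- !is.na(amp)
  if (any(keep)) {
    lo <- vapply(specs, `[[`, integer(1), "min_len")
    hi <- vapply(specs, `[[`, integer(1), "max_len")
    names(lo) <- names(hi) <- vapply(specs, `[[`, character(1),
                                     "amplicon_id")
    keep[keep] <- len[keep] >= lo[amp[keep]] & len[keep] <= hi[amp[keep]]
  }
  kept <- rs_subset(reads, keep)
  kept$amplicon_id <- amp[keep]
  list(kept = kept, discarded_ids = reads$read_id[!keep])
}

# amplicon_id per read via forward-primer prefix match; longest matched
# primer wins when several amplicons match. NA when none matches.
assign_amplicon <- function(reads, specs, homopolymer_slack) {
  amp <- rep(NA_character_, nrow(reads))
  best <- rep(-1L, nrow(reads))
  for (sp in specs) {
    m <- vapply(reads$sequence, function(s)
      match_primer_5p(s, sp$forward_primer, homopolymer_slack),
      integer(1), USE.NAMES = FALSE)
    better <- m > 0L & nchar(sp$forward_primer) > best
    amp[better] <- sp$amplicon_id
    best[better] <- nchar(sp$forward_primer)
  }
  amp
}

# Number of read bases consumed by the forward primer at the 5' end, or
# -1L if the primer does not match. The primer must match exactly except
# its 3'-terminal homopolymer run (when >= 2 bases long): that run may
# appear in the read with up to `slack` extra or missing bases (never
# fewer than 1); a read run longer than run+slack is only absorbed up to
# run+slack bases.
match_primer_5p <- function(s, primer, slack) {
  np <- nchar(primer)
  r <- terminal_run_length(primer)
  if (r < 2L || slack == 0L) {
    return(if (nchar(s) >= np && substr(s, 1L, np) == primer) np else -1L)
  }
  ch <- substr(primer, np, np)
  stem <- substr(primer, 1L, np - r)
  ns <- nchar(stem)
  if (nchar(s) < ns + 1L || (ns > 0L && substr(s, 1L, ns) != stem))
    return(-1L)
  k <- run_length_at(s, ns + 1L, ch)
  if (k < max(1L, r - slack)) return(-1L)
  ns + min(k, r + slack)
}

# Number of read bases consumed at the 3' end by the reverse complement of
# the reverse primer, or -1L. The tolerant homopolymer run is the terminal
# run of the reverse-complemented primer, i.e. the run at the read's 3'
# extremity; its length in the read may deviate by up to `slack` bases and
# the whole variant run is trimmed with the primer.
match_primer_3p <- function(s, rev_primer, slack) {
  rc <- revcomp(rev_primer)
  np <- nchar(rc)
  r <- terminal_run_length(rc)
  n <- nchar(s)
  if (r < 2L || slack == 0L) {
    return(if (n >= np && substr(s, n - np + 1L, n) == rc) np else -1L)
  }
  ch <- substr(rc, np, np)
  stem <- substr(rc, 1L, np - r)
  ns <- nchar(stem)
  # maximal terminal run of `ch` at the very end of the read
  k <- 0L
  while (n - k >= 1L && substr(s, n - k, n - k) == ch) k <- k + 1L
  if (k < max(1L, r - slack) || k > r + slack) return(-1L)
  if (n < ns + k ||
      (ns > 0L && substr(s, n - k - ns + 1L, n - k) != stem))
    return(-1L)
  ns + k
}

#' Trim PCR primers with homopolymer tolerance
#'
#' The forward primer must match the 5' end of the read and the reverse
#' complement of the reverse primer must match the 3' end. Matching is
#' exact ("perfect identity") except for the primer-terminal homopolymer
#' run facing the insert: 454 chemistry generates run-length variants at
#' homopolymers, so when the primer ends in a run of two or more identical
#' bases the read may carry that run with up to `homopolymer_slack` extra
#' or missing bases, and the whole variant run is absorbed into the trim.
#' Quality values for all removed bases are removed in lockstep. Reads
#' failing either primer are no-matches and are discarded by the driver.
#'
#' @param reads a [read_set()] with `amplicon_id` assigned (reads without
#'   one are matched against every spec, longest forward primer first).
#' @param specs list of `primer_barcode_spec` objects.
#' @param homopolymer_slack run-length deviation tolerated (default 3).
#' @return list with `kept` (insert-only reads) and `unmatched_ids`.
#' @export
trim_primers <- function(reads, specs, homopolymer_slack = 3L) {
  if (all(is.na(reads$amplicon_id)) && nrow(reads) > 0L) {
    reads$amplicon_id <- assign_amplicon(reads, specs, homopolymer_slack)
  }
  spec_by_id <- stats::setNames(specs, vapply(specs, `[[`, character(1),
                                              "amplicon_id"))
  from <- integer(nrow(reads))
  to <- integer(nrow(reads))
  ok <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    aid <- reads$amplicon_id[i]
    if (is.na(aid) || is.null(spec_by_id[[aid]])) next
    sp <- spec_by_id[[aid]]
    s <- reads$sequence[i]
    f <- match_primer_5p(s, sp$forward_primer, homopolymer_slack)
    if (f < 0L) next
    b <- match_primer_3p(s, sp$reverse_primer, homopolymer_slack)
    if (b < 0L) next
    if (f + b >= nchar(s)) next  # primers overlap: no insert left
    ok[i] <- TRUE
    from[i] <- f
    to[i] <- nchar(s) - b
  }
  kept <- rs_trim(rs_subset(reads, ok), from[ok], to[ok])
  list(kept = kept, unmatched_ids = reads$read_id[!ok])
}

#' Mean-quality filter
#'
#' Keeps a read iff the arithmetic mean of its remaining quality values
#' (everything belonging to adapter, barcode and primers has already been
#' removed) is at least `threshold`; strictly lower means discarded. Reads
#' left empty by trimming are discarded.
#'
#' @param reads a fully trimmed [read_set()].
#' @param threshold minimum mean quality.
#' @return list with `kept` and `discarded_ids`.
#' @export
filter_quality <- function(reads, threshold) {
  mq <- vapply(reads$qualities, function(q)
    if (length(q)) mean(q) else -Inf, numeric(1))
  keep <- mq >= threshold
  list(kept = rs_subset(reads, keep),
       discarded_ids = reads$read_id[!keep])
}

#' Dereplicate reads into a non-redundant sequence set
#'
#' Groups fully processed reads by exact string identity -- no alignment is
#' performed, so two sequences differing only by an indel are deliberately
#' kept as independent variants (454 homopolymer indels downstream of the
#' primers are treated as informative). Records pooled and per-sample copy
#' numbers and ranks variants by descending pooled frequency, ties broken
#' lexicographically by sequence.
#'
#' @param reads a [read_set()] with sample assignments.
#' @return list of class `derep_result` with elements `pooled` (data frame
#'   `rank`, `sequence`, `frequency`), `links` (data frame `rank`,
#'   `sample_id`, `frequency`; the pooled-to-sample frequency relation) and
#'   `per_sample` (data frame `sample_id`, `amplicon_id`, `sequence`,
#'   `frequency`).
#' @export
dereplicate <- function(reads) {
  if (nrow(reads) == 0L) {
    empty <- data.frame(rank = integer(0), sequence = character(0),
                        frequency = integer(0), stringsAsFactors = FALSE)
    return(structure(list(pooled = empty,
                          links = data.frame(rank = integer(0),
                                             sample_id = character(0),
                                             frequency = integer(0)),
                          per_sample = data.frame(sample_id = character(0),
                                                  amplicon_id = character(0),
                                                  sequence = character(0),
                                                  frequency = integer(0))),
                     class = "derep_result"))
  }
  cnt <- table(reads$sequence)
  ord <- order(-as.integer(cnt), names(cnt))
  pooled <- data.frame(rank = seq_along(ord),
                       sequence = names(cnt)[ord],
                       frequency = as.integer(cnt)[ord],
                       stringsAsFactors = FALSE)
  rank_of <- stats::setNames(pooled$rank, pooled$sequence)
  sid <- ifelse(is.na(reads$sample_id), "(unassigned)", reads$sample_id)
  link_cnt <- stats::aggregate(list(frequency = rep(1L, nrow(reads))),
                               by = list(rank = rank_of[reads$sequence],
                                         sample_id = sid),
                               FUN = sum)
  link_cnt <- link_cnt[order(link_cnt$rank, link_cnt$sample_id), ]
  rownames(link_cnt) <- NULL
  aid <- ifelse(is.na(reads$amplicon_id), "(unassigned)", reads$amplicon_id)
  ps <- stats::aggregate(list(frequency = rep(1L, nrow(reads))),
                         by = list(sample_id = sid, amplicon_id = aid,
                                   sequence = reads$sequence),
                         FUN = sum)
  ps <- ps[order(ps$sample_id, -ps$frequency, ps$sequence), ]
  rownames(ps) <- NULL
  structure(list(pooled = pooled, links = link_cnt, per_sample = ps),
            class = "derep_result")
}

#' @export
print.derep_result <- function(x, ...) {
  cat("non-redundant set:", nrow(x$pooled), "variants,",
      sum(x$pooled$frequency), "reads,",
      length(unique(x$links$sample_id)), "samples\n")
  invisible(x)
}

step_log <- function(step_name, n_in, kept_ids, discarded_ids,
                     parameters = list()) {
  list(step_name = step_name, n_in = n_in,
       n_kept = n_in - length(discarded_ids),
       n_discarded = length(discarded_ids),
       discarded_ids = as.character(discarded_ids),
       parameters = parameters)
}

#' Run the full seven-step cleaning pipeline
#'
#' Executes, in order: (1) poly-N stripping plus adapter B trimming,
#' (2) ambiguity filtering, (3) barcode demultiplexing, (4) cross-sample
#' singleton removal, (5) per-amplicon length filtering, (6) homopolymer
#' aware primer trimming, (7) mean-quality filtering; then dereplicates
#' the survivors. Singleton removal deliberately precedes primer trimming
#' (the cross-sample criterion is evaluated on the pre-primer-trim
#' strings), and new singletons created by the final quality filter are
#' left in the data set. One log entry is emitted per step whether or not
#' the step is enabled.
#'
#' @param reads a [read_set()] of raw reads.
#' @param specs list of `primer_barcode_spec` objects.
#' @param sample_info optional `sample_info` data frame; when given, every
#'   sample named by a barcode must be present in it (checked before any
#'   processing).
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `reads` (final read set),
#'   `derep` (a `derep_result`), `logs` (list of 7 step logs) and
#'   `config`.
#' @export
run_pipeline <- function(reads, specs, sample_info = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(sample_info)) {
    spec_samples <- unique(unlist(lapply(specs, `[[`, "sample_ids")))
    missing <- setdiff(spec_samples, sample_info$sample_id)
    if (length(missing))
      stop("sample(s) in primer & barcode file absent from sample info: ",
           paste(missing, collapse = ", "))
  }
  logs <- vector("list", 7L)
  cur <- reads

  # 1. poly-N stripping + adapter B
  n_in <- nrow(cur)
  if (config$trim_adapter) {
    stripped <- strip_polyN(cur)
    empty_ids <- stripped$read_id[nchar(stripped$sequence) == 0L]
    stripped <- rs_subset(stripped, nchar(stripped$sequence) > 0L)
    adapters <- unique(vapply(specs, `[[`, character(1), "adapter_b"))
    tr <- trim_adapter_b(stripped, adapters, mode = config$adapter_mode,
                         fuzzy_budget = config$fuzzy_max_mismatch_per_10bp)
    cur <- tr$kept
    disc <- c(empty_ids, tr$unmatched_ids)
  } else disc <- character(0)
  logs[[1]] <- step_log("adapter_b", n_in, cur$read_id, disc,
                        list(enabled = config$trim_adapter,
                             mode = config$adapter_mode,
                             fuzzy_budget = config$fuzzy_max_mismatch_per_10bp))

  # 2. ambiguity filter
  n_in <- nrow(cur)
  if (config$remove_ambiguous) {
    st <- filter_ambiguous(cur)
    cur <- st$kept
    disc <- st$discarded_ids
  } else disc <- character(0)
  logs[[2]] <- step_log("ambiguity", n_in, cur$read_id, disc,
                        list(enabled = config$remove_ambiguous))

  # 3. demultiplex
  n_in <- nrow(cur)
  if (config$demultiplex) {
    st <- demultiplex(cur, specs)
    cur <- st$kept
    disc <- st$unassigned_ids
  } else disc <- character(0)
  logs[[3]] <- step_log("demultiplex", n_in, cur$read_id, disc,
                        list(enabled = config$demultiplex,
                             n_barcodes = length(combined_barcode_map(specs))))

  # 4. cross-sample singleton removal
  n_in <- nrow(cur)
  if (config$remove_singletons) {
    st <- remove_cross_sample_singletons(
      cur, fallback = config$single_sample_singleton_fallback)
    cur <- st$kept
    disc <- st$discarded_ids
  } else disc <- character(0)
  logs[[4]] <- step_log("singletons", n_in, cur$read_id, disc,
                        list(enabled = config$remove_singletons,
                             fallback = config$single_sample_singleton_fallback))

  # 5. length filter
  n_in <- nrow(cur)
  if (config$filter_length) {
    st <- filter_length(cur, specs, config$homopolymer_slack)
    cur <- st$kept
    disc <- st$discarded_ids
  } else disc <- character(0)
  logs[[5]] <- step_log("length", n_in, cur$read_id, disc,
                        list(enabled = config$filter_length))

  # 6. primer trimming
  n_in <- nrow(cur)
  if (config$trim_primers) {
    st <- trim_primers(cur, specs, config$homopolymer_slack)
    cur <- st$kept
    disc <- st$unmatched_ids
  } else disc <- character(0)
  logs[[6]] <- step_log("primers", n_in, cur$read_id, disc,
                        list(enabled = config$trim_primers,
                             homopolymer_slack = config$homopolymer_slack))

  # 7. quality filter
  n_in <- nrow(cur)
  if (config$filter_quality) {
    st <- filter_quality(cur, config$quality_threshold)
    cur <- st$kept
    disc <- st$discarded_ids
  } else disc <- character(0)
  logs[[7]] <- step_log("quality", n_in, cur$read_id, disc,
                        list(enabled = config$filter_quality,
                             threshold = config$quality_threshold))

  structure(list(reads = cur, derep = dereplicate(cur), logs = logs,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run:", x$logs[[1]]$n_in, "reads in,",
      nrow(x$reads), "retained\n")
  for (i in seq_along(x$logs)) {
    s <- x$logs[[i]]
    cat(sprintf("  %d %-12s in %6d  discarded %6d\n", i, s$step_name,
                s$n_in, s$n_discarded))
  }
  invisible(x)
}
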