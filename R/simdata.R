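# Synthetic 454-style amplicon datasets with per-step ground truth.
#
# Reads are assembled as
#   barcode + forward primer + template + revcomp(reverse primer)
#   + adapter B [+ poly-N tail]
# and defects are injected at stated rates. Ground truth (which read the
# pipeline should discard at which step) is NOT obtained by running the
# pipeline: it is re-derived here by a deliberately naive, loop-based
# re-statement of each step's rule, so that the generator's bookkeeping is
# an independent oracle for the pipeline implementation.

run_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

sim_defaults <- function() {
  list(poly_n = 0.10,        # benign 3' poly-N tail
       adapter_missing = 0.03,
       adapter_mutated = 0.05,  # one mismatch; recoverable in fuzzy mode
       adapter_truncated = 0.05, # benign: only a 6-base adapter prefix
       internal_n = 0.04,
       barcode_bad = 0.02,
       chimera = 0.02,       # two templates spliced (jumping PCR)
       low_quality = 0.03,
       hp_slip = 0.05)       # +-1 base in the primer-terminal homopolymer
}

sim_template_fractions <- function() {
  list(singleton = 0.15,     # planted in a single sample only
       offlen = 0.10,        # amplicon length outside [min_len, max_len]
       badprimer = 0.10,     # mutated reverse primer (fails step 6)
       indel_variant = 0.20) # extra template differing by one indel
}

#' Generate a synthetic 454 amplicon dataset with ground truth
#'
#' Builds reads with the canonical 454 amplicon layout (barcode, forward
#' primer, insert, reverse-complemented reverse primer, adapter B,
#' optional poly-N tail), injects defects at the stated rates, and records
#' for every read which pipeline step -- if any -- should discard it. The
#' expectation is computed by an internal naive re-statement of each
#' step's rule over the actual read contents, so interactions between
#' defects (e.g. a chimera that also becomes a cross-sample singleton) are
#' attributed to the first fatal step under the supplied configuration.
#'
#' @param n_reads number of reads.
#' @param n_samples number of barcoded samples (max 8 with the built-in
#'   barcode pool).
#' @param n_templates number of underlying true sequence variants.
#' @param defect_rates named list overriding the default per-read defect
#'   rates (see `ampliconDB:::sim_defaults()`); all in `[0, 1]`.
#' @param template_fractions named list overriding the default fractions
#'   of templates planted as singletons, off-length, reverse-primer
#'   mutants and indel variants.
#' @param quality_profile list with `mean`, `sd` (per-base truncated
#'   normal), `tail_frac`/`tail_drop` (linear 3' degradation) and
#'   `low_mean` (mean for planted low-quality reads).
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param config the [pipeline_config()] the ground truth is computed for.
#' @param dir if non-`NULL`, writes `reads.fasta`, `reads.qual`,
#'   `primer_barcode.tsv`, `sample_info.tsv` and `ground_truth.tsv` there.
#' @return list with `reads` (a [read_set()]), `specs`, `sample_info`,
#'   and `truth`: `per_read` (read_id, template_id, sample_id, defects,
#'   first_fatal_step 1..7 or 0 when retained), `expected_discards` (list
#'   of 7 read-id vectors), `expected_counts` (step, n_in, n_discarded),
#'   `retained` (read_id, sample_id, final_sequence after naive trimming).
#' @export
generate_dataset <- function(n_reads = 1000L, n_samples = 4L,
                             n_templates = 20L,
                             defect_rates = list(),
                             template_fractions = list(),
                             quality_profile = list(mean = 35, sd = 5,
                                                    tail_frac = 0.2,
                                                    tail_drop = 10,
                                                    low_mean = 15),
                             seed = 1L,
                             config = pipeline_config(),
                             dir = NULL) {
  rates <- utils::modifyList(sim_defaults(), defect_rates)
  frac <- utils::modifyList(sim_template_fractions(), template_fractions)
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1),
            n_samples >= 1, n_samples <= 8, n_templates >= 4)
  qp <- utils::modifyList(list(mean = 35, sd = 5, tail_frac = 0.2,
                               tail_drop = 10, low_mean = 15),
                          quality_profile)

  fwd <- "GTGCCAGCAGCCGCGGTAA"       # ends in an AA homopolymer (run 2)
  rev <- "CCGTCAATTCCTTTGAGTTT"      # revcomp starts with AAA (run 3)
  adapter <- "CTGAGACTGCCAAGG"
  rc_rev <- revcomp(rev)
  barcode_pool <- c("ACAG", "CGTAC", "GTACCA", "TACGG",
                    "AAGG", "CCTTA", "GGATCC", "TTCA")
  samples <- paste0("s", seq_len(n_samples))
  barcodes <- stats::setNames(barcode_pool[seq_len(n_samples)], samples)
  min_len <- 100L
  max_len <- 300L

  out <- run_with_seed(seed, {
    # --- templates ------------------------------------------------------
    rand_template <- function(len) {
      x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # keep the bases adjacent to the primer-terminal homopolymers
      # distinct from those runs so trimming boundaries are exact
      if (x[1] == "A") x[1] <- sample(c("C", "G", "T"), 1)
      if (x[len] == "A") x[len] <- sample(c("C", "G", "T"), 1)
      paste(x, collapse = "")
    }
    n_role <- function(f) if (f <= 0) 0L else
      max(1L, as.integer(round(f * n_templates)))
    n_singleton <- n_role(frac$singleton)
    n_offlen <- n_role(frac$offlen)
    n_badprimer <- n_role(frac$badprimer)
    n_variant <- n_role(frac$indel_variant)

    tlen <- sample(120:200, n_templates, replace = TRUE)
    role <- rep("normal", n_templates)
    idx <- sample(n_templates)
    role[idx[seq_len(n_singleton)]] <- "singleton"
    role[idx[n_singleton + seq_len(n_offlen)]] <- "offlen"
    role[idx[n_singleton + n_offlen + seq_len(n_badprimer)]] <- "badprimer"
    tlen[role == "offlen"] <- rep_len(c(30L, 320L), sum(role == "offlen"))
    templates <- vapply(tlen, rand_template, character(1))
    template_id <- paste0("t", seq_len(n_templates))

    # indel variants: one extra base inserted mid-template, planted as
    # additional templates so they occur in >= 2 samples and survive as
    # separate dereplication entries
    donors <- sample(which(role == "normal"),
                     min(n_variant, sum(role == "normal")))
    for (d in donors) {
      s <- templates[d]
      pos <- sample(10:(nchar(s) - 10), 1)
      v <- paste0(substr(s, 1, pos), substr(s, pos, pos),
                  substr(s, pos + 1, nchar(s)))
      templates <- c(templates, v)
      role <- c(role, "variant")
      template_id <- c(template_id, paste0(template_id[d], "v"))
      tlen <- c(tlen, nchar(v))
    }
    ntpl <- length(templates)

    # sample assignment plan: singletons in exactly one sample, all other
    # templates in >= 2 samples (when the run has >= 2)
    tpl_samples <- lapply(seq_len(ntpl), function(i) {
      if (n_samples == 1L) return(samples)
      if (role[i] == "singleton") sample(samples, 1) else
        sample(samples, sample(2:n_samples, 1))
    })
    weights <- 1 / seq_len(ntpl)   # rank-abundance

    # --- per-read assembly ---------------------------------------------
    tpl_of <- sample(seq_len(ntpl), n_reads, replace = TRUE,
                     prob = weights)
    read_id <- sprintf("r%05d", seq_len(n_reads))
    seqs <- character(n_reads)
    quals <- vector("list", n_reads)
    samp <- character(n_reads)
    defects <- character(n_reads)

    for (i in seq_len(n_reads)) {
      ti <- tpl_of[i]
      samp[i] <- if (length(tpl_samples[[ti]]) == 1L) tpl_samples[[ti]]
      else sample(tpl_samples[[ti]], 1)
      def <- character(0)
      tpl <- templates[ti]
      if (role[ti] != "normal") def <- c(def, role[ti])

      if (stats::runif(1) < rates$chimera) {
        other <- sample(setdiff(seq_len(ntpl), ti), 1)
        t2 <- templates[other]
        tpl <- paste0(substr(tpl, 1, nchar(tpl) %/% 2),
                      substr(t2, nchar(t2) %/% 2 + 1, nchar(t2)))
        if (substr(tpl, nchar(tpl), nchar(tpl)) == "A")
          tpl <- paste0(substr(tpl, 1, nchar(tpl) - 1), "C")
        def <- c(def, "chimera")
      }
      if (stats::runif(1) < rates$internal_n) {
        pos <- sample(5:(nchar(tpl) - 4), 1)
        substr(tpl, pos, pos) <- "N"
        def <- c(def, "internal_n")
      }

      bc <- barcodes[[samp[i]]]
      if (stats::runif(1) < rates$barcode_bad) {
        first <- substr(bc, 1, 1)
        substr(bc, 1, 1) <- sample(setdiff(c("A", "C", "G", "T"), first), 1)
        def <- c(def, "barcode_bad")
      }

      fwd_part <- fwd
      if (stats::runif(1) < rates$hp_slip) {
        delta <- sample(c(-1L, 1L), 1)
        fwd_part <- paste0(substr(fwd, 1, nchar(fwd) - 2),
                           strrep("A", 2L + delta))
        def <- c(def, "hp_slip")
      }

      rc_part <- rc_rev
      if (role[ti] == "badprimer") {
        cur <- substr(rc_part, 10, 10)
        substr(rc_part, 10, 10) <-
          setdiff(c("A", "C", "G", "T"), cur)[1]
      }

      fate <- sample(c("normal", "missing", "mutated", "truncated"), 1,
                     prob = c(1 - rates$adapter_missing -
                                rates$adapter_mutated -
                                rates$adapter_truncated,
                              rates$adapter_missing,
                              rates$adapter_mutated,
                              rates$adapter_truncated))
      ad_part <- switch(fate,
        normal = adapter,
        missing = "",
        mutated = {
          a <- adapter
          cur <- substr(a, 3, 3)
          substr(a, 3, 3) <- setdiff(c("A", "C", "G", "T"), cur)[1]
          a
        },
        truncated = substr(adapter, 1, 6))
      if (fate != "normal") def <- c(def, paste0("adapter_", fate))

      tailN <- if (stats::runif(1) < rates$poly_n) {
        def <- c(def, "poly_n")
        strrep("N", sample(2:8, 1))
      } else ""

      s <- paste0(bc, fwd_part, tpl, rc_part, ad_part, tailN)
      lowq <- stats::runif(1) < rates$low_quality
      if (lowq) def <- c(def, "low_quality")
      quals[[i]] <- sim_qualities(nchar(s), nchar(tailN),
                                  if (lowq) qp$low_mean else qp$mean,
                                  qp$sd, qp$tail_frac, qp$tail_drop)
      seqs[i] <- s
      defects[i] <- paste(def, collapse = ",")
    }

    specs <- list(structure(list(amplicon_id = "amp1",
                                 forward_primer = fwd,
                                 reverse_primer = rev,
                                 adapter_b = adapter,
                                 min_len = min_len, max_len = max_len,
                                 barcode_map = barcodes,
                                 sample_ids = samples),
                            class = "primer_barcode_spec"))

    temps <- rep_len(c(8, 15, 25, 12, 30, 21, 5, 17), n_samples)
    si <- data.frame(sample_id = samples,
                     temperature = temps,
                     pH = round(stats::runif(n_samples, 6, 9), 1),
                     site = rep_len(c("lake", "river"), n_samples),
                     stringsAsFactors = FALSE)
    class(si) <- c("sample_info", "data.frame")

    reads <- read_set(read_id, seqs, quals)
    truth <- naive_ground_truth(reads, specs, config)
    truth$per_read <- data.frame(read_id = read_id,
                                 template_id = template_id[tpl_of],
                                 sample_id = samp,
                                 defects = defects,
                                 first_fatal_step = truth$first_fatal,
                                 stringsAsFactors = FALSE)
    truth$first_fatal <- NULL
    list(reads = reads, specs = specs, sample_info = si, truth = truth)
  })

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta_qual(out$reads, file.path(dir, "reads.fasta"),
                     file.path(dir, "reads.qual"))
    write_primer_barcode_file(out$specs,
                              file.path(dir, "primer_barcode.tsv"))
    utils::write.table(out$sample_info, file.path(dir, "sample_info.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth$per_read,
                       file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

sim_qualities <- function(len, n_tail, mean, sd, tail_frac, tail_drop) {
  q <- round(stats::rnorm(len, mean, sd))
  ntail <- floor(len * tail_frac)
  if (ntail > 0) {
    drop <- seq(0, tail_drop, length.out = ntail)
    q[(len - ntail + 1):len] <- q[(len - ntail + 1):len] - round(drop)
  }
  if (n_tail > 0) q[(len - n_tail + 1):len] <- 3L
  pmin(pmax(as.integer(q), 0L), 40L)
}

# ---------------------------------------------------------------------
# Naive re-statement of the seven step rules, used only for ground truth.
# Written as plain per-read loops, independent of the pipeline functions.
# ---------------------------------------------------------------------

naive_adapter_cut <- function(s, adapters, mode, budget, min_prefix = 4L) {
  n <- nchar(s)
  best <- c(pos = -1L, len = -1L)
  for (ad in adapters) {
    la <- nchar(ad)
    allow <- if (mode == "fuzzy") ceiling(la / 10) * budget else 0L
    if (la <= n) {
      for (start in 1:(n - la + 1L)) {
        win <- substr(s, start, start + la - 1L)
        mm <- if (win == ad) 0L else if (allow == 0L) la else {
          m <- 0L
          for (j in 1:la)
            if (substr(win, j, j) != substr(ad, j, j)) m <- m + 1L
          m
        }
        if (mm <= allow) {
          pos <- start - 1L
          if (pos > best["pos"] ||
              (pos == best["pos"] && la > best["len"]))
            best <- c(pos = pos, len = la)
        }
      }
    }
    for (p in min(la - 1L, n):min_prefix) {
      if (p < min_prefix) break
      if (substr(s, n - p + 1L, n) == substr(ad, 1L, p)) {
        pos <- n - p
        if (pos > best["pos"] ||
            (pos == best["pos"] && p > best["len"]))
          best <- c(pos = pos, len = p)
        break
      }
    }
  }
  unname(best["pos"])
}

naive_match5p <- function(s, primer, slack) {
  np <- nchar(primer)
  last <- substr(primer, np, np)
  r <- 0L
  while (np - r >= 1L && substr(primer, np - r, np - r) == last)
    r <- r + 1L
  if (r < 2L || slack == 0L)
    return(if (substr(s, 1L, np) == primer && nchar(s) >= np) np else -1L)
  stem <- substr(primer, 1L, np - r)
  if (substr(s, 1L, nchar(stem)) != stem) return(-1L)
  k <- 0L
  while (nchar(stem) + k + 1L <= nchar(s) &&
         substr(s, nchar(stem) + k + 1L, nchar(stem) + k + 1L) == last)
    k <- k + 1L
  if (k < max(1L, r - slack)) return(-1L)
  nchar(stem) + min(k, r + slack)
}

naive_match3p <- function(s, rev_primer, slack) {
  rc <- revcomp(rev_primer)
  np <- nchar(rc)
  last <- substr(rc, np, np)
  r <- 0L
  while (np - r >= 1L && substr(rc, np - r, np - r) == last) r <- r + 1L
  n <- nchar(s)
  if (r < 2L || slack == 0L)
    return(if (n >= np && substr(s, n - np + 1L, n) == rc) np else -1L)
  stem <- substr(rc, 1L, np - r)
  ns <- nchar(stem)
  k <- 0L
  while (n - k >= 1L && substr(s, n - k, n - k) == last) k <- k + 1L
  if (k < max(1L, r - slack) || k > r + slack) return(-1L)
  if (n < ns + k || substr(s, n - k - ns + 1L, n - k) != stem)
    return(-1L)
  ns + k
}

naive_ground_truth <- function(reads, specs, config) {
  n <- nrow(reads)
  seqs <- reads$sequence
  quals <- reads$qualities
  samp <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  fatal <- rep(0L, n)
  expected <- vector("list", 7L)
  adapters <- unique(vapply(specs, `[[`, character(1), "adapter_b"))
  bm <- unlist(lapply(specs, `[[`, "barcode_map"))
  slack <- config$homopolymer_slack

  kill <- function(step, dead) {
    fatal[dead] <<- step
    alive[dead] <<- FALSE
    expected[[step]] <<- reads$read_id[dead]
  }

  # 1: poly-N + adapter B
  dead <- logical(n)
  if (config$trim_adapter) {
    for (i in which(alive)) {
      s <- sub("N+$", "", seqs[i])
      if (nchar(s) == 0L) { dead[i] <- TRUE; next }
      cut <- naive_adapter_cut(s, adapters, config$adapter_mode,
                               config$fuzzy_max_mismatch_per_10bp)
      if (cut < 0L) { dead[i] <- TRUE; next }
      seqs[i] <- substr(s, 1L, cut)
      quals[[i]] <- quals[[i]][seq_len(cut)]
    }
  }
  kill(1L, which(dead))

  # 2: ambiguities
  dead <- config$remove_ambiguous & alive &
    grepl("N", seqs, fixed = TRUE)
  kill(2L, which(dead))

  # 3: barcodes
  dead <- logical(n)
  if (config$demultiplex) {
    for (i in which(alive)) {
      hit <- NA_character_
      for (j in seq_along(bm))
        if (startsWith(seqs[i], bm[[j]])) { hit <- names(bm)[j]; break }
      if (length(bm) == 0L) {
        samp[i] <- specs[[1]]$sample_ids[1]
      } else if (is.na(hit)) dead[i] <- TRUE
      else {
        samp[i] <- hit
        keep <- nchar(seqs[i]) - nchar(bm[[hit]])
        seqs[i] <- substr(seqs[i], nchar(bm[[hit]]) + 1L, nchar(seqs[i]))
        quals[[i]] <- quals[[i]][(length(quals[[i]]) - keep + 1L):
                                   length(quals[[i]])]
        if (keep == 0L) quals[[i]] <- integer(0)
      }
    }
  }
  kill(3L, which(dead))

  # 4: cross-sample singletons
  dead <- logical(n)
  if (config$remove_singletons) {
    live <- which(alive)
    nsample <- length(unique(samp[live][!is.na(samp[live])]))
    if (nsample <= 1L) {
      if (config$single_sample_singleton_fallback == "min_two_copies") {
        cnt <- table(seqs[live])
        for (i in live) if (cnt[[seqs[i]]] < 2L) dead[i] <- TRUE
      }
    } else {
      per <- tapply(samp[live], seqs[live],
                    function(x) length(unique(x)))
      for (i in live) if (per[[seqs[i]]] < 2L) dead[i] <- TRUE
    }
  }
  kill(4L, which(dead))

  # 5: amplicon length
  amp <- rep(NA_character_, n)
  dead <- logical(n)
  if (config$filter_length) {
    for (i in which(alive)) {
      best <- -1L
      for (sp in specs) {
        if (naive_match5p(seqs[i], sp$forward_primer, slack) > 0L &&
            nchar(sp$forward_primer) > best) {
          best <- nchar(sp$forward_primer)
          amp[i] <- sp$amplicon_id
        }
      }
      if (is.na(amp[i])) { dead[i] <- TRUE; next }
      sp <- specs[[match(amp[i],
                         vapply(specs, `[[`, character(1),
                                "amplicon_id"))]]
      if (nchar(seqs[i]) < sp$min_len || nchar(seqs[i]) > sp$max_len)
        dead[i] <- TRUE
    }
  }
  kill(5L, which(dead))

  # 6: primer trimming
  dead <- logical(n)
  if (config$trim_primers) {
    for (i in which(alive)) {
      aid <- amp[i]
      if (is.na(aid)) {
        for (sp in specs)
          if (naive_match5p(seqs[i], sp$forward_primer, slack) > 0L) {
            aid <- sp$amplicon_id; break
          }
      }
      if (is.na(aid)) { dead[i] <- TRUE; next }
      sp <- specs[[match(aid, vapply(specs, `[[`, character(1),
                                     "amplicon_id"))]]
      f <- naive_match5p(seqs[i], sp$forward_primer, slack)
      b <- naive_match3p(seqs[i], sp$reverse_primer, slack)
      if (f < 0L || b < 0L || f + b >= nchar(seqs[i])) {
        dead[i] <- TRUE
        next
      }
      seqs[i] <- substr(seqs[i], f + 1L, nchar(seqs[i]) - b)
      quals[[i]] <- quals[[i]][(f + 1L):(length(quals[[i]]) - b)]
    }
  }
  kill(6L, which(dead))

  # 7: quality
  dead <- logical(n)
  if (config$filter_quality) {
    for (i in which(alive)) {
      if (length(quals[[i]]) == 0L ||
          mean(quals[[i]]) < config$quality_threshold)
        dead[i] <- TRUE
    }
  }
  kill(7L, which(dead))

  for (k in 1:7) if (is.null(expected[[k]])) expected[[k]] <- character(0)
  counts <- data.frame(step = 1:7,
                       n_discarded = vapply(expected, length, integer(1)))
  counts$n_in <- n - c(0L, cumsum(counts$n_discarded)[-7])
  list(expected_discards = expected,
       expected_counts = counts[c("step", "n_in", "n_discarded")],
       retained = data.frame(read_id = reads$read_id[alive],
                             sample_id = samp[alive],
                             final_sequence = seqs[alive],
                             stringsAsFactors = FALSE),
       first_fatal = fatal)
}
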