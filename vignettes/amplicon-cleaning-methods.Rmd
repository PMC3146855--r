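---
title: "Methods: cleaning, storing and querying 454 amplicon surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleaning, storing and querying 454 amplicon surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`ampliconDB`, in the spirit of the methods sections that accompany
mature sequence-processing packages. It states no empirical result that
the test suite does not itself compute.

## The read model

A 454 amplicon read is modelled as

    barcode + forward_primer + insert + revcomp(reverse_primer)
            + adapter_B [+ poly-N tail]

with per-base phred-style qualities carried in a paired QUAL file. All
trimming operations remove sequence and quality values in lockstep, and
every pipeline step satisfies the conservation law
`n_in = n_kept + n_discarded` with the retained and discarded id-sets
partitioning its input; these invariants are enforced in code and
re-checked by property tests.

## The seven cleaning steps and their parameters

**1. Poly-N stripping and adapter B removal.** The maximal terminal run
of `N` is removed first, then the *rightmost* occurrence of any
configured adapter B is located and everything from its first base to
the read end is cut. Two extensions matter in practice:

* *Terminal partial adapters.* A read shorter than the full template
  truncates adapter B. An exact prefix of an adapter, at least 4 bases
  long, at the very end of the read therefore counts as a match. Four
  bases is the shortest prefix whose chance occurrence at a fixed
  position (1/256) does not dominate genuine truncations; the rule stays
  exact even in fuzzy mode because a mismatch budget over arbitrarily
  short prefixes would match almost any read end.
* *Fuzzy mode* (`adapter_mode = "fuzzy"`) tolerates mismatches — no
  indels — up to `ceiling(len/10) * fuzzy_max_mismatch_per_10bp`
  (default 1 per started 10 bp) in full-adapter occurrences. Ties
  between adapters matching at the same position go to the longest
  adapter, so nested adapters of different lengths resolve
  deterministically.

Reads with no match are discarded: an amplicon read that never reaches
adapter B cannot be assumed complete, and treating no-match as benign
would leak adapter fragments into downstream variants.

**2. Ambiguity filter.** Any remaining `N` discards the read. Applied
after adapter trimming so that poly-N tails do not needlessly kill
otherwise clean reads.

**3. Demultiplexing.** Barcodes may have different lengths; the parser
rejects any barcode set in which one barcode is a prefix of another, so
at most one barcode can match a read and the assignment is unambiguous
without alignment. Single-sample runs may omit barcodes entirely; the
step then tags reads with the lone sample and discards nothing.

**4. Cross-sample singleton removal.** A sequence string (compared
*before* primer trimming) is kept only if it occurs in at least two
distinct samples. This is intentionally stricter than a copy-number
cutoff: a chimera formed in an early PCR cycle can be abundant within
its sample but is unlikely to arise independently in a second one.
Consequently a variant seen five times in one sample is still removed.
For single-sample runs the criterion is undefined;
`single_sample_singleton_fallback` selects either the older two-copy
rule (`"min_two_copies"`, default) or skipping the step. Combining the
raw reads of several runs (`combine_and_reprocess()`) before filtering
is the supported way to rescue true low-frequency variants.

**5. Length filter.** Reads are assigned to an amplicon by matching
each spec's forward primer at the 5' end (homopolymer-tolerantly, see
step 6); among multiple matches the longest primer wins. Reads matching
no forward primer have no length contract to check and are discarded
here. Bounds are inclusive and are checked on the read *after* adapter
and barcode removal but *before* primer removal, i.e. on
`primer + insert + primer`.

**6. Primer trimming with homopolymer slack.** 454 chemistry estimates
homopolymer lengths from flow intensities and gets them wrong at a rate
that grows with run length; the diagnostic failure mode is a run-length
variant where a primer meets the insert. Primers must match with
perfect identity *except* for the tolerant homopolymer run, which must
be at least 2 bases long in the primer (`homopolymer_slack`, default 3,
caps the deviation; slack 0 restores strict matching):

* *Forward primer:* its 3'-terminal run (insert-facing) may appear in
  the read with between `max(1, r - slack)` and `r + slack` bases. If
  the read's run is even longer — possible when the insert itself
  begins with the same base — only `r + slack` bases are absorbed and
  the excess stays with the insert. This keeps such reads rather than
  discarding them, at the cost of occasionally leaving a genuine
  sequencing surplus on the insert; the alternative (rejecting) would
  systematically lose every template starting with the primer's last
  base.
* *Reverse primer:* its reverse complement is matched at the 3' end;
  the tolerant run is the terminal run of the reverse-complemented
  primer, i.e. the run at the read's 3' extremity. Here there is no
  "excess stays" case — the run ends at the read end — so a deviation
  beyond the slack is a no-match.

Both primers must match for a read to survive: a missing reverse primer
means the read did not span the amplicon, so its 3' boundary — and
hence its variant identity under indel-informative dereplication — is
unknown.

**7. Quality filter.** The arithmetic mean of the qualities remaining
after all trimming (adapter, barcode, primer values removed) must be at
least `quality_threshold`; strictly lower is discarded, so a read
exactly at the threshold is kept. The default of 25 is a conventional
mid-stringency choice for 454 amplicon data; 0 disables the filter.
Reads trimmed to zero length are discarded here. New singletons created
by this step deliberately remain in the data set — re-running the
singleton filter would conflate two different error models.

Every step can be disabled individually; a disabled step logs
`n_discarded = 0` and passes reads through, so the seven-section log is
always complete.

## Dereplication

Retained reads are grouped by exact string identity — no alignment, so
two sequences differing only by an indel are distinct variants (454
homopolymer indels downstream of the primers carry signal). Variants
are ranked by descending pooled copy number; ties are broken
lexicographically by sequence, an arbitrary but deterministic rule
chosen so that output files and database rows are byte-stable across
runs. Pooled frequency always equals the sum of the per-sample link
rows, which the store's `audit_store()` re-checks in SQL.

## The datastore

The original design created a fresh set of seven tables per uploaded
dataset. This package keeps the same seven relations — sample info,
primer/barcode info, raw reads, redundant (trimmed) reads, pooled
non-redundant, per-sample non-redundant, pooled-to-sample links — but
scopes rows with a `dataset_id` foreign key in a static schema on
embedded SQLite: identical per-dataset semantics, but auditable with
ordinary foreign-key checks and no runtime DDL. Uploads run in a single
transaction (a partially written dataset would corrupt the statistics
contract), discarded-read identities are persisted so the
reproducibility log can be regenerated from the store, and manual
taxonomy edits live in their own column beside — never instead of —
the automatic assignment, with editor and timestamp.

## Query semantics

The six filter axes combine by AND, matching the "restrict the search"
reading of the original interface; within the metadata axis a sample
must satisfy *every* listed constraint. Numeric ranges are inclusive on
both bounds (a stated example like "temperature 10–20 °C" naturally
includes its endpoints); categorical variables use equality, and a
range over a categorical variable is an error rather than a silent
empty result. The taxon axis is a case-insensitive substring match
against the *effective* path — the edited path when present, else the
assigned one. Random subsampling draws reads (frequency-expanded, so
abundant variants are proportionally likely) *without replacement*:
rarefaction-style downstream analyses assume subsets of the observed
reads, and with-replacement draws would inflate singleton counts.
Requesting more reads than the pool holds is an explicit error, never a
silent truncation. A fixed seed reproduces the identical draw; the seed
is applied in a local RNG scope so library calls do not perturb user
RNG state.

## Sample-information typing

Variables are typed per column: if every non-missing value in a column
parses as a number the column is numeric, otherwise all its values are
kept as categorical strings. A column mixing `15` and `10-20` is
therefore categorical as a whole — per-cell typing would make range
semantics depend on which rows happen to be present. Empty cells are
missing (`NA`) and never satisfy any constraint.

## The synthetic-data generator and what a green test means

`generate_dataset()` emulates the artifacts the pipeline is built to
remove: poly-N tails (10 % of reads), missing / one-mismatch / truncated
adapter B (3 / 5 / 5 %), internal Ns (4 %), corrupted barcodes (2 %),
chimeras spliced from two templates (2 %), low-quality reads (3 %,
per-base mean 15 instead of 35), and ±1 homopolymer slips at the
forward-primer junction (5 %). Template-level roles plant single-sample
sequences (15 % of templates), off-range lengths (10 %), reverse-primer
mutants (10 %) and one-indel variants of donor templates (20 %).
Qualities are truncated normal per base (mean 35, sd 5, clipped to
0–40) with a linear drop of up to 10 over the final 20 % of the read.
These rates are this package's choices — stated once here, fixed in
`sim_defaults()`, and not tuned against test outcomes.

Ground truth is *not* produced by running the pipeline: the generator
re-derives every step's outcome with deliberately naive per-read loops
over the reads it just built, attributing each read to its first fatal
step under the configured step order. Interactions therefore resolve
exactly — e.g. a chimeric read is usually removed as a singleton (step
4) rather than at a "chimera step" that does not exist, and a
homopolymer-slipped read whose slipped string fails to recur in a
second sample is likewise a step-4 casualty. The test suite adds a
third, independent brute-force implementation (regexes and exhaustive
enumeration) for the per-filter oracle-equivalence checks, so no rule
is ever checked against itself.

The generator does **not** emulate flowgram-level error models, SFF
artifacts, chimera breakpoint hotspots, length-dependent quality
structure beyond the linear tail, or cross-talk between barcodes. A
green suite therefore establishes that the implementation honors its
stated rules on data with these artifact classes — not that the
defaults are optimal for any particular real survey.

## Known limitations

* FASTQ and SFF input are out of scope (the paired FASTA+QUAL
  convention of the 454 toolchain is the only reader); chimera
  detection by alignment is delegated to the singleton rule; rarefaction
  and OTU clustering are left to external tools over exported FASTA.
* The similarity search behind taxonomy assignment is an external hook:
  the package consumes its tabular output and applies the
  closest-hit rule (lowest e-value, then highest bit score, then
  lexicographic subject id — the last tie-break is arbitrary but makes
  the result independent of hit-file row order). No identity or
  e-value cutoff is applied unless requested.
* The store is single-writer; concurrent multi-user access was part of
  the original web deployment and is out of scope here.
* The step order is fixed in `run_pipeline()` and the CLI:
  demultiplexing must precede singleton removal because the
  cross-sample criterion needs sample assignments. Users who need a
  different composition can chain the individually exported step
  functions themselves.
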