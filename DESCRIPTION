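Package: ampliconDB
Title: Cleaning, Storing and Querying 454 Amplicon Survey Data
Version: 0.1.0
Authors@R: person("ampliconDB", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A stand-alone re-implementation of the classic 454 amplicon
    survey workflow: a seven-step read-cleaning pipeline (adapter B and
    poly-N trimming, ambiguity filtering, barcode demultiplexing,
    cross-sample singleton removal, per-amplicon length filtering,
    homopolymer-aware PCR primer trimming, mean-quality filtering)
    followed by indel-informative dereplication; an embedded relational
    store holding raw reads, trimmed reads, non-redundant sequence sets
    and sample metadata for multiple datasets; a six-axis query and
    random-subsampling interface over the stored sequences; closest-hit
    taxonomic path assignment from tabular similarity-search output; and
    a synthetic-data generator with per-step ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
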