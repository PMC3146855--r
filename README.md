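# ampliconDB

Cleaning, storing and querying 454 pyrosequencing amplicon surveys.

PCR-amplicon surveys on the 454 platform produced hundreds of thousands
of reads per run, each laid out as

```
5'  [barcode] [forward primer] [insert] [revcomp(reverse primer)] [adapter B] [poly-N]  3'
```

with platform-specific artifacts: read-through into adapter B, ambiguous
bases, homopolymer run-length errors at and after the primers, chimeras
from jumping PCR, and quality decay toward the 3' end. Ecologists and
clinicians running such surveys also need to keep many runs organized
and to ask questions that join sequences to sample metadata ("which
variants occur in water samples between 10 and 20 °C?").

`ampliconDB` is a stand-alone R package covering that workflow end to
end:

1. **Seven-step read cleaning** (`run_pipeline()`), each step
   individually configurable and separately logged:
   1. poly-N stripping and adapter B trimming (perfect or
      mismatch-tolerant matching, multiple adapters of different
      lengths, exact terminal adapter prefixes ≥ 4 bp);
   2. removal of reads with ≥ 1 ambiguous base;
   3. demultiplexing by prefix-free, variable-length 5' barcodes;
   4. cross-sample singleton removal: a sequence is kept only if it
      occurs in ≥ 2 distinct samples, a deliberately strict chimera
      filter (a chimera amplified early in PCR can be abundant within
      one sample, but is unlikely to recur independently in another);
   5. per-amplicon length filtering against the spec's inclusive
      `[min_len, max_len]`;
   6. primer trimming requiring perfect identity except for the
      primer-terminal homopolymer run, whose length may vary by a
      configurable slack (454 misestimates homopolymer lengths);
   7. mean-quality filtering: keep iff mean(phred) ≥ threshold.
2. **Indel-informative dereplication** (`dereplicate()`): exact-string
   grouping — variants differing by a single indel stay separate —
   ranked by descending pooled copy number with per-sample frequencies.
3. **An embedded relational store** (`ads_connect()`,
   `upload_dataset()`, `combine_and_reprocess()`, ...): a single-file
   SQLite database holding, per dataset, raw reads, trimmed reads, the
   pooled and per-sample non-redundant sets, the pooled-to-sample
   frequency links, primer/barcode and sample metadata, per-step
   statistics and discarded-read identities. Uploads are atomic;
   combining raw reads from several runs and re-processing them rescues
   true low-frequency variants that look like singletons in each run
   alone.
4. **Six-axis querying** (`select_sequences()`, `random_subsample()`,
   `sequence_abundance()`): datasets × amplicons × samples × metadata
   ranges × taxonomic group × seeded random subsampling without
   replacement.
5. **Closest-hit taxonomy** (`assign_taxonomic_path()`): consumes
   standard 12-column tabular similarity-search output plus a lineage
   map; the best hit per query is lowest e-value, then highest bit
   score, then lexicographic subject id. Manual corrections
   (`set_edited_taxonomy()`) never overwrite the automatic assignment.
6. **A synthetic-data generator** (`generate_dataset()`) that plants
   every artifact class at stated rates and records, per read, the
   pipeline step that should discard it — the package's own test
   oracle.

## Worked example

```r
library(ampliconDB)

sim <- generate_dataset(n_reads = 1000, n_samples = 4, seed = 42)
res <- run_pipeline(sim$reads, sim$specs, sim$sample_info,
                    pipeline_config(quality_threshold = 25))
res
#> pipeline run: 1000 reads in, 473 retained
#>   1 adapter_b    in   1000  discarded     85
#>   2 ambiguity    in    915  discarded     34
#>   3 demultiplex  in    881  discarded     14
#>   4 singletons   in    867  discarded    282
#>   5 length       in    585  discarded     48
#>   6 primers      in    537  discarded     52
#>   7 quality      in    485  discarded     12
```

Each line is one cleaning step: reads entering it and reads it
discarded (85 reads had no recognizable adapter B, 34 contained an N,
14 carried no known barcode, 282 sequences did not recur in a second
sample, and so on; counts chain, so 473 survive). The survivors
dereplicate into a ranked non-redundant set:

```r
res$derep
#> non-redundant set: 17 variants, 473 reads, 4 samples
head(res$derep$pooled$frequency, 3)
#> [1] 112  70  48
```

Store the run and query by sample metadata (the simulated samples carry
temperatures 8, 15, 25 and 12 °C):

```r
store <- ads_connect(":memory:")   # or a file path
id <- upload_dataset(store, sim$reads, sim$specs, sim$sample_info,
                     name = "demo run")
summary_statistics(store, id)      # the per-step elimination table

sel <- select_sequences(store,
         query_filter(ranges = list(temperature = c(10, 20))))
unique(sel$sample_id)
#> [1] "s2" "s4"                    # exactly the 15 and 12 degree samples
ads_disconnect(store)
```

The same operations are available from the shell through the wrapper in
`inst/scripts/ampliconDB` (subcommands `simulate`, `upload`,
`reprocess`, `query`, `abundance`, `edit-sample`, `edit-taxonomy`,
`assign-taxonomy`, `stats`, `delete`, `export`).

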