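# orfkit

Ribosome profiling (Ribo-Seq) identifies open reading frames (ORFs) that are
actively translated, including thousands of *noncanonical* ORFs — translated
regions that are not annotated CDSs nor in-frame variants of one. Published
counts of these ORFs vary by orders of magnitude because different calling
algorithms, replicates and datasets disagree, each catalog uses its own
nomenclature and inclusion rules, and the proteomic evidence behind any
individual ORF ranges from none to rigorous two-peptide detection.

`orfkit` is an R toolkit for the analysis layer that sits on top of ORF
callers, for researchers comparing callers, harmonizing published smORF
catalogs, or triaging candidates for annotation:

- **Domain model & I/O** — transcript models from GTF, ORF call sets from
  BED12 or a provenance-carrying TSV dialect; 0-based half-open coordinates
  internally; stop codons included in stored coordinates but excluded from
  reported lengths.
- **Classification** — each ORF is assigned one of the six standardized
  noncanonical categories (uORF, uoORF, intORF, doORF, dORF, lncRNA-ORF) or
  flagged as an in-frame CDS variant, by comparing its transcript-space
  interval `o = [o_s, o_e)` and frame with the annotated CDS `c = [c_s, c_e)`.
- **Similarity clustering** — two calls are *similar* when one's exonic base
  set is fully contained in the other's, both share the stop codon, and the
  shorter covers at least a fraction *f* of the longer (lengths in nt,
  stops excluded). Similarity is merged transitively: connected components
  of the similarity graph are the *unique ORFs*, enabling
  replicate-sharing curves, category compositions and length distributions.
- **Catalog harmonization** — the ≥16 aa / AUG inclusion filter with
  internal-AUG rescue, dataset-dialect label remapping (Duffy, Ouspenskaia,
  Chothani dialects ship with the package), pseudogene and small-RNA
  exclusions, and cross-dataset replication counting by exact amino-acid
  sequence (meta-catalogs reported against but never counted as support).
- **Ribo-Seq QC** — codon periodicity (in-frame fraction of 28–30 nt
  footprints over annotated CDSs; ≥70% pass, 60–70% gray, <60% fail),
  CDS-mapping fraction (pass iff >80%), detected-CDS counting (>9000 at
  human scale) and footprint-yield arithmetic (15–30% of sequenced reads).
- **Evidence tiers** — the tiered evidence framework for noncanonical ORFs,
  including the HUPO/HPP two-peptide rule (≥2 nonnested, uniquely mapping
  tryptic peptides, each ≥9 aa, total residue extent ≥18): tiers 1A
  "Protein candidate", 1B "Presented", 2A/2B "Detected", 3 "Putative",
  4 "Ribo-Seq ORF", 5 "Predicted".
- **Synthetic data** — seeded generators for transcriptomes, multi-caller /
  multi-replicate call sets with known ground truth (start-site jitter
  around shared stops, dropout, spurious calls, category bias), P-site
  tables with tunable periodicity, and peptide-evidence scenarios, so the
  whole pipeline is testable without downloads.

## Worked example

```r
library(orfkit)

txs <- gen_transcriptome(n_coding = 40, n_noncoding = 10, seed = 11)
profiles <- list(
  caller_profile("alpha", jitter_prob = 0.3, dropout_prob = 0.2,
                 spurious_rate = 2),
  caller_profile("beta", jitter_prob = 0.1, dropout_prob = 0.4,
                 spurious_rate = 1, category_bias = c(intORF = 1.5)))
sim <- gen_orf_callsets(txs, c(uORF = 10, uoORF = 4, intORF = 6, doORF = 4,
                               dORF = 6, `lncRNA-ORF` = 6),
                        profiles, n_replicates = 6, seed = 12)

pooled <- unlist(lapply(sim$callsets, unlist, recursive = FALSE),
                 recursive = FALSE, use.names = FALSE)
clusters <- build_unique_clusters(pooled, min_frac = 0.9)
cat("calls:", length(pooled), " unique ORFs:", nrow(clusters), "\n")
#> calls: 331  unique ORFs: 69
```

331 individual calls across 2 callers × 6 replicates collapse to 69 unique
ORFs at a 90% overlap threshold (36 true ORFs plus spurious singletons).
Composition among well-replicated clusters (≥3 replicate/caller
combinations) recovers the simulated category mix:

```r
category_composition(clusters, k = 3)
#>     category  n  percent
#> 1      doORF  4 10.52632
#> 2       dORF  7 18.42105
#> 3     intORF  7 18.42105
#> 4 lncRNA-ORF  6 15.78947
#> 5      uoORF  4 10.52632
#> 6       uORF 10 26.31579

replicate_sharing_curve(sim$callsets$alpha, min_frac_grid = c(0.5, 0.9),
                        k_values = c(1, 3, 6))
#>   min_frac k n_unique_shared
#> 1      0.5 1              48
#> 2      0.5 3              36
#> 3      0.5 6              10
#> 4      0.9 1              62
#> 5      0.9 3              34
#> 6      0.9 6               5
```

The sharing table reads: at a lenient 50% overlap threshold caller
"alpha" yields 48 unique ORFs, 36 of which appear in ≥3 of its 6
replicates; tightening the threshold to 90% splits jittered variants into
more unique ORFs (62) and fewer survive all six replicates — the
threshold/replication trade-off that drives disagreement between callers.

QC on a synthetic P-site table (true periodicity 0.72, 20,000 footprints):

```r
ps <- gen_psite_table(txs, periodicity = 0.72, depth = 20000, seed = 13)
qc <- qc_report(ps, total_reads = 150e6, detected_cds_threshold = 10L)
#> periodicity 0.712 (pass), CDS mapping 0.846 (pass),
#> detected CDSs 40 (pass)
footprint_yield(150e6)
#>      low     high
#> 22500000 45000000
```

A 150-million-read library is expected to yield 22.5–45 million usable
footprints; the measured periodicity 0.712 clears the ≥0.70 pass boundary
and 84.6% of footprints map to annotated CDSs (>80% required).

## Command line

```sh
Rscript -e 'orfkit::orfkit_cli()' simulate --n-coding 150 --n-noncoding 50 \
    --seed 1 --outdir sim/
Rscript -e 'orfkit::orfkit_cli()' classify --gtf ref.gtf --orfs calls.tsv \
    --out classified.tsv
Rscript -e 'orfkit::orfkit_cli()' qc --psites psites.tsv --total-reads 150000000 \
    --out qc.json
```

(Subcommands: `validate`, `convert`, `simulate`, `classify`, `compare`,
`qc`, `tier`, `harmonize`; `inst/cli/orfkit` is an equivalent launcher.)

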