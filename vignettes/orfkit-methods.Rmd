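---
title: "orfkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orfkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfkit)
```

# Scope and model

`orfkit` implements the analysis layer above Ribo-Seq ORF callers: given
transcript annotations and per-caller, per-replicate ORF call sets, it
classifies each call into the standardized noncanonical categories, merges
similar calls into unique ORFs, summarizes reproducibility across
replicates and callers, harmonizes heterogeneous published catalogs,
computes library-level quality metrics, and assigns tiered proteogenomic
evidence classes. It deliberately does *not* run callers, align reads,
search spectra, predict HLA binding, or handle pseudogene/repeat-derived
ORFs.

## Coordinates and the stop-codon convention

All internal coordinates are 0-based half-open. GTF input (1-based
inclusive) is converted at the boundary; BED12 passes through unchanged.
Two fixed, non-configurable rules remove a whole class of off-by-three
ambiguities:

* stored ORF coordinates **include** the stop codon;
* reported ORF lengths (`orf_nt_length`, cluster length distributions,
  overlap fractions) **exclude** it.

A minimal ORF — a start codon directly followed by a stop — therefore
occupies 6 nt and has reported length 3 nt (1 codon). The ≥16-amino-acid
catalog filter corresponds to 48 nt excluding the stop.

On minus-strand transcripts, transcript coordinate 0 is the genomically
rightmost exonic base; `to_transcript_coords` is length-preserving and
strictly monotone on both strands, and each ORF block must lie within a
single exon (a block spanning two genomically adjacent exons is treated as
a mapping error rather than silently fused).

## Category assignment

With `o = [o_s, o_e)` the ORF and `c = [c_s, c_e)` the CDS, both in
transcript coordinates with stops included, and
`frame = (o_s - c_s) mod 3`, the decision order is:

1. no CDS on the transcript → **lncRNA-ORF**;
2. `o == c` → canonical (identical);
3. `frame == 0` and `o_e == c_e` → canonical N-extension/N-truncation by
   start comparison;
4. `o_e <= c_s` → **uORF** (an ORF whose stop abuts the CDS start still
   lies entirely upstream, so it is a uORF, not a uoORF — overlap must be
   physical);
5. `o_s < c_s < o_e <= c_e` → **uoORF**;
6. `c_s <= o_s` and `o_e <= c_e`, `frame != 0` → **intORF**; the
   `frame == 0` variant of this geometry would imply two different stops
   for one frame on one transcript and raises a validation error;
7. `c_s <= o_s < c_e < o_e` → **doORF**;
8. `o_s >= c_e` → **dORF**;
9. anything remaining (intervals spanning the whole CDS with a different
   stop, e.g. readthrough-like in-frame overlaps) → canonical
   `other_in_frame`, flagged but never silently dropped or guessed.

The order is a total function: a property test sweeps randomized intervals
and checks that every mappable ORF receives exactly one category, and that
`+`/`-` strand constructions of the same transcript-space geometry agree.
Classification is strictly per `(ORF, transcript_id)` pair; no
cross-isoform reconciliation is attempted.

## Similarity and unique ORFs

Call `a` is similar to call `b` at fraction `f` when (i) `a`'s exonic base
set is a subset of `b`'s, (ii) both have identical chromosome, strand and
stop-codon position, and (iii) `len(a) >= f * len(b)` with lengths in nt
excluding stops. Using stop-exclusive lengths keeps overlap fractions
consistent with reported length distributions, so results are reproducible
bit-exactly from the documentation alone.

Similarity relations are merged transitively — a chain A ⊂ B ⊂ C with a
shared stop is one unique ORF — which is implemented as connected
components of the undirected similarity graph (`igraph`). The test suite
checks equivalence against an independent brute-force oracle (explicit
base-position sets, all-pairs similarity, union-find) on hundreds of
random instances, plus two monotonicity properties: lowering `f` never
increases the number of unique clusters, and the number of clusters shared
by ≥ k replicates is non-increasing in k.

A `strict_junctions` mode additionally requires the child's internal
splice junctions to be a subset of the parent's. It defaults to off: plain
base-set containment is the documented relation, and the strict mode exists
only to guard against spurious containment across incompatible splice
forms.

The cluster representative is the longest member (ties broken by smallest
`orf_id`), so with jitter-only noise the representative recovers the true
(longest) variant and its length.

## Catalog harmonization

The inclusion filter keeps AUG-initiated entries of ≥16 aa; non-AUG
(near-cognate) entries are re-anchored at their first internal methionine
and kept if the rescued protein is ≥16 aa. The filter is idempotent and its
audit conserves counts (kept + per-reason rejections = input).

Nomenclature remapping applies, in order: pseudogene final-classification
exclusion; small-RNA label/biotype exclusion (rRNA, snoRNA, tRNA, snRNA,
miRNA); then the dataset dialect. The three shipped dialects translate,
e.g., "external" → doORF and "noncoding"/"lncRNA"/"antisense_RNA"/
"misc_RNA"/"TEC"/"processed_transcript" → lncRNA-ORF (Duffy), plotType
labels "3′ dORF" → dORF, "3′ overlap dORF" → doORF, "5′ overlap uORF" →
uoORF, "5′ uORF" → uORF, "out-of-frame" → intORF (Ouspenskaia), and the
final ORF types of Chothani, where "ncORF" → lncRNA-ORF is an *assumed*
one-to-one mapping (the source nomenclature lists it without an explicit
equivalence). Labels are matched case-insensitively after folding
typographic prime variants (3′ vs 3'), because published tables mix
typography. Unknown (dataset, label) pairs raise — there is no silent
default. `EXCLUDED` records are retained with their flag so downstream
accounting balances.

Cross-dataset replication matches ORFs by exact amino-acid sequence after
rescue/filtering. The published catalogs use different genome assemblies
and coordinate conventions, so sequence identity is the only
dataset-neutral key; a coordinate key would require a shared assembly and
liftover, which is out of scope. Meta-analysis catalogs are reported in the
overlap matrix but never counted as primary support. The dialect registry
ships as JSON rather than YAML because the package avoids adding a YAML
parser dependency; the format carries the same dataset → label → category
structure.

## Quality control

* **Codon periodicity**: in-frame fraction of P-site counts over CDS
  positions for 28–30 nt reads, per length and pooled. Frames are defined
  relative to the transcript's CDS start (not genomic phase). Verdicts:
  ≥0.70 pass, 0.60–0.70 gray (usable with caution), <0.60 fail. An empty
  CDS table yields `not_evaluated`, never zero.
* **CDS-mapping fraction**: share of all counts on CDS regions; pass iff
  strictly >0.80.
* **Detected CDSs**: either counted from caller output (calls classified
  as identical to an annotated CDS) or, as a fallback, transcripts with at
  least `min_psites_per_cds` in-frame P-sites. The guideline threshold
  (strictly >9000) presumes a human-scale annotation; at synthetic scale it
  must be overridden and the function warns. Neither operational definition
  is asserted to be the guideline's own — both are exposed.
* **Footprint yield**: exact arithmetic `total_reads × (0.15, 0.30)`; a
  150 M-read library maps to 22.5–45 M expected footprints.
* Library-complexity assessment beyond these metrics (PCR-duplicate/UMI
  modeling) is out of scope: no operational formula exists to implement.
  Likewise, start-site drug-treatment assays (harringtonine/lactimidomycin)
  are only a documentation note here.

All verdict boundaries follow the printed guideline inequalities exactly
and live in a single configuration block (`orfkit:::qc_thresholds`).

## Evidence tiers

The two-peptide rule is satisfied when some subset of ≥2 peptides exists
in which each peptide maps uniquely, is ≥9 residues, no interval is nested
in another (identical intervals count as mutually nested), and the union
of covered residue positions is ≥18. Two disjoint 9-mers pass at exactly
18; two 9-mers overlapping by 8 cover only 10 positions and fail. The
union interpretation of "total extent" is the default; a sum-of-lengths
variant is switchable (`extent_rule = "sum"`). The subset-search
implementation is verified against exhaustive subset enumeration.

Tiers are evaluated in priority order: 1A (Ribo-Seq + qualifying tryptic
pair), 1B (Ribo-Seq + ≥2 HLA observations from ≥2 distinct sources), 2A
(Ribo-Seq + any tryptic evidence failing the full rule), 2B (Ribo-Seq + a
single-source HLA observation), 3 (proteomics without Ribo-Seq), 4
(Ribo-Seq only), 5 (in silico prediction only). A record qualifying for
both 1A and 1B reports 1A with the 1B qualification kept in its reasons.
"Distinct sources" defaults to study/experiment granularity
(`source_id`) and can be switched to `sample_id`; the framework's own
granularity is unspecified, so neither is asserted. The Ribo-Seq
credibility flag is an upstream input (gated on the QC verdicts), not
re-derived here. Tier 2A accepts *any* tryptic evidence failing the full
rule, including peptides shorter than 9 aa — the framework does not state
a lower bound for this tier.

An exhaustive grid over evidence configurations (Ribo-Seq × tryptic × HLA
× prediction, minus the invalid empty cell) verifies that exactly one tier
fires per configuration and that the tier → outcome-label map holds.

# The synthetic world

The generators state one fixed world; their defaults are not tuned to make
tests pass.

* **Transcriptomes**: 1–4 exons per transcript (introns 50–300 nt), UTRs of
  90–240 nt so that every coding transcript can host uORFs and dORFs, CDSs
  of 60–200 codons, lncRNAs of 300–900 nt. The default pipeline scale
  (≈200 transcripts, 6 replicates, a few hundred calls) runs in seconds on
  one CPU; tests scale the instance counts, not the mechanisms.
* **Call sets**: six replicates mirror the replicate structure typical of
  caller comparisons. Jitter moves starts by 1–3 whole codons and never
  crosses the stop codon, mirroring real caller disagreement on start
  sites with shared stops; it is clamped so a jittered call never changes
  its true category (e.g. a uoORF start never slides into the CDS).
  Distinct true ORFs are guaranteed distinct stop codons so the
  ground-truth partition is identifiable by construction. Dropout models
  false negatives; spurious calls (Poisson per replicate, uniform
  placement, random frame, 7–30 codons) model stochastic or pervasive
  translation and carry cluster label `"noise"`. With jitter-only noise,
  clustering at the analytic threshold — the minimum over clusters of
  (shortest member length)/(longest member length) — recovers the
  ground-truth partition exactly, and the acceptance suite asserts this.
* **P-site tables**: each footprint lands on a CDS with probability
  `p_cds = 0.85` (a value inside the >80% CDS-mapping band of a good
  library; the guideline does not fix a simulated value), then in frame 0
  with probability `periodicity`, else uniformly frames 1/2, over 28–30 nt
  read lengths with equal default weights. The estimator-recovery
  acceptance test (100 tables, depth 10,000, true periodicity uniform in
  [0.4, 0.95]) bounds |bias| by 0.005.
* **Peptide evidence**: scenarios pin peptides down exactly (offset,
  length, uniqueness, sample, source), so every tier is constructible by
  design rather than by sampling luck.

What the generators do **not** emulate: sequence-level signal (no genome
FASTA, no codon usage), coverage gradients along ORFs (5′ bias), read-level
artifacts (no FASTQ), isoform ambiguity, or inter-caller correlation
structure beyond the profile parameters. A green synthetic test therefore
establishes the correctness of the analysis machinery, not the realism of
any particular caller's error model.

# Numerical and degenerate-input choices

* Record-level invariant violations (overlapping blocks, length not
  divisible by 3) reject the record into a reasons report and continue;
  file-level syntax errors (malformed GTF line, unknown strand symbol)
  abort. Real caller outputs contain stray rows; truncated files should
  never be half-read.
* Empty inputs return empty tables (`category_composition`,
  `tier_table`), and QC on empty evidence returns `not_evaluated` —
  distinct from a measured zero.
* `k` above the replicate count yields 0 shared clusters, not an error.
* Representative ties break by smallest `orf_id`; percentages are exact
  fractions of 100 (the displayed "±70%" style rounding of published
  overlap figures is left to presentation).
* Generators restore the caller's RNG state; all determinism is through
  explicit seeds.

# Known limitations

* Sequence-based operations require the caller to provide `aa_seq` (or a
  scenario); no genome FASTA translation is built in.
* Coordinate-based catalog matching is available only conceptually behind
  the sequence key; no assembly liftover.
* The detected-CDS rule and the HLA "distinct sources" granularity are both
  exposed as options because their operational definitions are unspecified
  upstream; defaults are documented above.
* Absolute caller-comparison counts from full-scale datasets are out of
  reach at desk scale by design; the package reproduces the machinery and
  verifies it on synthetic ground truth instead.
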