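Package: orfkit
Title: Comparison, Classification and Evidence Tiering of Ribo-Seq ORF Calls
Version: 0.1.0
Authors@R: person("orfkit", "developers", role = c("aut", "cre"),
    email = "orfkit@example.org")
Description: Tools for working with noncanonical open reading frames (ORFs)
    called from ribosome profiling (Ribo-Seq) data: reading transcript
    annotations (GTF) and ORF call sets (BED12/TSV), classifying ORFs into the
    standard noncanonical categories (uORF, uoORF, intORF, doORF, dORF,
    lncRNA-ORF), clustering similar calls across callers and replicates by
    exon containment with a shared stop codon, harmonizing heterogeneous
    published smORF catalogs, computing Ribo-Seq quality-control metrics
    (codon periodicity, CDS-mapping fraction, footprint-yield arithmetic), and
    assigning tiered proteogenomic evidence classes including the HUPO/HPP
    two-peptide rule. A synthetic-data module generates transcriptomes,
    multi-caller call sets with known ground truth, P-site tables and peptide
    evidence so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
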