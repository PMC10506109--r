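# ---------------------------------------------------------------------------
# Harmonization of published smORF catalogs: inclusion filter with internal-
# AUG rescue, dataset-dialect nomenclature remapping, exclusion rules, and
# cross-dataset replication counting.
# ---------------------------------------------------------------------------

# small-RNA labels/biotypes always excluded, regardless of dataset
SMALL_RNA_LABELS <- c("rrna", "snorna", "trna", "snrna", "mirna")

# lower-case, trim, fold typographic prime/quote variants to ASCII '
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[′’´`]", "'", x)
}

#' Trim a translated sequence to its first internal methionine
#'
#' Catalog entries initiated at near-cognate (non-AUG) start codons are
#' rescued by re-anchoring the ORF at the first internal AUG: sequences
#' already starting with `M` are returned unchanged, otherwise the suffix
#' from the first `M` is returned, or `NA` when no methionine exists.
#' Idempotent; never lengthens a sequence.
#'
#' @param aa_seq One-letter amino-acid string.
#' @return Trimmed sequence, or `NA_character_` when no rescue is possible.
#' @export
rescue_internal_aug <- function(aa_seq) {
  if (!is.character(aa_seq) || length(aa_seq) != 1L || is.na(aa_seq) ||
      !nzchar(aa_seq))
    stop("argument error: aa_seq must be a non-empty string")
  if (startsWith(aa_seq, "M")) return(aa_seq)
  pos <- regexpr("M", aa_seq, fixed = TRUE)
  if (pos < 0L) return(NA_character_)
  substring(aa_seq, pos)
}

#' Apply the catalog inclusion filter (AUG start, >= 16 amino acids)
#'
#' AUG-initiated records are kept iff their protein is at least 16 aa long.
#' Non-AUG records are replaced by their internal-AUG rescue
#' ([rescue_internal_aug()]) and kept iff the rescued protein is >= 16 aa.
#' Nothing is silently dropped: the audit table accounts for every input row
#' (kept + rejected = input), with one row per rejection reason.
#'
#' @param records `data.frame` with at least `aa_seq` and `start_codon`
#'   columns (catalog rows; see [harmonize_catalogs()]).
#' @param min_aa Inclusion boundary, default 16 (inclusive).
#' @return List with `kept` (filtered records, `aa_seq` rewritten to the
#'   rescued suffix where rescue occurred, plus a logical `rescued` column)
#'   and `audit` (`data.frame` of `reason`, `n`).
#' @export
apply_inclusion_filter <- function(records, min_aa = 16L) {
  records <- as.data.frame(records)
  stopifnot(all(c("aa_seq", "start_codon") %in% colnames(records)))
  n <- nrow(records)
  keep <- logical(n); rescued <- logical(n); reason <- character(n)
  aa <- records$aa_seq
  is_aug <- toupper(records$start_codon) %in% c("ATG", "AUG")
  for (i in seq_len(n)) {
    s <- aa[i]
    if (!is_aug[i]) {
      s <- rescue_internal_aug(s)
      if (is.na(s)) { reason[i] <- "no internal AUG"; next }
      rescued[i] <- TRUE
      aa[i] <- s
    }
    if (nchar(s) < min_aa) {
      reason[i] <- if (is_aug[i]) "length<16" else "length<16 after rescue"
      next
    }
    keep[i] <- TRUE
  }
  kept <- records[keep, , drop = FALSE]
  kept$aa_seq <- aa[keep]
  kept$rescued <- rescued[keep]
  rownames(kept) <- NULL
  reasons <- c("kept", sort(unique(reason[!keep])))
  audit <- data.frame(
    reason = reasons,
    n = vapply(reasons, function(r)
      if (r == "kept") sum(keep) else sum(reason == r & !keep), integer(1L)),
    row.names = NULL)
  list(kept = kept, audit = audit)
}

#' Load the dataset dialect registry
#'
#' The registry maps each dataset's native category labels onto the
#' standardized vocabulary; the three published dialects (Duffy,
#' Ouspenskaia, Chothani) ship with the package.
#'
#' @param path JSON registry; defaults to the shipped copy.
#' @return Named list: dataset -> named character vector (label -> category).
#' @export
load_dialects <- function(path = system.file("extdata", "dialects.json",
                                             package = "orfkit")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) setNames(unlist(m), normalize_label(names(m))))
}

#' Remap one catalog record's native label to a standardized category
#'
#' Applied in order: (1) records whose final classification is pseudogene
#' are `EXCLUDED`; (2) small-RNA labels or biotypes (rRNA, snoRNA, tRNA,
#' snRNA, miRNA) are `EXCLUDED`; (3) the dataset's dialect table translates
#' the native label. Labels are matched case-insensitively after folding
#' typographic prime variants. Unknown (dataset, label) pairs raise — there
#' is no silent default.
#'
#' @param dataset Registered dataset name.
#' @param source_label Dataset-native category string.
#' @param transcript_biotype,final_classification Optional strings (`NA` ok).
#' @param dialects Registry from [load_dialects()].
#' @return One of [orf_categories()].
#' @export
remap_category <- function(dataset, source_label,
                           transcript_biotype = NA_character_,
                           final_classification = NA_character_,
                           dialects = load_dialects()) {
  if (!is.na(final_classification) &&
      normalize_label(final_classification) == "pseudogene")
    return("EXCLUDED")
  lab <- normalize_label(source_label)
  bio <- if (is.na(transcript_biotype)) "" else
    normalize_label(transcript_biotype)
  if (lab %in% SMALL_RNA_LABELS || bio %in% SMALL_RNA_LABELS)
    return("EXCLUDED")
  dkey <- normalize_label(dataset)
  if (!dkey %in% names(dialects))
    stop("dataset '", dataset, "' not registered in the dialect table")
  map <- dialects[[dkey]]
  if (!lab %in% names(map))
    stop("unknown label '", source_label, "' for dataset '", dataset, "'")
  unname(map[[lab]])
}

#' Harmonize catalog records: filter, rescue, and remap
#'
#' Convenience wrapper running [apply_inclusion_filter()] then
#' [remap_category()] on every kept record. `EXCLUDED` records are retained
#' (flagged, never deleted) so downstream accounting balances.
#'
#' @param records `data.frame` with columns `dataset`, `orf_id`, `aa_seq`,
#'   `start_codon`, `source_label`, and optionally `transcript_biotype`,
#'   `final_classification`.
#' @param dialects Registry from [load_dialects()].
#' @param min_aa Passed to [apply_inclusion_filter()].
#' @return List with `records` (kept rows plus a `category` column),
#'   `audit` (filter audit).
#' @export
harmonize_catalogs <- function(records, dialects = load_dialects(),
                               min_aa = 16L) {
  flt <- apply_inclusion_filter(records, min_aa = min_aa)
  kept <- flt$kept
  if (nrow(kept)) {
    kept$category <- vapply(seq_len(nrow(kept)), function(i) {
      remap_category(kept$dataset[i], kept$source_label[i],
                     if ("transcript_biotype" %in% colnames(kept))
                       kept$transcript_biotype[i] else NA_character_,
                     if ("final_classification" %in% colnames(kept))
                       kept$final_classification[i] else NA_character_,
                     dialects)
    }, character(1L))
  } else {
    kept$category <- character(0L)
  }
  list(records = kept, audit = flt$audit)
}

#' Count replication of each ORF across primary datasets
#'
#' ORFs are matched across catalogs by exact amino-acid sequence after
#' rescue/filtering (the only dataset-neutral key when catalogs use
#' different assemblies). Meta-analysis catalogs (e.g. an aggregate set) are
#' reported against but never counted as primary support.
#'
#' @param records Harmonized records (`dataset`, `orf_id`, `aa_seq`).
#' @param meta_datasets Character vector of dataset names to exclude from
#'   replication counting.
#' @return List with `per_orf` (`aa_seq`, `n_primary_datasets`,
#'   `in_meta` flag, `datasets`) and `overlap` (dataset x dataset matrix of
#'   shared sequences, all datasets included).
#' @export
cross_dataset_replication <- function(records, meta_datasets = character()) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L || length(unique(records$dataset)) == 0L)
    stop("argument error: no datasets in input")
  ds <- sort(unique(records$dataset))
  primary <- setdiff(ds, meta_datasets)
  by_seq <- split(records$dataset, records$aa_seq)
  per_orf <- data.frame(
    aa_seq = names(by_seq),
    n_primary_datasets = vapply(by_seq, function(d)
      length(unique(intersect(d, primary))), integer(1L)),
    in_meta = vapply(by_seq, function(d)
      any(d %in% meta_datasets), logical(1L)),
    datasets = vapply(by_seq, function(d)
      paste(sort(unique(d)), collapse = ","), character(1L)),
    row.names = NULL)
  overlap <- matrix(0L, length(ds), length(ds), dimnames = list(ds, ds))
  seqs_by_ds <- lapply(setNames(ds, ds), function(d)
    unique(records$aa_seq[records$dataset == d]))
  for (a in ds) for (b in ds)
    overlap[a, b] <- length(intersect(seqs_by_ds[[a]], seqs_by_ds[[b]]))
  list(per_orf = per_orf, overlap = overlap)
}

#' Per-dataset summary: ORF counts against profiling effort
#'
#' @param records Harmonized records with a `dataset` column.
#' @param sample_counts,cell_type_counts Named numeric vectors
#'   (dataset -> count).
#' @return `data.frame`, one row per dataset ordered by name, with `n_orfs`,
#'   `n_samples`, `n_cell_types`, `orfs_per_cell_type`, `orfs_per_sample`,
#'   and their `ratio`. Missing or zero metadata leaves the ratios `NA` with
#'   a warning.
#' @export
per_dataset_summary <- function(records, sample_counts, cell_type_counts) {
  ds <- sort(unique(records$dataset))
  rows <- lapply(ds, function(d) {
    n <- sum(records$dataset == d)
    ns <- if (d %in% names(sample_counts)) sample_counts[[d]] else NA_real_
    nc <- if (d %in% names(cell_type_counts)) cell_type_counts[[d]] else NA_real_
    if (is.na(ns) || is.na(nc) || ns == 0 || nc == 0)
      warning("dataset '", d, "': missing or zero metadata; ratios omitted")
    opc <- if (!is.na(nc) && nc > 0) n / nc else NA_real_
    ops <- if (!is.na(ns) && ns > 0) n / ns else NA_real_
    data.frame(dataset = d, n_orfs = n, n_samples = ns, n_cell_types = nc,
               orfs_per_cell_type = opc, orfs_per_sample = ops,
               ratio = if (!is.na(opc) && !is.na(ops) && ops > 0)
                 opc / ops else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
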