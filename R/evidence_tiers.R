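# ---------------------------------------------------------------------------
# Tiered evidence classification for noncanonical ORFs.
#
# Tier 1A "Protein candidate": Ribo-Seq + HUPO/HPP-qualifying tryptic
#   peptides (>=2 nonnested uniquely mapping peptides, each >=9 aa, total
#   residue extent >=18).
# Tier 1B "Presented": Ribo-Seq + >=2 HLA observations from >=2 distinct
#   sources.
# Tier 2A/2B "Detected": Ribo-Seq + any tryptic evidence / a single HLA
#   observation.
# Tier 3 "Putative": proteomic evidence without Ribo-Seq.
# Tier 4 "Ribo-Seq ORF": Ribo-Seq only. Tier 5 "Predicted": in silico only.
# ---------------------------------------------------------------------------

TIER_LABELS <- c("1A" = "Protein candidate", "1B" = "Presented",
                 "2A" = "Detected", "2B" = "Detected", "3" = "Putative",
                 "4" = "Ribo-Seq ORF", "5" = "Predicted")

#' Construct a peptide-evidence table
#'
#' One row per observed peptide, mapped to amino-acid coordinates within its
#' ORF (0-based offset). Used for both tryptic and HLA evidence.
#'
#' @param orf_id,peptide_seq,aa_start,uniquely_mapping,evidence_type,sample_id,source_id
#'   Vectors, recycled to a common length. `evidence_type` is `"tryptic"` or
#'   `"hla"`; `source_id` identifies the study/experiment.
#' @param orf_aa_len Optional ORF protein length for bounds checking.
#' @return `data.frame` with an additional `aa_len` column.
#' @export
peptide_evidence <- function(orf_id, peptide_seq, aa_start,
                             uniquely_mapping = TRUE,
                             evidence_type = "tryptic",
                             sample_id = NA_character_,
                             source_id = NA_character_,
                             orf_aa_len = NA_integer_) {
  if (length(peptide_seq) == 0L)
    return(data.frame(orf_id = character(), peptide_seq = character(),
                      aa_start = integer(), aa_len = integer(),
                      uniquely_mapping = logical(),
                      evidence_type = character(), sample_id = character(),
                      source_id = character()))
  df <- data.frame(orf_id = orf_id, peptide_seq = peptide_seq,
                   aa_start = as.integer(aa_start),
                   aa_len = nchar(peptide_seq),
                   uniquely_mapping = uniquely_mapping,
                   evidence_type = evidence_type,
                   sample_id = sample_id, source_id = source_id,
                   stringsAsFactors = FALSE)
  if (any(df$aa_len < 1L)) stop("peptides must have length >= 1")
  if (any(df$aa_start < 0L)) stop("aa_start must be >= 0")
  if (!is.na(orf_aa_len) && any(df$aa_start + df$aa_len > orf_aa_len))
    stop("argument error: peptide extends beyond the ORF (", orf_aa_len,
         " aa)")
  if (!all(df$evidence_type %in% c("tryptic", "hla")))
    stop("evidence_type must be 'tryptic' or 'hla'")
  df
}

#' Check the HUPO/HPP two-peptide rule for one ORF
#'
#' TRUE iff some subset of >=2 peptides exists in which every peptide maps
#' uniquely and is at least `min_len` residues long, no peptide's residue
#' interval is contained in another's (nonnested; identical intervals are
#' mutually nested), and the union of residue positions covered by the
#' subset spans at least `min_extent` amino acids. The default extent rule
#' is the position-union ("union"); `extent_rule = "sum"` instead sums
#' peptide lengths.
#'
#' @param peptides Tryptic [peptide_evidence()] rows for one ORF (may be
#'   empty).
#' @param min_len Minimum residues per peptide (default 9).
#' @param min_extent Minimum total extent in amino acids (default 18).
#' @param extent_rule `"union"` (default) or `"sum"`.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   every failure encountered; empty on success).
#' @export
hupo_hpp_check <- function(peptides, min_len = 9L, min_extent = 18L,
                           extent_rule = c("union", "sum")) {
  extent_rule <- match.arg(extent_rule)
  if (is.null(peptides) || nrow(peptides) == 0L)
    return(list(pass = FALSE, reasons = "no peptides"))
  reasons <- character()
  cand <- peptides[peptides$uniquely_mapping & peptides$aa_len >= min_len, ,
                   drop = FALSE]
  if (sum(!peptides$uniquely_mapping) > 0L)
    reasons <- c(reasons, "non-uniquely-mapping peptides ignored")
  if (sum(peptides$aa_len < min_len) > 0L)
    reasons <- c(reasons, sprintf("peptides shorter than %d ignored", min_len))
  # deduplicate identical residue intervals: mutually nested, at most one
  # copy can ever qualify
  iv <- unique(data.frame(s = cand$aa_start, e = cand$aa_start + cand$aa_len))
  if (nrow(iv) < 2L) {
    reasons <- c(reasons,
                 if (nrow(cand) < 2L) "fewer than 2 qualifying peptides"
                 else "nested pair")
    return(list(pass = FALSE, reasons = reasons))
  }
  iv <- iv[order(iv$s, iv$e), , drop = FALSE]
  nested <- function(a, b) (iv$s[a] >= iv$s[b] && iv$e[a] <= iv$e[b]) ||
    (iv$s[b] >= iv$s[a] && iv$e[b] <= iv$e[a])
  coverage <- function(idx) {
    if (extent_rule == "sum") return(sum(iv$e[idx] - iv$s[idx]))
    pos <- unlist(lapply(idx, function(i) seq.int(iv$s[i], iv$e[i] - 1L)))
    length(unique(pos))
  }
  # exact search: grow pairwise-nonnested subsets, succeed when >=2 members
  # reach the extent; peptide sets per ORF are small in practice
  n <- nrow(iv)
  found <- FALSE
  recurse <- function(chosen, next_i) {
    if (found) return()
    if (length(chosen) >= 2L && coverage(chosen) >= min_extent) {
      found <<- TRUE; return()
    }
    if (next_i > n) return()
    for (i in next_i:n) {
      if (all(vapply(chosen, function(j) !nested(i, j), logical(1L)))) {
        recurse(c(chosen, i), i + 1L)
        if (found) return()
      }
    }
  }
  recurse(integer(), 1L)
  if (!found) {
    any_nonnested_pair <- FALSE
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
      if (!nested(a, b)) any_nonnested_pair <- TRUE
    reasons <- c(reasons,
                 if (!any_nonnested_pair) "nested pair" else
                   sprintf("extent<%d", min_extent))
  }
  list(pass = found, reasons = reasons)
}

#' Bundle the evidence channels for one ORF
#'
#' @param orf_id Identifier.
#' @param riboseq_detected Detected in credible Ribo-Seq data (a QC-gated
#'   upstream flag; this module does not re-derive it).
#' @param insilico_predicted Computationally predicted on an expressed
#'   transcript.
#' @param tryptic,hla [peptide_evidence()] tables (possibly empty/`NULL`).
#' @return List of class `evidence_record`.
#' @export
evidence_record <- function(orf_id, riboseq_detected = FALSE,
                            insilico_predicted = FALSE,
                            tryptic = NULL, hla = NULL) {
  n_tryp <- if (is.null(tryptic)) 0L else nrow(tryptic)
  n_hla <- if (is.null(hla)) 0L else nrow(hla)
  if (!riboseq_detected && !insilico_predicted && n_tryp == 0L && n_hla == 0L)
    stop("validation error: ORF '", orf_id,
         "' has no evidence and no prediction flag")
  structure(list(orf_id = orf_id, riboseq_detected = riboseq_detected,
                 insilico_predicted = insilico_predicted,
                 tryptic = tryptic, hla = hla),
            class = "evidence_record")
}

#' Assign the evidence tier for one ORF
#'
#' Rules are evaluated in priority order (1A, 1B, 2A, 2B, 3, 4, 5); the
#' first match wins and every rule evaluated is recorded in `reasons`. When
#' a record qualifies for both 1A and 1B, 1A is reported and the 1B
#' qualification is noted.
#'
#' @param ev An [evidence_record()].
#' @param hla_source_field Granularity of "distinct sources" for tier 1B:
#'   `"source_id"` (study/experiment, default) or `"sample_id"`.
#' @return List of class `tier_result` with `orf_id`, `tier`, `label`,
#'   `reasons`.
#' @export
assign_tier <- function(ev, hla_source_field = c("source_id", "sample_id")) {
  hla_source_field <- match.arg(hla_source_field)
  stopifnot(inherits(ev, "evidence_record"))
  tryptic <- ev$tryptic; hla <- ev$hla
  n_tryp <- if (is.null(tryptic)) 0L else nrow(tryptic)
  n_hla <- if (is.null(hla)) 0L else nrow(hla)
  n_hla_sources <- if (n_hla == 0L) 0L else
    length(unique(hla[[hla_source_field]]))
  hupo <- hupo_hpp_check(tryptic)
  reasons <- character()
  qual_1b <- ev$riboseq_detected && n_hla >= 2L && n_hla_sources >= 2L
  tier <- if (ev$riboseq_detected && hupo$pass) {
    reasons <- c(reasons, "HUPO/HPP two-peptide rule satisfied",
                 if (qual_1b) "also qualifies for 1B (HLA multi-source)")
    "1A"
  } else if (qual_1b) {
    reasons <- c(reasons, sprintf("%d HLA observations from %d sources",
                                  n_hla, n_hla_sources))
    "1B"
  } else if (ev$riboseq_detected && n_tryp >= 1L) {
    reasons <- c(reasons, sprintf(
      "%d tryptic peptide(s) not satisfying HUPO/HPP criteria (%s)",
      n_tryp, paste(hupo$reasons, collapse = "; ")))
    "2A"
  } else if (ev$riboseq_detected && n_hla >= 1L) {
    reasons <- c(reasons, "single-source HLA observation(s)")
    "2B"
  } else if (!ev$riboseq_detected && (n_tryp >= 1L || n_hla >= 1L)) {
    reasons <- c(reasons, "proteomic evidence without Ribo-Seq")
    "3"
  } else if (ev$riboseq_detected) {
    reasons <- c(reasons, "Ribo-Seq evidence without proteomic evidence")
    "4"
  } else if (ev$insilico_predicted) {
    reasons <- c(reasons, "in silico prediction only")
    "5"
  } else {
    stop("validation error: ORF '", ev$orf_id,
         "' has no evidence and no prediction flag")
  }
  structure(list(orf_id = ev$orf_id, tier = tier,
                 label = unname(TIER_LABELS[tier]), reasons = reasons),
            class = "tier_result")
}

#' @export
print.tier_result <- function(x, ...) {
  cat(sprintf("<tier_result> %s: Tier %s (\"%s\")\n", x$orf_id, x$tier,
              x$label))
  invisible(x)
}

#' Tabulate tiers over a set of evidence records
#'
#' @param records List of [evidence_record()]s with unique `orf_id`s.
#' @param ... Passed to [assign_tier()].
#' @return List with `per_orf` (`data.frame` of `orf_id`, `tier`, `label`,
#'   `reasons`) and `counts` (`data.frame` of `tier`, `label`, `n` over the
#'   seven tiers; counts partition the input).
#' @export
tier_table <- function(records, ...) {
  ids <- vapply(records, function(r) r$orf_id, character(1L))
  if (anyDuplicated(ids))
    stop("validation error: duplicate orf_id '", ids[duplicated(ids)][1L], "'")
  res <- lapply(records, assign_tier, ...)
  per_orf <- data.frame(
    orf_id = ids,
    tier = vapply(res, function(r) r$tier, character(1L)),
    label = vapply(res, function(r) r$label, character(1L)),
    reasons = vapply(res, function(r) paste(r$reasons, collapse = "; "),
                     character(1L)),
    row.names = NULL)
  tiers <- names(TIER_LABELS)
  counts <- data.frame(tier = tiers, label = unname(TIER_LABELS),
                       n = as.integer(table(factor(per_orf$tier,
                                                   levels = tiers))),
                       row.names = NULL)
  list(per_orf = per_orf, counts = counts)
}
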