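# ---------------------------------------------------------------------------
# Ribo-Seq quality control: codon periodicity, detected-CDS counting,
# footprint-yield arithmetic, CDS-mapping fraction.
#
# A P-site table is a data.frame with columns transcript_id, tx_position,
# read_length, count, frame (0/1/2 relative to the transcript's CDS start;
# NA outside CDS), region (CDS, UTR5, UTR3, noncoding). Verdict boundaries
# follow the printed guideline inequalities exactly: periodicity >=0.70 pass,
# 0.60-0.70 gray, <0.60 fail; CDS mapping strictly >0.80; detected CDSs
# strictly >9000 at human scale.
# ---------------------------------------------------------------------------

qc_thresholds <- function() {
  list(periodicity_pass = 0.70, periodicity_gray = 0.60,
       cds_mapping_pass = 0.80, detected_cds = 9000L,
       yield_frac_low = 0.15, yield_frac_high = 0.30)
}

#' In-frame fraction of CDS-mapped P-sites (codon periodicity)
#'
#' The fraction of P-site counts on CDS positions whose frame relative to
#' the annotated CDS start is 0, per read length and pooled over the
#' requested lengths. Invariant to uniform count scaling.
#'
#' @param psites P-site table (see module header).
#' @param read_lengths Read lengths to evaluate; default 28-30 nt.
#' @return List with `per_length` (named numeric), `aggregate` (numeric or
#'   `NA` when no CDS rows exist), and `n_counts` used.
#' @export
codon_periodicity <- function(psites, read_lengths = c(28L, 29L, 30L)) {
  sel <- psites$region == "CDS" & psites$read_length %in% read_lengths
  sub <- psites[sel, , drop = FALSE]
  per_length <- vapply(setNames(read_lengths, read_lengths), function(rl) {
    s <- sub[sub$read_length == rl, , drop = FALSE]
    tot <- sum(s$count)
    if (tot == 0) NA_real_ else sum(s$count[s$frame == 0L]) / tot
  }, numeric(1L))
  tot <- sum(sub$count)
  aggregate <- if (tot == 0) NA_real_ else
    sum(sub$count[sub$frame == 0L]) / tot
  list(per_length = per_length, aggregate = aggregate, n_counts = tot)
}

#' Periodicity verdict
#'
#' @param fraction In-frame fraction in `[0, 1]`, or `NA`.
#' @param pass,gray Verdict boundaries: `>= pass` passes, `[gray, pass)` is
#'   the gray zone where data may be used with caution, `< gray` fails.
#' @return `"pass"`, `"gray"`, `"fail"`, or `"not_evaluated"` for `NA`.
#' @export
periodicity_verdict <- function(fraction, pass = 0.70, gray = 0.60) {
  if (is.na(fraction)) return("not_evaluated")
  if (fraction < 0 || fraction > 1)
    stop("argument error: fraction must be in [0, 1]")
  if (fraction >= pass) "pass" else if (fraction >= gray) "gray" else "fail"
}

#' Count detected annotated CDSs
#'
#' A CDS counts as detected either because the caller output contains it as
#' an annotated CDS (a classified call with canonical relation `identical`),
#' or - fallback - because it accumulates at least `min_psites_per_cds`
#' in-frame P-sites. The default threshold (9000, strict `>`) reflects a
#' sufficiently sequenced human library and must be overridden at synthetic
#' scale, which triggers a scale warning.
#'
#' @param psites Optional P-site table.
#' @param classified Optional list of `classified_orf` (from
#'   [classify_all()]`$classified`).
#' @param min_psites_per_cds In-frame P-site threshold for the fallback rule.
#' @param threshold Detected-CDS count above which the verdict passes.
#' @param n_annotated Optional number of annotated CDSs in the reference;
#'   when supplied and smaller than `threshold`, a scale warning is issued.
#' @return List with `count`, `verdict` (`pass`/`fail`/`not_evaluated`), and
#'   `scale_warning` (logical).
#' @export
detected_cds_count <- function(psites = NULL, classified = NULL,
                               min_psites_per_cds = 10L, threshold = 9000L,
                               n_annotated = NA_integer_) {
  count <- NA_integer_
  if (!is.null(classified)) {
    ids <- unique(vapply(
      Filter(function(x) x$canonical_relation == "identical", classified),
      function(x) x$orf$transcript_id, character(1L)))
    count <- length(ids)
  } else if (!is.null(psites)) {
    cds <- psites[psites$region == "CDS" & psites$frame == 0L, , drop = FALSE]
    if (nrow(cds)) {
      per_tx <- tapply(cds$count, cds$transcript_id, sum)
      count <- sum(per_tx >= min_psites_per_cds)
    } else count <- 0L
  }
  if (is.na(count))
    return(list(count = NA_integer_, verdict = "not_evaluated",
                scale_warning = FALSE))
  scale_warning <- !is.na(n_annotated) && n_annotated < threshold
  if (scale_warning)
    warning("only ", n_annotated, " annotated CDSs available but the ",
            "detection threshold is ", threshold,
            "; override `threshold` for small-scale data")
  list(count = as.integer(count),
       verdict = if (count > threshold) "pass" else "fail",
       scale_warning = scale_warning)
}

#' Expected ribosome-footprint yield from total sequenced reads
#'
#' For human libraries roughly 15-30% of sequenced reads are usable
#' ribosome footprints; a 150 million read library therefore yields about
#' 22.5 to 45 million footprints.
#'
#' @param total_reads Non-negative read count.
#' @param frac_low,frac_high Yield fractions, `0 <= frac_low <= frac_high <= 1`.
#' @return Named numeric vector `c(low, high)`, exact products.
#' @export
footprint_yield <- function(total_reads, frac_low = 0.15, frac_high = 0.30) {
  if (total_reads < 0) stop("argument error: total_reads must be >= 0")
  if (frac_low < 0 || frac_high > 1 || frac_low > frac_high)
    stop("argument error: need 0 <= frac_low <= frac_high <= 1")
  c(low = total_reads * frac_low, high = total_reads * frac_high)
}

#' Fraction of footprint counts mapping to annotated CDS regions
#'
#' @param psites P-site table with region labels.
#' @param pass Verdict boundary; strict inequality (`fraction > pass`).
#' @return List with `fraction` and `verdict` (`pass`/`fail`, or
#'   `not_evaluated` on an empty table).
#' @export
cds_mapping_fraction <- function(psites, pass = 0.80) {
  tot <- sum(psites$count)
  if (tot == 0)
    return(list(fraction = NA_real_, verdict = "not_evaluated"))
  frac <- sum(psites$count[psites$region == "CDS"]) / tot
  list(fraction = frac, verdict = if (frac > pass) "pass" else "fail")
}

#' Assemble a full QC report
#'
#' Bundles periodicity (per length and aggregate), detected-CDS count,
#' CDS-mapping fraction and footprint-yield arithmetic into one report with
#' per-metric verdicts, serializable as JSON.
#'
#' @param psites P-site table.
#' @param total_reads Optional sequenced-read count for yield arithmetic.
#' @param classified Optional classified callset for CDS detection.
#' @param thresholds List as from `orfkit:::qc_thresholds()`.
#' @param detected_cds_threshold Override for the detected-CDS boundary.
#' @param n_annotated Number of annotated CDSs in the reference, if known.
#' @return List of class `qc_report`.
#' @export
qc_report <- function(psites, total_reads = NA_real_, classified = NULL,
                      thresholds = qc_thresholds(),
                      detected_cds_threshold = thresholds$detected_cds,
                      n_annotated = NA_integer_) {
  per <- codon_periodicity(psites)
  cdsmap <- cds_mapping_fraction(psites, pass = thresholds$cds_mapping_pass)
  det <- detected_cds_count(psites = psites, classified = classified,
                            threshold = detected_cds_threshold,
                            n_annotated = n_annotated)
  yield <- if (is.na(total_reads)) NULL else
    footprint_yield(total_reads, thresholds$yield_frac_low,
                    thresholds$yield_frac_high)
  structure(list(
    periodicity_by_length = per$per_length,
    aggregate_periodicity = per$aggregate,
    n_detected_cds = det$count,
    cds_mapping_fraction = cdsmap$fraction,
    footprint_yield_range = yield,
    verdicts = list(
      periodicity = periodicity_verdict(per$aggregate,
                                        thresholds$periodicity_pass,
                                        thresholds$periodicity_gray),
      cds_mapping = cdsmap$verdict,
      detected_cds = det$verdict,
      footprint_yield = if (is.null(yield)) "not_evaluated" else "pass")),
    class = "qc_report")
}

#' Serialize a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
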