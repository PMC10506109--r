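# ---------------------------------------------------------------------------
# ORF category assignment
#
# Categories are decided entirely in transcript coordinates by comparing the
# ORF interval o = [o_start, o_end) with the annotated CDS interval
# c = [c_start, c_end), both stop-inclusive. The decision order below is a
# total function over mappable ORFs; every ORF receives exactly one category.
# ---------------------------------------------------------------------------

#' Classify one ORF against its host transcript
#'
#' Assigns one of the six noncanonical categories (uORF, uoORF, intORF,
#' doORF, dORF, lncRNA-ORF) or flags the ORF as an in-frame variant of the
#' annotated CDS (identical, N-/C-terminal extension or truncation, or other
#' in-frame overlap). An ORF whose stop codon abuts but does not overlap the
#' CDS counts as a uORF. An out-of-frame ORF strictly inside the CDS is an
#' intORF; an in-frame strictly-internal interval with a different stop is
#' impossible on a single transcript and raises a validation error.
#'
#' @param orf An [orf_record()].
#' @param tx The matching [transcript_model()].
#' @return A list of class `classified_orf` with elements `orf`, `category`,
#'   `frame_offset` (`(o_start - c_start) %% 3`, `NA` without a CDS), and
#'   `canonical_relation` (one of `none`, `identical`, `N_extension`,
#'   `N_truncation`, `C_extension`, `other_in_frame`).
#' @export
classify_orf <- function(orf, tx) {
  o <- to_transcript_coords(orf, tx)
  if (is.null(tx$cds_tx)) {
    return(classified(orf, "lncRNA-ORF", NA_integer_, "none"))
  }
  cds <- tx$cds_tx
  fo <- (o[1L] - cds[1L]) %% 3L
  if (o[1L] == cds[1L] && o[2L] == cds[2L])
    return(classified(orf, "CANONICAL_VARIANT", fo, "identical"))
  if (fo == 0L && o[2L] == cds[2L]) {
    rel <- if (o[1L] < cds[1L]) "N_extension" else "N_truncation"
    return(classified(orf, "CANONICAL_VARIANT", fo, rel))
  }
  if (o[2L] <= cds[1L])
    return(classified(orf, "uORF", fo, "none"))
  if (o[1L] < cds[1L] && cds[1L] < o[2L] && o[2L] <= cds[2L])
    return(classified(orf, "uoORF", fo, "none"))
  if (cds[1L] <= o[1L] && o[2L] <= cds[2L]) {
    if (fo == 0L)
      stop("validation error: ORF '", orf$orf_id,
           "' is in-frame and strictly inside the CDS but has a different ",
           "stop codon; impossible on one transcript")
    return(classified(orf, "intORF", fo, "none"))
  }
  if (cds[1L] <= o[1L] && o[1L] < cds[2L] && cds[2L] < o[2L])
    return(classified(orf, "doORF", fo, "none"))
  if (o[1L] >= cds[2L])
    return(classified(orf, "dORF", fo, "none"))
  # remaining: in-frame overlap with a different stop (readthrough-like)
  classified(orf, "CANONICAL_VARIANT", fo, "other_in_frame")
}

classified <- function(orf, category, frame_offset, relation) {
  structure(list(orf = orf, category = category,
                 frame_offset = frame_offset,
                 canonical_relation = relation),
            class = "classified_orf")
}

#' @export
print.classified_orf <- function(x, ...) {
  cat(sprintf("<classified_orf> %s -> %s (frame offset %s, relation %s)\n",
              x$orf$orf_id, x$category,
              ifelse(is.na(x$frame_offset), "-", x$frame_offset),
              x$canonical_relation))
  invisible(x)
}

#' Classify a collection of ORFs and tabulate categories
#'
#' Classification is per (ORF, transcript) pair using each ORF's stated
#' `transcript_id`; duplicated records are counted twice. ORFs whose
#' transcript is missing, or which fail mapping/validation, are reported in
#' the `errors` table rather than aborting the run.
#'
#' @param orfs List of [orf_record()]s.
#' @param txs Named list of [transcript_model()]s.
#' @return List with `classified` (list of `classified_orf`), `counts`
#'   (`data.frame` of category counts, in-frame variants and exclusions
#'   reported separately from the six noncanonical categories), and `errors`
#'   (`data.frame` of per-record failures).
#' @export
classify_all <- function(orfs, txs) {
  res <- list(); errs <- list()
  for (o in orfs) {
    if (is.na(o$transcript_id) || is.null(txs[[o$transcript_id]])) {
      errs[[length(errs) + 1L]] <- data.frame(
        orf_id = o$orf_id, error = paste0("missing transcript '",
                                          o$transcript_id, "'"))
      next
    }
    cl <- tryCatch(classify_orf(o, txs[[o$transcript_id]]),
                   error = function(e) e)
    if (inherits(cl, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(orf_id = o$orf_id,
                                              error = conditionMessage(cl))
    } else {
      res[[length(res) + 1L]] <- cl
    }
  }
  cats <- vapply(res, function(x) x$category, character(1L))
  lev <- orf_categories()
  counts <- data.frame(category = lev,
                       n = as.integer(table(factor(cats, levels = lev))))
  list(classified = res, counts = counts,
       errors = if (length(errs)) do.call(rbind, errs) else
         data.frame(orf_id = character(), error = character()))
}
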