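#' @importFrom stats rbinom rpois runif setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# ---------------------------------------------------------------------------
# Domain types
#
# All internal coordinates are 0-based half-open [start, end); GTF input
# (1-based inclusive) is converted at the boundary, BED12 passes through.
# Stored ORF coordinates INCLUDE the stop codon; reported nt lengths EXCLUDE
# it. Both rules are fixed, not configurable.
# ---------------------------------------------------------------------------

#' Construct a transcript model
#'
#' A transcript model holds the exon chain of one transcript on one strand,
#' its biotype, and (for coding transcripts) the CDS expressed in transcript
#' coordinates with the stop codon included.
#'
#' @param transcript_id,gene_id Identifier strings.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with integer columns `start`, `end` (0-based
#'   half-open), sorted by genomic position, non-overlapping.
#' @param biotype Transcript biotype string (e.g. `"protein_coding"`,
#'   `"lncRNA"`); captured verbatim from the annotation.
#' @param cds_tx Optional length-2 integer vector `(start, end)` in transcript
#'   coordinates, half-open, stop codon included; `NULL` for noncoding
#'   transcripts.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id, chrom,
                             strand, exons, biotype = "protein_coding",
                             cds_tx = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) == 0L)
    stop("validation error: transcript '", transcript_id, "' has no exons")
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end))
    stop("validation error: transcript '", transcript_id,
         "' has an empty or inverted exon")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("validation error: transcript '", transcript_id,
         "' has overlapping exons")
  tx_len <- sum(exons$end - exons$start)
  if (!is.null(cds_tx)) {
    cds_tx <- as.integer(cds_tx)
    if (length(cds_tx) != 2L || cds_tx[1L] < 0L || cds_tx[2L] > tx_len ||
        cds_tx[1L] >= cds_tx[2L])
      stop("validation error: transcript '", transcript_id,
           "' CDS outside [0, transcript length]")
    if ((cds_tx[2L] - cds_tx[1L]) %% 3L != 0L)
      stop("validation error: transcript '", transcript_id,
           "' CDS length not divisible by 3")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 biotype = biotype, cds_tx = cds_tx, tx_length = tx_len),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s) %s:%s %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_id, x$biotype, x$chrom, x$strand,
              nrow(x$exons), x$tx_length,
              if (is.null(x$cds_tx)) "" else
                sprintf(", CDS tx [%d,%d)", x$cds_tx[1L], x$cds_tx[2L])))
  invisible(x)
}

#' Construct an ORF call record
#'
#' An exon-block genomic ORF with its start codon, the genomic position of the
#' first base of its stop codon, an optional category and amino-acid
#' sequence, and `(dataset, caller, replicate, sample)` provenance. Blocks
#' include the stop codon.
#'
#' @param orf_id Unique identifier.
#' @param transcript_id Host transcript identifier.
#' @param chrom,strand Genomic location of the blocks.
#' @param blocks `data.frame` with columns `start`, `end` (0-based half-open),
#'   non-overlapping; total length must be divisible by 3 and at least 6 nt.
#' @param start_codon 3-letter nucleotide string (e.g. `"ATG"`).
#' @param aa_seq Optional amino-acid sequence, length `nt/3` excluding the
#'   stop codon.
#' @param category Optional category, one of [orf_categories()].
#' @param dataset,caller,replicate,sample Provenance tag fields.
#' @return An object of class `orf_record`.
#' @export
orf_record <- function(orf_id, transcript_id, chrom, strand, blocks,
                       start_codon = "ATG", aa_seq = NULL, category = NULL,
                       dataset = NA_character_, caller = NA_character_,
                       replicate = NA_character_, sample = NA_character_) {
  if (!strand %in% c("+", "-"))
    stop("parse error: unknown strand symbol '", strand, "'")
  blocks <- as.data.frame(blocks)[, c("start", "end")]
  blocks$start <- as.integer(blocks$start); blocks$end <- as.integer(blocks$end)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks) == 0L) stop("ORF '", orf_id, "': no blocks")
  if (any(blocks$start >= blocks$end))
    stop("ORF '", orf_id, "': empty or inverted block")
  if (nrow(blocks) > 1L && any(blocks$start[-1L] < blocks$end[-nrow(blocks)]))
    stop("ORF '", orf_id, "': overlapping blocks")
  len <- sum(blocks$end - blocks$start)
  if (len %% 3L != 0L)
    stop("ORF '", orf_id, "': block length not divisible by 3")
  if (len < 6L)
    stop("ORF '", orf_id, "': shorter than start + stop codon")
  if (!is.null(category) && !category %in% orf_categories())
    stop("ORF '", orf_id, "': unknown category '", category, "'")
  if (!is.null(aa_seq) && !is.na(aa_seq) && nzchar(aa_seq) &&
      nchar(aa_seq) != (len - 3L) %/% 3L)
    stop("ORF '", orf_id, "': aa_seq length ", nchar(aa_seq),
         " != nt length/3 = ", (len - 3L) %/% 3L)
  structure(list(orf_id = orf_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, blocks = blocks,
                 start_codon = start_codon,
                 stop_codon_pos = chain_base_at(blocks, strand, len - 3L),
                 aa_seq = if (is.null(aa_seq) || is.na(aa_seq) ||
                              !nzchar(aa_seq)) NULL else aa_seq,
                 category = category,
                 source = list(dataset = dataset, caller = caller,
                               replicate = as.character(replicate),
                               sample = sample)),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("<orf_record> %s on %s %s:%s %d block(s), %d nt (excl. stop)%s\n",
              x$orf_id, x$transcript_id, x$chrom, x$strand, nrow(x$blocks),
              orf_nt_length(x),
              if (is.null(x$category)) "" else paste0(" [", x$category, "]")))
  invisible(x)
}

#' The standardized ORF category vocabulary
#'
#' Six noncanonical categories (upstream, upstream-overlapping, internal
#' out-of-frame, downstream-overlapping, downstream, and lncRNA-hosted ORFs)
#' plus the two bookkeeping classes for in-frame CDS variants and records
#' excluded by harmonization rules.
#' @return Character vector of valid category names.
#' @export
orf_categories <- function() {
  c("uORF", "uoORF", "intORF", "doORF", "dORF", "lncRNA-ORF",
    "CANONICAL_VARIANT", "EXCLUDED")
}

noncanonical_categories <- function() {
  c("uORF", "uoORF", "intORF", "doORF", "dORF", "lncRNA-ORF")
}

# genomic position of the k-th base (0-based) along the 5'->3' block chain
chain_base_at <- function(blocks, strand, k) {
  widths <- blocks$end - blocks$start
  if (strand == "-") {
    blocks <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
    widths <- rev(widths)
  }
  off <- cumsum(c(0L, widths))
  i <- findInterval(k, off, rightmost.closed = FALSE)
  if (k < 0L || k >= off[length(off)]) stop("chain offset out of range")
  within <- k - off[i]
  if (strand == "+") blocks$start[i] + within else blocks$end[i] - 1L - within
}

# ---------------------------------------------------------------------------
# Coordinate conversion
# ---------------------------------------------------------------------------

# strand-aware offset of each exon's 5'-most base in transcript coordinates.
# On '-' transcripts coordinate 0 is the genomically rightmost exonic base.
tx_offsets <- function(tx) {
  ex <- tx$exons
  w <- ex$end - ex$start
  if (tx$strand == "+") {
    cumsum(c(0L, w))[seq_len(nrow(ex))]
  } else {
    rev(cumsum(c(0L, rev(w)))[seq_len(nrow(ex))])
  }
}

# transcript coordinate of genomic base gpos (scalar); NA when intronic
g2t <- function(tx, gpos) {
  ex <- tx$exons
  i <- which(gpos >= ex$start & gpos < ex$end)
  if (length(i) != 1L) return(NA_integer_)
  off <- tx_offsets(tx)
  if (tx$strand == "+") off[i] + (gpos - ex$start[i])
  else off[i] + (ex$end[i] - 1L - gpos)
}

#' Map an ORF's genomic blocks to a transcript-coordinate interval
#'
#' Returns the half-open interval `(tx_start, tx_end)` that the ORF occupies
#' on its host transcript, stop codon included. The mapping is
#' length-preserving and strictly monotone along the transcript on both
#' strands.
#'
#' @param orf An [orf_record()].
#' @param tx The matching [transcript_model()].
#' @return Integer vector `c(tx_start, tx_end)`, 0-based half-open.
#' @export
to_transcript_coords <- function(orf, tx) {
  if (orf$transcript_id != tx$transcript_id)
    stop("mapping error: ORF '", orf$orf_id, "' targets transcript '",
         orf$transcript_id, "', not '", tx$transcript_id, "'")
  ex <- tx$exons
  for (b in seq_len(nrow(orf$blocks))) {
    s <- orf$blocks$start[b]; e <- orf$blocks$end[b]
    if (!any(s >= ex$start & e <= ex$end))
      stop("mapping error: ORF '", orf$orf_id, "' block [", s, ",", e,
           ") outside the exons of ", tx$transcript_id)
  }
  len <- sum(orf$blocks$end - orf$blocks$start)
  first <- g2t(tx, chain_base_at(orf$blocks, orf$strand, 0L))
  last <- g2t(tx, chain_base_at(orf$blocks, orf$strand, len - 1L))
  if (is.na(first) || is.na(last) || last != first + len - 1L)
    stop("mapping error: ORF '", orf$orf_id,
         "' blocks are not contiguous on transcript ", tx$transcript_id)
  c(first, last + 1L)
}

# genomic blocks (sorted by genomic start) covering transcript interval
# [t_start, t_end); inverse of to_transcript_coords
tx_interval_to_blocks <- function(tx, t_start, t_end) {
  stopifnot(t_start >= 0L, t_end <= tx$tx_length, t_start < t_end)
  ex <- tx$exons
  w <- ex$end - ex$start
  ord <- if (tx$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  off <- 0L
  out <- list()
  for (i in ord) {
    a <- max(t_start, off); b <- min(t_end, off + w[i])
    if (a < b) {
      if (tx$strand == "+") {
        out[[length(out) + 1L]] <- c(ex$start[i] + (a - off),
                                     ex$start[i] + (b - off))
      } else {
        out[[length(out) + 1L]] <- c(ex$end[i] - (b - off),
                                     ex$end[i] - (a - off))
      }
    }
    off <- off + w[i]
  }
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1L], end = m[, 2L])
  df[order(df$start), , drop = FALSE]
}

#' ORF length in nucleotides, excluding the stop codon
#'
#' @param orf An [orf_record()].
#' @return Integer: sum of block lengths minus 3.
#' @export
orf_nt_length <- function(orf) {
  sum(orf$blocks$end - orf$blocks$start) - 3L
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read transcript models from a GTF file
#'
#' Parses exon and CDS features of an Ensembl-dialect GTF (1-based inclusive
#' coordinates) into [transcript_model()] objects with 0-based half-open
#' internal coordinates. When the GTF annotates the stop codon separately
#' (Ensembl convention: CDS excludes it), the stop codon is appended to the
#' transcript-coordinate CDS.
#'
#' @param path Path to a GTF file.
#' @return Named list of `transcript_model` objects (names = transcript ids).
#' @export
read_transcript_models <- function(path) {
  validate_gtf_syntax(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (length(gr) == 0L) stop("validation error: no exon/CDS features in ", path)
  biocol <- intersect(c("transcript_biotype", "transcript_type", "biotype"),
                      colnames(md))
  txids <- as.character(md$transcript_id)
  out <- list()
  for (tid in unique(txids)) {
    sel <- txids == tid
    sub <- gr[sel]; smd <- md[sel, , drop = FALSE]
    exi <- smd$type == "exon"
    if (!any(exi))
      stop("validation error: transcript '", tid, "' has zero exon lines")
    ex <- data.frame(start = GenomicRanges::start(sub[exi]) - 1L,
                     end = GenomicRanges::end(sub[exi]))
    strand <- as.character(GenomicRanges::strand(sub))[1L]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1L]
    bt <- if (length(biocol))
      as.character(smd[[biocol[1L]]][1L]) else "protein_coding"
    gid <- if ("gene_id" %in% colnames(smd))
      as.character(smd$gene_id[1L]) else tid
    tm <- transcript_model(tid, gid, chrom, strand, ex, biotype = bt)
    cdsi <- smd$type == "CDS"
    if (any(cdsi)) {
      cds <- data.frame(start = GenomicRanges::start(sub[cdsi]) - 1L,
                        end = GenomicRanges::end(sub[cdsi]))
      stopi <- smd$type == "stop_codon"
      stop_len <- if (any(stopi))
        sum(GenomicRanges::end(sub[stopi]) - GenomicRanges::start(sub[stopi]) + 1L)
      else 0L
      t_pos <- unlist(lapply(seq_len(nrow(cds)), function(i) {
        c(g2t(tm, cds$start[i]), g2t(tm, cds$end[i] - 1L))
      }))
      if (anyNA(t_pos))
        stop("validation error: CDS outside exons for transcript '", tid, "'")
      cds_start <- min(t_pos); cds_end <- max(t_pos) + 1L
      cds_len <- sum(cds$end - cds$start)
      if (cds_end - cds_start != cds_len)
        stop("validation error: CDS not contiguous on transcript '", tid, "'")
      cds_end <- cds_end + stop_len  # append stop codon when annotated apart
      if (stop_len == 0L && cds_len %% 3L != 0L)
        stop("validation error: CDS length of '", tid,
             "' not divisible by 3 and no stop_codon feature")
      tm <- transcript_model(tid, gid, chrom, strand, ex, biotype = bt,
                             cds_tx = c(cds_start, cds_end))
    }
    out[[tid]] <- tm
  }
  out
}

validate_gtf_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1L]]) < 8L)
      stop("parse error at line ", i, " of ", path,
           ": expected >=8 tab-separated fields")
  }
  invisible(TRUE)
}

#' Read ORF calls from BED12 or the orfkit TSV dialect
#'
#' BED12 files (0-based half-open, block-structured) are parsed with
#' `rtracklayer`; the TSV dialect carries explicit provenance columns
#' (`orf_id`, `transcript_id`, `chrom`, `strand`, `block_starts`,
#' `block_sizes`, `start_codon`, `dataset`, `caller`, `replicate`, `sample`,
#' optionally `category`, `aa_seq`). Records violating ORF invariants
#' (overlapping blocks, length not divisible by 3, ...) are rejected
#' individually and reported; file-level syntax errors abort.
#'
#' @param path Input file; format guessed from the extension unless given.
#' @param format `"auto"`, `"bed"` or `"tsv"`.
#' @return Named list of [orf_record()]s with attribute `"rejections"`, a
#'   `data.frame` of rejected row identifiers and reasons.
#' @export
read_orf_calls <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  rows <- if (format == "bed") orf_rows_from_bed(path) else orf_rows_from_tsv(path)
  out <- list(); rej <- list()
  for (r in rows) {
    rec <- tryCatch(do.call(orf_record, r), error = function(e) e)
    if (inherits(rec, "error")) {
      reason <- conditionMessage(rec)
      if (grepl("parse error", reason)) stop(rec)  # strand etc.: fatal
      rej[[length(rej) + 1L]] <- data.frame(orf_id = r$orf_id,
                                            reason = reason)
    } else {
      if (rec$orf_id %in% names(out))
        stop("validation error: duplicate orf_id '", rec$orf_id, "'")
      out[[rec$orf_id]] <- rec
    }
  }
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(orf_id = character(), reason = character())
  out
}

orf_rows_from_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  lapply(seq_along(gr), function(i) {
    st <- as.character(GenomicRanges::strand(gr[i]))
    if (!st %in% c("+", "-"))
      stop("parse error: unknown strand symbol '", st, "' in ", path)
    b <- if (!is.null(blocks) && length(blocks[[i]]) > 0L) {
      data.frame(
        start = GenomicRanges::start(gr[i]) - 1L + IRanges::start(blocks[[i]]) - 1L,
        end = GenomicRanges::start(gr[i]) - 1L + IRanges::end(blocks[[i]]))
    } else {
      data.frame(start = GenomicRanges::start(gr[i]) - 1L,
                 end = GenomicRanges::end(gr[i]))
    }
    nm <- S4Vectors::mcols(gr)$name
    list(orf_id = if (is.null(nm) || is.na(nm[i])) paste0("orf", i) else nm[i],
         transcript_id = NA_character_,
         chrom = as.character(GenomicRanges::seqnames(gr[i])),
         strand = st, blocks = b)
  })
}

orf_rows_from_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("orf_id", "transcript_id", "chrom", "strand", "block_starts",
            "block_sizes", "start_codon", "dataset", "caller", "replicate",
            "sample")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("parse error: TSV missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    if (!df$strand[i] %in% c("+", "-"))
      stop("parse error: unknown strand symbol '", df$strand[i],
           "' at data row ", i)
    starts <- as.integer(strsplit(df$block_starts[i], ",", fixed = TRUE)[[1L]])
    sizes <- as.integer(strsplit(df$block_sizes[i], ",", fixed = TRUE)[[1L]])
    if (length(starts) != length(sizes) || anyNA(starts) || anyNA(sizes))
      stop("parse error: malformed block columns at data row ", i)
    list(orf_id = df$orf_id[i], transcript_id = df$transcript_id[i],
         chrom = df$chrom[i], strand = df$strand[i],
         blocks = data.frame(start = starts, end = starts + sizes),
         start_codon = df$start_codon[i],
         aa_seq = if ("aa_seq" %in% colnames(df) && nzchar(df$aa_seq[i]))
           df$aa_seq[i] else NULL,
         category = if ("category" %in% colnames(df) && nzchar(df$category[i]))
           df$category[i] else NULL,
         dataset = df$dataset[i], caller = df$caller[i],
         replicate = df$replicate[i], sample = df$sample[i])
  })
}

#' Write ORF calls to the orfkit TSV dialect
#'
#' Inverse of [read_orf_calls()] for the TSV dialect; round-trips block
#' structures and provenance bit-exactly for valid records.
#'
#' @param orfs List of [orf_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_calls <- function(orfs, path) {
  df <- orfs_as_table(orfs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Flatten a list of ORF records into the TSV-dialect table
#' @param orfs List of [orf_record()]s.
#' @return `data.frame` with one row per record.
#' @export
orfs_as_table <- function(orfs) {
  do.call(rbind, lapply(orfs, function(o) {
    data.frame(orf_id = o$orf_id, transcript_id = o$transcript_id,
               chrom = o$chrom, strand = o$strand,
               block_starts = paste(o$blocks$start, collapse = ","),
               block_sizes = paste(o$blocks$end - o$blocks$start, collapse = ","),
               start_codon = o$start_codon,
               dataset = o$source$dataset, caller = o$source$caller,
               replicate = o$source$replicate, sample = o$source$sample,
               category = if (is.null(o$category)) "" else o$category,
               aa_seq = if (is.null(o$aa_seq)) "" else o$aa_seq,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
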