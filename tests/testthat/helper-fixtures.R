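# Fixture builders and independent oracles. Everything here is constructed
# in code at test time; no external files.

# single-exon transcript on one synthetic chromosome
simple_tx <- function(id = "tx1", strand = "+", tx_len = 600L,
                      cds = c(100L, 400L), chrom = "chr1", offset = 0L,
                      biotype = if (is.null(cds)) "lncRNA" else
                        "protein_coding") {
  transcript_model(id, paste0("g_", id), chrom, strand,
                   data.frame(start = offset, end = offset + tx_len),
                   biotype = biotype, cds_tx = cds)
}

# ORF on a simple transcript, given a transcript-space interval
tx_orf <- function(tx, t_start, t_end, orf_id = "o1", ...) {
  orf_record(orf_id, tx$transcript_id, tx$chrom, tx$strand,
             tx_interval_to_blocks(tx, t_start, t_end), ...)
}

# single-exon + strand ORF with an explicit genomic interval
ivl_orf <- function(orf_id, start, end, chrom = "chr1", strand = "+", ...) {
  orf_record(orf_id, NA_character_, chrom, strand,
             data.frame(start = start, end = end), ...)
}

# ---------------------------------------------------------------------------
# Independent clustering oracle: explicit base-position sets + union-find
# over brute-force all-pairs similarity. Deliberately avoids the package's
# interval-walking containment code.
# ---------------------------------------------------------------------------

oracle_positions <- function(orf) {
  unlist(mapply(function(s, e) seq.int(s, e - 1L),
                orf$blocks$start, orf$blocks$end, SIMPLIFY = FALSE))
}

oracle_similar <- function(child, parent, min_frac) {
  if (child$chrom != parent$chrom || child$strand != parent$strand)
    return(FALSE)
  if (child$stop_codon_pos != parent$stop_codon_pos) return(FALSE)
  pc <- oracle_positions(child); pp <- oracle_positions(parent)
  if (!all(pc %in% pp)) return(FALSE)
  (length(pc) - 3L) >= min_frac * (length(pp) - 3L)
}

oracle_partition <- function(orfs, min_frac) {
  n <- length(orfs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && oracle_similar(orfs[[i]], orfs[[j]], min_frac)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  ids <- vapply(orfs, function(o) o$orf_id, character(1L))
  canon_partition(unname(split(ids, roots)))
}

# canonical form of a partition for comparison
canon_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, character(1L), 1L))]
}

clusters_partition <- function(clusters) {
  canon_partition(strsplit(clusters$members, ",", fixed = TRUE))
}

# random single/two-block ORF sets sharing stop codons, for oracle tests
random_orf_set <- function(n, seed) {
  set.seed(seed)
  n_groups <- max(1L, n %/% 3L)
  groups <- data.frame(
    stop_right = sample(500:5000, n_groups) * 3L,
    strand = sample(c("+", "-"), n_groups, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n_groups, replace = TRUE))
  orfs <- list()
  for (i in seq_len(n)) {
    g <- sample(n_groups, 1L)
    L <- 3L * sample(4:40, 1L)  # total nt including stop
    if (groups$strand[g] == "+") {
      e <- groups$stop_right[g]; s <- e - L
    } else {
      s <- groups$stop_right[g]; e <- s + L
    }
    if (runif(1L) < 0.3 && L >= 12L) {
      # two blocks with a random gap at a random in-chain junction
      cut <- 3L * sample(seq_len(L %/% 3L - 1L), 1L)
      gap <- 3L * sample(1:5, 1L)
      blocks <- if (groups$strand[g] == "+")
        data.frame(start = c(s - gap, s + cut), end = c(s + cut - gap, e))
      else
        data.frame(start = c(s, s + cut + gap), end = c(s + cut, e + gap))
    } else {
      blocks <- data.frame(start = s, end = e)
    }
    orfs[[i]] <- orf_record(sprintf("r%02d", i), NA_character_,
                            groups$chrom[g], groups$strand[g], blocks)
  }
  orfs
}

# ---------------------------------------------------------------------------
# HUPO/HPP brute-force oracle: enumerate every subset of <= 8 peptides
# ---------------------------------------------------------------------------

oracle_hupo <- function(peptides, min_len = 9L, min_extent = 18L) {
  n <- nrow(peptides)
  if (n == 0L) return(FALSE)
  for (mask in 1:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 2L) next
    sub <- peptides[idx, , drop = FALSE]
    if (!all(sub$uniquely_mapping)) next
    if (!all(sub$aa_len >= min_len)) next
    s <- sub$aa_start; e <- sub$aa_start + sub$aa_len
    nested <- FALSE
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a != b && s[a] >= s[b] && e[a] <= e[b]) nested <- TRUE
    }
    if (nested) next
    pos <- unique(unlist(mapply(function(a, b) seq.int(a, b - 1L), s, e,
                                SIMPLIFY = FALSE)))
    if (length(pos) >= min_extent) return(TRUE)
  }
  FALSE
}

# small in-memory GTF writer for reader tests
write_test_gtf <- function(path, rows) {
  writeLines(vapply(rows, function(r) {
    paste(r$chrom, "test", r$type, r$start, r$end, ".", r$strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                  r$gene, r$tx, r$biotype), sep = "\t")
  }, character(1L)), path)
  path
}
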