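# ---------------------------------------------------------------------------
# Similarity relation and unique-ORF clustering
#
# Two ORFs are similar when the exonic base set of one is fully contained in
# the other's, both share the stop codon position (and chrom/strand), and the
# child covers at least min_frac of the parent's length (nt, stops excluded).
# Similarity relations are merged transitively: connected components of the
# undirected similarity graph are the "unique ORFs".
# ---------------------------------------------------------------------------

# TRUE when every [start,end) block of `child` is covered by the union of
# `parent` blocks. Blocks are sorted and non-overlapping by construction.
blocks_contained <- function(child, parent) {
  for (i in seq_len(nrow(child))) {
    s <- child$start[i]; e <- child$end[i]
    covered <- FALSE
    for (j in seq_len(nrow(parent))) {
      if (s >= parent$start[j] && e <= parent$end[j]) { covered <- TRUE; break }
    }
    if (!covered) {
      # a child block may span several parent blocks only if they are
      # genomically adjacent; walk the residual interval
      pos <- s
      repeat {
        j <- which(parent$start <= pos & pos < parent$end)
        if (length(j) != 1L) return(FALSE)
        pos <- parent$end[j]
        if (pos >= e) { covered <- TRUE; break }
      }
      if (!covered) return(FALSE)
    }
  }
  TRUE
}

# splice junctions internal to the chain, as "end|start" strings
internal_junctions <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return(character())
  paste(blocks$end[-n], blocks$start[-1L], sep = "|")
}

#' Are two ORF calls similar?
#'
#' @param child,parent [orf_record()]s.
#' @param min_frac Required overlap fraction in `(0, 1]`:
#'   `orf_nt_length(child) >= min_frac * orf_nt_length(parent)`.
#' @param strict_junctions When `TRUE`, additionally require the child's
#'   internal splice junctions to be a subset of the parent's (guards against
#'   spurious containment across incompatible splice forms); default `FALSE`.
#' @return `TRUE` iff the child's exonic base set is contained in the
#'   parent's, both share `chrom`, `strand` and `stop_codon_pos`, and the
#'   length fraction passes. Cross-chromosome comparisons return `FALSE`.
#' @export
is_similar <- function(child, parent, min_frac, strict_junctions = FALSE) {
  stopifnot(min_frac > 0, min_frac <= 1)
  if (child$chrom != parent$chrom || child$strand != parent$strand)
    return(FALSE)
  if (child$stop_codon_pos != parent$stop_codon_pos) return(FALSE)
  if (!blocks_contained(child$blocks, parent$blocks)) return(FALSE)
  if (strict_junctions &&
      !all(internal_junctions(child$blocks) %in%
           internal_junctions(parent$blocks)))
    return(FALSE)
  orf_nt_length(child) >= min_frac * orf_nt_length(parent)
}

#' Cluster ORF calls into unique ORFs
#'
#' Builds the similarity graph over all pairs (grouped by shared
#' chrom/strand/stop-codon position, the necessary condition for an edge) and
#' returns its connected components: a chain A in B in C with a shared stop
#' collapses to one unique ORF. The cluster representative is the longest
#' member, ties broken by smallest `orf_id`.
#'
#' @param orfs List of [orf_record()]s with unique `orf_id`s.
#' @param min_frac Overlap-fraction threshold in `(0, 1]`.
#' @param strict_junctions Passed to [is_similar()].
#' @return `data.frame` with one row per cluster: `cluster_id`, `members`
#'   (comma-joined orf_ids), `n_members`, `representative`, `length_nt`
#'   (representative length excluding stop), `replicate_support` (distinct
#'   `(dataset, caller, replicate)` provenance triples among members),
#'   `caller_support`, and `category` (of the representative).
#' @export
build_unique_clusters <- function(orfs, min_frac, strict_junctions = FALSE) {
  ids <- vapply(orfs, function(o) o$orf_id, character(1L))
  if (anyDuplicated(ids))
    stop("validation error: duplicate orf_id '", ids[duplicated(ids)][1L], "'")
  n <- length(orfs)
  if (n == 0L)
    return(data.frame(cluster_id = character(), members = character(),
                      n_members = integer(), representative = character(),
                      length_nt = integer(), replicate_support = integer(),
                      caller_support = integer(), category = character()))
  key <- vapply(orfs, function(o)
    paste(o$chrom, o$strand, o$stop_codon_pos, sep = "@"), character(1L))
  edges <- list()
  for (grp in split(seq_len(n), key)) {
    if (length(grp) < 2L) next
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (a == b) next
      i <- grp[a]; j <- grp[b]
      if (is_similar(orfs[[i]], orfs[[j]], min_frac, strict_junctions))
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
  comp <- igraph::components(g)$membership
  rows <- lapply(split(seq_len(n), comp), function(members) {
    lens <- vapply(orfs[members], orf_nt_length, integer(1L))
    mids <- ids[members]
    best <- members[order(-lens, mids)][1L]
    prov <- vapply(orfs[members], function(o)
      paste(o$source$dataset, o$source$caller, o$source$replicate, sep = "/"),
      character(1L))
    callers <- vapply(orfs[members], function(o)
      paste(o$source$dataset, o$source$caller, sep = "/"), character(1L))
    data.frame(cluster_id = ids[best],
               members = paste(sort(mids), collapse = ","),
               n_members = length(members),
               representative = ids[best],
               length_nt = orf_nt_length(orfs[[best]]),
               replicate_support = length(unique(prov)),
               caller_support = length(unique(callers)),
               category = if (is.null(orfs[[best]]$category))
                 NA_character_ else orfs[[best]]$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cluster_id), , drop = FALSE]
}

#' Replicate-sharing curve over an overlap-threshold grid
#'
#' For each overlap threshold, pools all replicates' calls, clusters them,
#' and counts clusters supported by at least `k` distinct replicates.
#'
#' @param callsets Named list (one element per replicate) of [orf_record()]
#'   lists. Record `orf_id`s must be unique across the pool.
#' @param min_frac_grid Numeric vector of thresholds in `(0, 1]`.
#' @param k_values Integer vector of minimum replicate counts.
#' @return `data.frame` with columns `min_frac`, `k`, `n_unique_shared`.
#'   `k` beyond the replicate count yields 0, not an error.
#' @export
replicate_sharing_curve <- function(callsets, min_frac_grid = seq(0.5, 1, 0.05),
                                    k_values = c(1L, 3L, 6L)) {
  stopifnot(length(callsets) >= 1L, all(min_frac_grid > 0),
            all(min_frac_grid <= 1))
  pooled <- unlist(callsets, recursive = FALSE, use.names = FALSE)
  out <- list()
  for (mf in min_frac_grid) {
    cl <- build_unique_clusters(pooled, mf)
    for (k in k_values) {
      out[[length(out) + 1L]] <- data.frame(
        min_frac = mf, k = as.integer(k),
        n_unique_shared = sum(cl$replicate_support >= k))
    }
  }
  do.call(rbind, out)
}

#' Category composition of well-supported clusters
#'
#' @param clusters Output of [build_unique_clusters()].
#' @param k Minimum replicate support.
#' @return `data.frame` of `category`, `n`, `percent` over clusters with
#'   `replicate_support >= k`; percentages sum to 100 up to float tolerance.
#'   Empty input yields an empty table.
#' @export
category_composition <- function(clusters, k = 1L) {
  sel <- clusters[clusters$replicate_support >= k, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(category = character(), n = integer(),
                      percent = numeric()))
  tab <- table(sel$category, useNA = "ifany")
  data.frame(category = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(sel),
             row.names = NULL)
}

#' Length distribution of cluster representatives
#'
#' @param clusters Output of [build_unique_clusters()].
#' @param k Minimum replicate support.
#' @return Integer vector of representative nt lengths (stop codon excluded).
#' @export
length_distribution <- function(clusters, k = 1L) {
  clusters$length_nt[clusters$replicate_support >= k]
}
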