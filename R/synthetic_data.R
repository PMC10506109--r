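# ---------------------------------------------------------------------------
# Synthetic data with known ground truth: transcriptomes, multi-caller /
# multi-replicate ORF call sets, P-site tables, peptide evidence.
#
# All generators are deterministic given their seed and restore the caller's
# RNG state on exit.
# ---------------------------------------------------------------------------

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Describe a simulated ORF caller
#'
#' A caller profile captures the behaviours that make real callers disagree:
#' start-site jitter around a shared stop codon, replicate dropout
#' (false negatives), spurious calls (false positives / stochastic
#' translation), and per-category call-probability biases.
#'
#' @param name Caller name.
#' @param start_codons Start codons the caller may emit for spurious calls.
#' @param jitter_prob Probability that a replicate call shifts its start by
#'   whole codons while keeping the stop codon.
#' @param dropout_prob Probability that an expressed ORF is missed in a
#'   replicate.
#' @param spurious_rate Expected number of false ORF calls per replicate
#'   (Poisson).
#' @param category_bias Named multipliers on per-category call probability
#'   (unnamed categories default to 1).
#' @return List of class `caller_profile`.
#' @export
caller_profile <- function(name, start_codons = "ATG", jitter_prob = 0,
                           dropout_prob = 0, spurious_rate = 0,
                           category_bias = numeric()) {
  stopifnot(jitter_prob >= 0, jitter_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1, spurious_rate >= 0)
  structure(list(name = name, start_codons = start_codons,
                 jitter_prob = jitter_prob, dropout_prob = dropout_prob,
                 spurious_rate = spurious_rate,
                 category_bias = category_bias),
            class = "caller_profile")
}

#' Generate a synthetic transcriptome
#'
#' Coding transcripts carry a 5'UTR / CDS / 3'UTR partition with UTRs long
#' enough to host upstream and downstream ORFs (90-240 nt each) and CDSs of
#' 60-200 codons including the stop; noncoding transcripts are 300-900 nt
#' lncRNAs. Each transcript has 1-4 exons separated by 50-300 nt introns,
#' random strand, laid out without overlap on one synthetic chromosome.
#'
#' @param n_coding,n_noncoding Transcript counts; the total must be >= 1.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return Named list of [transcript_model()]s.
#' @export
gen_transcriptome <- function(n_coding, n_noncoding, seed = 1L) {
  if (n_coding < 0L || n_noncoding < 0L || n_coding + n_noncoding < 1L)
    stop("argument error: need n_coding + n_noncoding >= 1, both >= 0")
  with_seed(seed, {
    out <- list()
    gpos <- 1000L
    n <- n_coding + n_noncoding
    coding <- rep(c(TRUE, FALSE), c(n_coding, n_noncoding))
    for (i in seq_len(n)) {
      tid <- sprintf("TX%04d", i)
      if (coding[i]) {
        utr5 <- sample(90:240, 1L)
        cds_len <- 3L * sample(60:200, 1L)  # includes the stop codon
        utr3 <- sample(90:240, 1L)
        tx_len <- utr5 + cds_len + utr3
        cds_tx <- c(utr5, utr5 + cds_len)
        biotype <- "protein_coding"
      } else {
        tx_len <- sample(300:900, 1L)
        cds_tx <- NULL
        biotype <- "lncRNA"
      }
      n_ex <- sample(1:4, 1L)
      # split tx_len into n_ex exon widths of >= 30 nt
      while (TRUE) {
        cuts <- sort(sample(seq_len(tx_len - 1L),
                            n_ex - 1L, replace = FALSE))
        w <- diff(c(0L, cuts, tx_len))
        if (all(w >= 30L)) break
      }
      strand <- sample(c("+", "-"), 1L)
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- gpos
      for (e in seq_len(n_ex)) {
        starts[e] <- p; ends[e] <- p + w[e]
        p <- ends[e] + sample(50:300, 1L)
      }
      # exon widths were drawn in transcript (5'->3') order; on '-' the
      # genomic order is the reverse
      if (strand == "-") {
        w_rev <- rev(w)
        p <- gpos
        for (e in seq_len(n_ex)) {
          starts[e] <- p; ends[e] <- p + w_rev[e]
          p <- ends[e] + sample(50:300, 1L)
        }
      }
      out[[tid]] <- transcript_model(tid, paste0("G", tid), "chrS", strand,
                                     data.frame(start = starts, end = ends),
                                     biotype = biotype, cds_tx = cds_tx)
      gpos <- p + 500L
    }
    out
  })
}

# draw a transcript-space interval (start, end) for one true ORF of the
# requested category on transcript tx; length in whole codons, >= min_codons
draw_true_interval <- function(tx, category, min_codons = 8L,
                               max_codons = 40L) {
  pick_len <- function(max_c) {
    if (max_c < min_codons) return(NA_integer_)
    3L * sample(min_codons:min(max_codons, max_c), 1L)
  }
  cds <- tx$cds_tx
  if (category == "lncRNA-ORF") {
    len <- pick_len(tx$tx_length %/% 3L - 1L)
    if (is.na(len) || len >= tx$tx_length) return(NULL)
    s <- sample(0:(tx$tx_length - len), 1L)
    return(c(s, s + len))
  }
  if (is.null(cds)) return(NULL)
  if (category == "uORF") {
    len <- pick_len(cds[1L] %/% 3L)
    if (is.na(len) || len > cds[1L]) return(NULL)
    s <- sample(0:(cds[1L] - len), 1L)
    return(c(s, s + len))
  }
  if (category == "uoORF") {
    # start in the 5'UTR out of frame, end inside the CDS (before its stop)
    for (try in 1:20) {
      len <- pick_len(min(max_codons, (cds[2L] - 3L) %/% 3L))
      if (is.na(len)) return(NULL)
      lo <- max(0L, cds[1L] - len + 3L); hi <- cds[1L] - 1L
      if (lo > hi) next
      s <- sample(lo:hi, 1L)
      e <- s + len
      if (e <= cds[1L] || e > cds[2L] - 3L) next
      if ((s - cds[1L]) %% 3L == 0L) next
      return(c(s, e))
    }
    return(NULL)
  }
  if (category == "intORF") {
    for (try in 1:20) {
      len <- pick_len((cds[2L] - cds[1L] - 6L) %/% 3L)
      if (is.na(len)) return(NULL)
      lo <- cds[1L]; hi <- cds[2L] - 3L - len
      if (lo > hi) next
      s <- sample(lo:hi, 1L)
      if ((s - cds[1L]) %% 3L == 0L) next
      return(c(s, s + len))
    }
    return(NULL)
  }
  if (category == "doORF") {
    utr3 <- tx$tx_length - cds[2L]
    for (try in 1:20) {
      len <- pick_len((cds[2L] - cds[1L] + utr3) %/% 3L)
      if (is.na(len)) return(NULL)
      lo <- max(cds[1L], cds[2L] + 3L - len); hi <- min(cds[2L] - 1L,
                                                        tx$tx_length - len)
      if (lo > hi) next
      s <- sample(lo:hi, 1L)
      e <- s + len
      if (e <= cds[2L] || e > tx$tx_length) next
      if ((s - cds[1L]) %% 3L == 0L) next
      return(c(s, e))
    }
    return(NULL)
  }
  if (category == "dORF") {
    utr3 <- tx$tx_length - cds[2L]
    len <- pick_len(utr3 %/% 3L)
    if (is.na(len) || len > utr3) return(NULL)
    s <- cds[2L] + sample(0:(utr3 - len), 1L)
    return(c(s, s + len))
  }
  stop("argument error: unknown category '", category, "'")
}

#' Generate multi-caller, multi-replicate ORF call sets with ground truth
#'
#' True ORFs of the requested categories are placed on the transcriptome;
#' each caller profile then emits, per replicate, a noisy view of them:
#' calls are dropped with `dropout_prob` (modulated by `category_bias`),
#' start sites jitter by 1-3 whole codons (upstream when the hosting region
#' allows, otherwise downstream) while always keeping the true stop codon,
#' and `spurious_rate` false calls per replicate are placed uniformly on
#' expressed transcripts in a random frame with cluster label `"noise"`.
#'
#' @param txs Transcriptome from [gen_transcriptome()].
#' @param true_orfs_per_category Named integer vector over the six
#'   noncanonical categories (e.g. `c(uORF = 10, dORF = 5)`).
#' @param profiles List of [caller_profile()]s.
#' @param n_replicates Replicates per caller.
#' @param seed Integer seed.
#' @return List with `callsets` (nested: `callsets[[caller]][[replicate]]` is
#'   a list of [orf_record()]s), `truth` (`data.frame`: `orf_id`,
#'   `true_cluster`, `true_category`, `caller`, `replicate`, `jittered`),
#'   and `true_orfs` (the underlying noise-free [orf_record()]s).
#' @export
gen_orf_callsets <- function(txs, true_orfs_per_category, profiles,
                             n_replicates = 6L, seed = 1L) {
  bad <- setdiff(names(true_orfs_per_category), noncanonical_categories())
  if (length(bad))
    stop("argument error: unknown category key '", bad[1L], "'")
  with_seed(seed, {
    coding <- Filter(function(t) !is.null(t$cds_tx), txs)
    noncod <- Filter(function(t) is.null(t$cds_tx), txs)
    true_orfs <- list(); meta <- list()
    used_stops <- character()  # distinct true ORFs get distinct stop codons
    k <- 0L
    for (cat in names(true_orfs_per_category)) {
      pool <- if (cat == "lncRNA-ORF") noncod else coding
      if (!length(pool))
        stop("argument error: no eligible transcripts for category ", cat)
      placed <- 0L
      while (placed < true_orfs_per_category[[cat]]) {
        tx <- pool[[sample(length(pool), 1L)]]
        iv <- draw_true_interval(tx, cat)
        if (is.null(iv)) next
        tid <- sprintf("T%03d", k + 1L)
        rec <- orf_record(tid, tx$transcript_id, tx$chrom, tx$strand,
                          tx_interval_to_blocks(tx, iv[1L], iv[2L]),
                          start_codon = "ATG", category = cat,
                          dataset = "truth", caller = "truth",
                          replicate = "0", sample = "truth")
        stop_key <- paste(rec$chrom, rec$strand, rec$stop_codon_pos,
                          sep = "@")
        if (stop_key %in% used_stops) next
        used_stops <- c(used_stops, stop_key)
        k <- k + 1L; placed <- placed + 1L
        true_orfs[[tid]] <- rec
        # jitter headroom in codons: upstream limited by the hosting
        # region's floor (keeps the category), downstream by a 7-codon
        # minimum length
        floor_tx <- switch(cat,
                           uORF = 0L, uoORF = 0L, dORF = tx$cds_tx[2L],
                           intORF = tx$cds_tx[1L], doORF = tx$cds_tx[1L],
                           `lncRNA-ORF` = 0L)
        head_up <- min(3L, (iv[1L] - floor_tx) %/% 3L)
        # downstream jitter must keep >=7 codons and must not push the start
        # across a category boundary (uoORF start stays 5' of the CDS,
        # doORF start stays 5' of the CDS end)
        ceil_down <- switch(cat,
                            uoORF = (tx$cds_tx[1L] - 1L - iv[1L]) %/% 3L,
                            doORF = (tx$cds_tx[2L] - 1L - iv[1L]) %/% 3L,
                            .Machine$integer.max)
        head_down <- min(3L, (iv[2L] - iv[1L]) %/% 3L - 7L, ceil_down)
        meta[[tid]] <- list(tx = tx, iv = iv, head_up = max(0L, head_up),
                            head_down = max(0L, head_down), category = cat)
      }
    }
    callsets <- list(); truth_rows <- list()
    for (pr in profiles) {
      reps <- list()
      for (r in seq_len(n_replicates)) {
        calls <- list()
        for (tid in names(true_orfs)) {
          m <- meta[[tid]]
          bias <- if (m$category %in% names(pr$category_bias))
            pr$category_bias[[m$category]] else 1
          p_keep <- min(1, max(0, (1 - pr$dropout_prob) * bias))
          if (runif(1L) >= p_keep) next
          iv <- m$iv; jittered <- FALSE
          if (runif(1L) < pr$jitter_prob && (m$head_up + m$head_down) > 0L) {
            dirs <- c(if (m$head_up > 0L) "up", if (m$head_down > 0L) "down")
            dir <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
            j <- sample(seq_len(if (dir == "up") m$head_up else m$head_down),
                        1L)
            iv <- if (dir == "up") c(iv[1L] - 3L * j, iv[2L])
            else c(iv[1L] + 3L * j, iv[2L])
            jittered <- TRUE
          }
          cid <- paste(tid, pr$name, r, sep = ".")
          calls[[cid]] <- orf_record(
            cid, m$tx$transcript_id, m$tx$chrom, m$tx$strand,
            tx_interval_to_blocks(m$tx, iv[1L], iv[2L]),
            start_codon = "ATG", category = m$category, dataset = "sim",
            caller = pr$name, replicate = r, sample = paste0("s", r))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            orf_id = cid, true_cluster = tid, true_category = m$category,
            caller = pr$name, replicate = r, jittered = jittered)
        }
        n_spur <- rpois(1L, pr$spurious_rate)
        for (s in seq_len(n_spur)) {
          tx <- txs[[sample(length(txs), 1L)]]
          c_max <- tx$tx_length %/% 3L - 1L
          c_len <- sample(7:min(30L, c_max), 1L)
          len <- 3L * c_len
          st <- sample(0:(tx$tx_length - len), 1L)
          cid <- sprintf("N.%s.%d.%d", pr$name, r, s)
          calls[[cid]] <- orf_record(
            cid, tx$transcript_id, tx$chrom, tx$strand,
            tx_interval_to_blocks(tx, st, st + len),
            start_codon = sample(pr$start_codons, 1L), dataset = "sim",
            caller = pr$name, replicate = r, sample = paste0("s", r))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            orf_id = cid, true_cluster = "noise",
            true_category = NA_character_, caller = pr$name, replicate = r,
            jittered = FALSE)
        }
        reps[[as.character(r)]] <- calls
      }
      callsets[[pr$name]] <- reps
    }
    list(callsets = callsets,
         truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
           data.frame(orf_id = character(), true_cluster = character(),
                      true_category = character(), caller = character(),
                      replicate = integer(), jittered = logical()),
         true_orfs = true_orfs)
  })
}

#' Generate a synthetic P-site table
#'
#' Footprints land on CDS positions with probability `p_cds` (uniform over
#' coding transcripts and codons); a CDS P-site falls in frame 0 with
#' probability `periodicity`, else uniformly in frames 1/2. The remaining
#' footprints land on UTRs or noncoding transcripts (frame undefined). Read
#' lengths are drawn from `read_len_weights`.
#'
#' @param txs Transcriptome from [gen_transcriptome()].
#' @param periodicity In-frame probability over CDS positions, in `[0, 1]`.
#' @param depth Total footprint count; 0 yields an empty table.
#' @param read_len_weights Named weights over read lengths (default 28-30 nt,
#'   equal); must sum to a positive value.
#' @param p_cds Fraction of footprints on CDS regions (default 0.85, inside
#'   the >80% guideline for a good library).
#' @param seed Integer seed.
#' @return `data.frame` with columns `transcript_id`, `tx_position`,
#'   `read_length`, `count`, `frame`, `region`.
#' @export
gen_psite_table <- function(txs, periodicity, depth,
                            read_len_weights = c("28" = 1, "29" = 1, "30" = 1),
                            p_cds = 0.85, seed = 1L) {
  if (periodicity < 0 || periodicity > 1)
    stop("argument error: periodicity must be in [0, 1]")
  if (sum(read_len_weights) <= 0)
    stop("argument error: read length weights must sum to a positive value")
  empty <- data.frame(transcript_id = character(), tx_position = integer(),
                      read_length = integer(), count = integer(),
                      frame = integer(), region = character())
  if (depth == 0L) return(empty)
  with_seed(seed, {
    coding <- Filter(function(t) !is.null(t$cds_tx), txs)
    noncod <- Filter(function(t) is.null(t$cds_tx), txs)
    if (!length(coding)) p_cds <- 0
    n_cds <- rbinom(1L, depth, p_cds)
    rows <- list()
    rl <- as.integer(names(read_len_weights))
    if (n_cds > 0L) {
      ti <- sample(length(coding), n_cds, replace = TRUE)
      frame <- ifelse(runif(n_cds) < periodicity, 0L,
                      sample(1:2, n_cds, replace = TRUE))
      pos <- vapply(seq_len(n_cds), function(i) {
        tx <- coding[[ti[i]]]
        n_codons <- (tx$cds_tx[2L] - tx$cds_tx[1L]) %/% 3L
        tx$cds_tx[1L] + 3L * (sample(n_codons, 1L) - 1L) + frame[i]
      }, integer(1L))
      rows[[1L]] <- data.frame(
        transcript_id = vapply(ti, function(i)
          coding[[i]]$transcript_id, character(1L)),
        tx_position = pos,
        read_length = sample(rl, n_cds, replace = TRUE,
                             prob = read_len_weights),
        frame = frame, region = "CDS")
    }
    n_other <- depth - n_cds
    if (n_other > 0L) {
      oth <- lapply(seq_len(n_other), function(i) {
        if (length(noncod) && (runif(1L) < 0.5 || !length(coding))) {
          tx <- noncod[[sample(length(noncod), 1L)]]
          data.frame(transcript_id = tx$transcript_id,
                     tx_position = sample(tx$tx_length, 1L) - 1L,
                     read_length = sample(rl, 1L, prob = read_len_weights),
                     frame = NA_integer_, region = "noncoding")
        } else {
          tx <- coding[[sample(length(coding), 1L)]]
          in5 <- tx$cds_tx[1L] > 0L &&
            (runif(1L) < 0.5 || tx$cds_tx[2L] >= tx$tx_length)
          pos <- if (in5) sample(tx$cds_tx[1L], 1L) - 1L
          else tx$cds_tx[2L] + sample(tx$tx_length - tx$cds_tx[2L], 1L) - 1L
          data.frame(transcript_id = tx$transcript_id, tx_position = pos,
                     read_length = sample(rl, 1L, prob = read_len_weights),
                     frame = NA_integer_,
                     region = if (in5) "UTR5" else "UTR3")
        }
      })
      rows[[length(rows) + 1L]] <- do.call(rbind, oth)
    }
    df <- do.call(rbind, rows)
    df$frame[is.na(df$frame)] <- -1L  # sentinel: aggregate() drops NA keys
    agg <- aggregate(list(count = rep(1L, nrow(df))),
                     by = df[c("transcript_id", "tx_position", "read_length",
                               "frame", "region")],
                     FUN = sum)
    agg$frame[agg$frame == -1L] <- NA_integer_
    agg <- agg[order(agg$transcript_id, agg$tx_position, agg$read_length),
               c("transcript_id", "tx_position", "read_length", "count",
                 "frame", "region")]
    rownames(agg) <- NULL
    agg
  })
}

#' Generate peptide evidence from an explicit scenario
#'
#' The scenario pins down, per ORF, its Ribo-Seq/prediction flags and the
#' exact tryptic and HLA peptides to emit (offset, length, uniqueness,
#' sample and source); emitted peptides satisfy their specs exactly, so each
#' evidence tier is constructible by design.
#'
#' @param orfs Named list of [orf_record()]s (for protein lengths and,
#'   where present, sequences).
#' @param scenario Named list (by `orf_id`); each element may contain
#'   `riboseq_detected`, `insilico_predicted`, and `tryptic` / `hla` lists of
#'   peptide specs `list(offset=, len=, unique=, sample_id=, source_id=)`.
#' @param seed Seed for the synthetic residue letters used when an ORF has
#'   no `aa_seq`.
#' @return List with `peptides` (one [peptide_evidence()] table) and
#'   `records` (list of [evidence_record()]s ready for [assign_tier()]).
#' @export
gen_peptide_evidence <- function(orfs, scenario, seed = 1L) {
  with_seed(seed, {
    peps <- list(); records <- list()
    for (oid in names(scenario)) {
      sc <- scenario[[oid]]
      orf <- orfs[[oid]]
      if (is.null(orf)) stop("argument error: unknown orf_id '", oid, "'")
      aa_len <- orf_nt_length(orf) %/% 3L
      aa_seq <- if (!is.null(orf$aa_seq)) orf$aa_seq else
        paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                     aa_len, replace = TRUE), collapse = "")
      mk <- function(specs, type) {
        if (is.null(specs) || !length(specs)) return(NULL)
        do.call(rbind, lapply(seq_along(specs), function(i) {
          s <- specs[[i]]
          if (s$offset + s$len > aa_len)
            stop("argument error: peptide beyond ORF '", oid, "' (",
                 aa_len, " aa)")
          peptide_evidence(
            orf_id = oid,
            peptide_seq = substring(aa_seq, s$offset + 1L, s$offset + s$len),
            aa_start = s$offset,
            uniquely_mapping = if (is.null(s$unique)) TRUE else s$unique,
            evidence_type = type,
            sample_id = if (is.null(s$sample_id))
              paste0("sample", i) else s$sample_id,
            source_id = if (is.null(s$source_id))
              paste0("study", i) else s$source_id,
            orf_aa_len = aa_len)
        }))
      }
      tryp <- mk(sc$tryptic, "tryptic")
      hla <- mk(sc$hla, "hla")
      if (!is.null(tryp)) peps[[length(peps) + 1L]] <- tryp
      if (!is.null(hla)) peps[[length(peps) + 1L]] <- hla
      records[[oid]] <- evidence_record(
        oid,
        riboseq_detected = isTRUE(sc$riboseq_detected),
        insilico_predicted = isTRUE(sc$insilico_predicted),
        tryptic = tryp, hla = hla)
    }
    list(peptides = if (length(peps)) do.call(rbind, peps) else
      peptide_evidence(character(), character(), integer())[0L, ],
      records = records)
  })
}
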