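test_that("is_similar requires containment, shared stop, and the length fraction", {
  a <- ivl_orf("a", 100, 163)   # 60 nt excluding stop
  expect_true(is_similar(a, a, 1.0))
  # child = parent minus its first 2 codons, shared stop
  child <- ivl_orf("b", 106, 163)  # 54 nt excluding stop; 54/60 = 0.9
  expect_true(is_similar(child, a, 0.9))
  expect_false(is_similar(child, a, 0.95))
  # same interval, different stop codon position
  shifted <- ivl_orf("c", 103, 166)
  expect_false(is_similar(a, shifted, 0.5))
  # contained but on the opposite strand
  minus <- ivl_orf("d", 106, 163, strand = "-")
  expect_false(is_similar(minus, a, 0.5))
  # cross-chromosome comparison is FALSE, not an error
  other <- ivl_orf("e", 106, 163, chrom = "chr2")
  expect_false(is_similar(other, a, 0.5))
})

test_that("strict junction mode rejects containment across splice forms", {
  parent <- ivl_orf("p", 100, 163)
  spliced <- orf_record("s", NA_character_, "chr1", "+",
                        data.frame(start = c(118L, 130L),
                                   end = c(124L, 163L)))
  # base positions of the spliced child are inside the parent interval
  expect_true(is_similar(spliced, parent, 0.3))
  expect_false(is_similar(spliced, parent, 0.3, strict_junctions = TRUE))
})

test_that("a containment chain collapses to one unique ORF", {
  a <- ivl_orf("a", 130, 163)
  b <- ivl_orf("b", 115, 163)
  c <- ivl_orf("c", 100, 163)
  cl <- build_unique_clusters(list(a, b, c), min_frac = 0.5)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$members, "a,b,c")
  expect_identical(cl$representative, "c")  # longest member
  expect_identical(cl$length_nt, 60L)

  # different stop codons never merge
  d <- ivl_orf("d", 100, 163); e <- ivl_orf("e", 100, 190)
  expect_identical(nrow(build_unique_clusters(list(d, e), 0.1)), 2L)

  # min_frac = 1 with no exact duplicates: all singletons
  cl1 <- build_unique_clusters(list(a, b, c), min_frac = 1.0)
  expect_identical(nrow(cl1), 3L)

  expect_error(build_unique_clusters(list(a, a), 0.5), "duplicate orf_id")
})

test_that("clustering equals the brute-force union-find oracle", {
  for (seed in 1:40) {
    orfs <- random_orf_set(sample(5:30, 1), seed = seed)
    mf <- sample(c(0.3, 0.6, 0.9, 1.0), 1)
    got <- clusters_partition(build_unique_clusters(orfs, mf))
    expect_identical(got, oracle_partition(orfs, mf),
                     info = paste("seed", seed, "min_frac", mf))
  }
})

test_that("replicate sharing counts match direct enumeration on ground truth", {
  txs <- gen_transcriptome(40, 10, seed = 31)
  prof <- caller_profile("noisy", jitter_prob = 0, dropout_prob = 0.3)
  sim <- gen_orf_callsets(txs, c(uORF = 10, dORF = 8, intORF = 6),
                          list(prof), n_replicates = 6, seed = 32)
  curve <- replicate_sharing_curve(sim$callsets$noisy, min_frac_grid = 0.9,
                                   k_values = c(1, 3, 6))
  # direct enumeration: replicates carrying each true cluster
  reps_per_cluster <- tapply(sim$truth$replicate, sim$truth$true_cluster,
                             function(r) length(unique(r)))
  for (k in c(1, 3, 6)) {
    expect_identical(curve$n_unique_shared[curve$k == k],
                     sum(reps_per_cluster >= k), info = paste("k", k))
  }
  # monotone in k
  expect_true(all(diff(curve$n_unique_shared) <= 0))
})

test_that("degenerate replicate structures behave as stated", {
  base <- lapply(1:4, function(i) ivl_orf(paste0("x", i),
                                          100 * i, 100 * i + 33))
  # identical call sets in 6 replicates: shared-in->=6 equals the
  # per-replicate unique count
  sets <- lapply(1:6, function(r)
    lapply(base, function(o) {
      o2 <- o; o2$orf_id <- paste0(o$orf_id, "_r", r)
      o2$source$replicate <- as.character(r); o2
    }))
  curve <- replicate_sharing_curve(sets, min_frac_grid = c(0.5, 1),
                                   k_values = 6)
  expect_true(all(curve$n_unique_shared == 4L))
  # k above the replicate count gives 0, not an error
  over <- replicate_sharing_curve(sets, min_frac_grid = 1, k_values = 7)
  expect_identical(over$n_unique_shared, 0L)
  # disjoint call sets: nothing shared by >= 2
  disjoint <- lapply(1:3, function(r)
    list(ivl_orf(paste0("d", r), 1000 * r, 1000 * r + 33,
                 replicate = r)))
  d <- replicate_sharing_curve(disjoint, min_frac_grid = 0.5, k_values = 2)
  expect_identical(d$n_unique_shared, 0L)
})

test_that("threshold and k monotonicity hold over random instances", {
  grid <- c(1.0, 0.9, 0.6, 0.3)
  for (seed in 101:120) {
    orfs <- random_orf_set(sample(8:25, 1), seed = seed)
    n_clusters <- vapply(grid, function(mf)
      nrow(build_unique_clusters(orfs, mf)), integer(1))
    # lowering min_frac never increases the number of unique clusters
    expect_true(all(diff(n_clusters) <= 0), info = paste("seed", seed))
  }
})

test_that("category composition and length distribution report representatives", {
  mk <- function(id, s, e, cat, rep_) ivl_orf(id, s, e, category = cat,
                                              replicate = rep_)
  orfs <- list(mk("u1", 100, 133, "uORF", 1), mk("u2", 200, 233, "uORF", 1),
               mk("u3", 300, 333, "uORF", 2), mk("d1", 400, 433, "dORF", 1))
  cl <- build_unique_clusters(orfs, 0.5)
  comp <- category_composition(cl, k = 1)
  expect_equal(sum(comp$percent), 100)
  expect_equal(comp$percent[comp$category == "uORF"], 75)
  expect_equal(comp$percent[comp$category == "dORF"], 25)
  expect_identical(length_distribution(cl, k = 1), rep(30L, 4))
  expect_identical(nrow(category_composition(cl[0, ], 1)), 0L)

  # jittered clusters: representative length equals the true (longest) length
  parent <- ivl_orf("p", 100, 163)
  jit <- ivl_orf("j", 109, 163)
  cl2 <- build_unique_clusters(list(parent, jit), 0.5)
  expect_identical(length_distribution(cl2), 60L)
})

test_that("a biased caller inflates its favoured category share", {
  txs <- gen_transcriptome(60, 10, seed = 41)
  fair <- caller_profile("fair", dropout_prob = 0.5)
  biased <- caller_profile("biased", dropout_prob = 0.5,
                           category_bias = c(intORF = 2))
  truth_counts <- c(uORF = 15, intORF = 15, dORF = 15)
  share <- function(prof, seed) {
    sim <- gen_orf_callsets(txs, truth_counts, list(prof),
                            n_replicates = 4, seed = seed)
    pooled <- unlist(sim$callsets[[prof$name]], recursive = FALSE,
                     use.names = FALSE)
    cl <- build_unique_clusters(pooled, 0.9)
    comp <- category_composition(cl)
    comp$percent[comp$category == "intORF"]
  }
  expect_gt(share(biased, 42), share(fair, 42))
})
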