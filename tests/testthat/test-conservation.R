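test_that("pairwise identity matches direct cases and its own emitted alignment", {
  expect_equal(pairwise_identity("ACGU", "ACGU"), 1.0)
  expect_equal(pairwise_identity("ACGU", "ACGG"), 0.75)
  expect_error(pairwise_identity("", "ACGU"), "empty")

  ## recount oracle: identity recomputed from the emitted alignment
  for (i in 1:30) {
    a <- random_rna(sample(20:40, 1), seed = 2 * i)
    b <- random_rna(sample(20:40, 1), seed = 2 * i + 1)
    id <- pairwise_identity(a, b, details = TRUE)
    pa <- strsplit(attr(id, "aligned_a"), "")[[1]]
    sa <- strsplit(attr(id, "aligned_b"), "")[[1]]
    expect_false(any(pa == "-" & sa == "-"))          # no dual-gap columns
    expect_equal(as.numeric(id), sum(pa == sa & pa != "-") / length(pa))
  }
})

test_that("single-linkage clustering honors the cutoff and discards singletons", {
  ## two identical pairs with low cross-identity
  a <- "ACGUACGUACGUACGUACGU"
  b <- "UGCAUGGAUCCAUGCAAGGA"
  seqs <- c(a1 = a, a2 = a, b1 = b, b2 = b)
  cross <- pairwise_identity(a, b)
  expect_lt(cross, 0.5)
  rep_high <- cluster_at_identity(seqs, 0.95)
  expect_equal(length(rep_high$clusters), 2L)
  rep_low <- cluster_at_identity(seqs, cross - 0.05)
  expect_equal(length(rep_low$clusters), 1L)
  expect_equal(sort(rep_low$clusters[[1]]), c("a1", "a2", "b1", "b2"))

  ## singleton discarded and counted
  seqs2 <- c(seqs, lone = random_rna(20, seed = 99))
  rep2 <- cluster_at_identity(seqs2, 0.95)
  expect_equal(rep2$singletons_discarded, 1L)
  expect_false("lone" %in% unlist(rep2$clusters))
  ## every member appears in at most one cluster
  expect_equal(anyDuplicated(unlist(rep2$clusters)), 0L)
})

test_that("cluster counts rise with the cutoff on hierarchical families", {
  ## three families, each of two tight subfamilies of three members
  anatomy <- default_antar_anatomy()
  seqs <- character(0)
  k <- 0
  for (fam in 1:3) {
    base <- sample_motif(anatomy, loop_mutation_rate = 0.5,
                         stem_mutation_rate = 0.5, seed = 1000 + fam)
    for (sub in 1:2) {
      center <- antarscan:::with_seed(fam * 10 + sub, {
        mutate_rna(base$sequence, 0.30)
      })
      for (m in 1:3) {
        k <- k + 1
        seqs[sprintf("f%ds%dm%d", fam, sub, m)] <-
          antarscan:::with_seed(k + 500, mutate_rna(center, 0.05))
      }
    }
  }
  sw <- sweep_clusters(seqs, cutoffs = seq(0.30, 0.60, by = 0.03))
  expect_true(all(diff(sw$n_clusters) >= 0))
  expect_true(all(diff(sw$largest_cluster) <= 0))
})

test_that("simplified folding matches forced structures and rejects bad input", {
  f <- fold_simplified("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$energy, -9)
  f2 <- fold_simplified("AAAAAA")
  expect_equal(f2$structure, "......")
  expect_equal(f2$energy, 0)
  expect_error(fold_simplified("ACGX"), "alphabet")
  ## balanced brackets always
  f3 <- fold_simplified(random_rna(60, seed = 5, gc = 0.6))
  op <- lengths(regmatches(f3$structure, gregexpr("\\(", f3$structure)))
  cl <- lengths(regmatches(f3$structure, gregexpr("\\)", f3$structure)))
  expect_equal(op, cl)
})

test_that("folding DP equals exhaustive enumeration on short sequences", {
  for (i in 1:150) {
    len <- 5 + (i %% 8)
    seq <- random_rna(len, seed = 3000 + i, gc = 0.55)
    expect_equal(fold_simplified(seq)$energy, oracle_fold_best(seq),
                 info = seq)
  }
})

test_that("SCI is 1 for identical rows, near 0 without common pairing, symmetric", {
  rows <- rep("GGGGAAAACCCCAAAAGGGGAAAACCCC", 5)
  res <- compute_sci(rows)
  expect_equal(res$sci, 1.0)
  expect_lt(res$consensus_energy, 0)

  ## rows folding at disjoint column windows: no common pairing, so the
  ## compatibility scaling drives the consensus energy to ~0
  anti <- c("GGGGAAAACCCCAAAAAAAAAAAA",
            "AAAAAAGGGGAAAACCCCAAAAAA",
            "AAAAAAAAAAAAGGGGAAAACCCC")
  res_anti <- compute_sci(anti)
  expect_lt(res_anti$mean_individual_energy, -10)
  expect_gte(res_anti$sci, 0)
  expect_lt(res_anti$sci, 0.2)

  ## invariant under row order permutation
  rows2 <- c("GGGAAACCCAAAGGGAAACCC", "GGGAAACCCAAAGGGAAACCU",
             "GGGAAACCCAAAGGGAAACCA")
  expect_equal(compute_sci(rows2)$sci, compute_sci(rev(rows2))$sci)

  ## all-gap column dropped with a notice
  gappy <- c("GGG-AAACCC", "GGG-AAACCC")
  expect_message(res_gap <- compute_sci(gappy), "all-gap")
  expect_equal(res_gap$sci, 1.0)
})

test_that("folding z-scores behave as standardized stability measures", {
  ## homopolymer: all shuffles identical, sd = 0 -> z = 0
  expect_equal(compute_zscore("AAAAAAAAAA", n_shuffles = 30, seed = 1), 0)

  ## population mean over random sequences is ~0 (mononucleotide null is
  ## exchangeable with the sequence itself)
  zs <- vapply(1:120, function(i)
    compute_zscore(random_rna(40, seed = 5000 + i), n_shuffles = 40,
                   mode = "mono", seed = i), numeric(1))
  expect_lt(abs(mean(zs)), 0.15)

  ## a strong planted dual stem-loop is stabler than its shuffles
  z <- compute_zscore(strong_anatomy()$sequence, n_shuffles = 100,
                      mode = "mono", seed = 11)
  expect_lt(z, -1)
})

test_that("column conservation reports loop and stem fractions by recount", {
  seed <- make_identical_seed(n = 8)
  cc <- column_conservation(seed$rows, seed$annotation)
  expect_equal(cc$loop1_A1_fraction, 1.0)
  expect_equal(cc$loop1_G4_fraction, 1.0)
  expect_equal(cc$loop2_A1_fraction, 1.0)
  expect_equal(cc$loop2_G4_fraction, 1.0)
  expect_equal(cc$mean_stem_pair_conservation, 1.0)

  ## mutate loop1 position 1 in half the rows
  rows <- seed$rows
  l1 <- seed$annotation$hairpins[[1]]$loop_cols[1]
  for (i in 1:4) substr(rows[i], l1, l1) <- "C"
  cc2 <- column_conservation(rows, seed$annotation)
  expect_equal(cc2$loop1_A1_fraction, 0.5)
  expect_equal(cc2$loop2_A1_fraction, 1.0)

  ## recount oracle on a random alignment
  aln <- fix_seed_aln()
  cc3 <- column_conservation(aln$rows, aln$annotation)
  mat <- do.call(rbind, strsplit(aln$rows, ""))
  expect_equal(cc3$loop1_A1_fraction,
               mean(mat[, aln$annotation$hairpins[[1]]$loop_cols[1]] == "A"))
  expect_equal(cc3$loop2_G4_fraction,
               mean(mat[, aln$annotation$hairpins[[2]]$loop_cols[4]] == "G"))
  expect_error(column_conservation(c("ACGU", "ACGU"), aln$annotation),
               "length")
})

test_that("mutual information detects perfect covariation and independence", {
  ## alternating AU / GC at a column pair: 1 bit
  rows <- rep(c("AAAU", "GAAC"), 5)
  expect_equal(pair_covariation(rows, rbind(c(1, 4))), 1.0)
  ## symmetry
  expect_equal(pair_covariation(rows, rbind(c(4, 1))), 1.0)
  ## independent columns: MI near 0 (small-sample bias only)
  rows2 <- vapply(1:200, function(i) random_rna(4, seed = 7000 + i),
                  character(1))
  expect_lt(pair_covariation(rows2, rbind(c(1, 4))), 0.1)
})

test_that("cluster statistics flag conserved stable families", {
  anatomy <- strong_anatomy(stem_bp = 8)
  members <- vapply(1:4, function(i)
    sample_motif(anatomy, loop_mutation_rate = 0.05,
                 stem_mutation_rate = 0.10, seed = 40 + i)$sequence,
    character(1))
  names(members) <- paste0("m", 1:4)
  st <- cluster_stats(members, n_shuffles = 60, seed = 2)
  expect_gt(st$sci, 0.4)
  expect_lt(st$mean_zscore, -0.5)
  expect_true(st$functional_candidate)
})
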