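test_that("p-distance counts differing sites and masks X", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AXAA", "AAAT"), 1 / 3)  # X site excluded
  expect_error(p_distance("AAA", "AAAA"), "equal-length")
  expect_error(p_distance("XX", "AA"), "comparable")

  # brute-force Hamming fraction on random 16-mers
  set.seed(61)
  for (i in 1:1000) {
    a <- random_aa_string(16)
    b <- random_aa_string(16)
    hand <- sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]]) / 16
    expect_equal(p_distance(a, b), hand)
  }
})

test_that("p-distance matrices are symmetric, bounded, zero-diagonal", {
  set.seed(62)
  aln <- stats::setNames(vapply(rep(16, 8), random_aa_string,
                                character(1L)), letters[1:8])
  d <- p_distance_matrix(aln)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 8))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("three-taxon NJ matches the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # a = (dAB+dAC-dBC)/2 = 1, b = 2, c = 3
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d)
})

test_that("NJ input validation rejects malformed matrices", {
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3L,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d), "symmetric")
  d2 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3L,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d2), "non-negative")
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
})

test_that("NJ recovers additive trees and agrees with an independent NJ", {
  set.seed(63)
  for (i in 1:25) {
    gen <- random_additive_tree(sample(8:16, 1L))
    dm <- ape::cophenetic.phylo(gen)
    ord <- sort(rownames(dm))
    tr <- neighbor_joining(dm[ord, ord])
    expect_equal(as.numeric(ape::dist.topo(tr, gen)), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
                      - dm)), 1e-9)
    # independent implementation agrees on topology
    ref <- ape::nj(dm)
    expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
  }
})

test_that("NJ topology is invariant to input row order", {
  set.seed(64)
  aln <- stats::setNames(vapply(rep(16, 10), random_aa_string,
                                character(1L)), letters[1:10])
  d <- p_distance_matrix(aln)
  t1 <- neighbor_joining(d)
  perm <- sample(10)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("bootstrap supports are deterministic and label-symmetric", {
  set.seed(65)
  centers <- vapply(rep(16, 3), random_aa_string, character(1L))
  aln <- stats::setNames(
    c(centers[1], mutate_sites(centers[1], 0.06),
      centers[2], mutate_sites(centers[2], 0.06),
      centers[3], mutate_sites(centers[3], 0.06)),
    sprintf("s%d", 1:6))
  t1 <- bootstrap_support(aln, n_reps = 200, seed = 9)
  t2 <- bootstrap_support(aln, n_reps = 200, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))

  # relabeling leaves permutes but does not change the support multiset
  aln2 <- stats::setNames(aln, sprintf("z%d", 6:1))
  t3 <- bootstrap_support(aln2, n_reps = 200, seed = 9)
  expect_setequal(t3$node.label, t1$node.label)
})

test_that("tree cutting recovers planted groups and degenerate ks", {
  set.seed(66)
  # 15 well-separated families of 3-5 motif-like 16-mers
  labels <- character(0); seqs <- character(0); truth <- character(0)
  for (f in 1:15) {
    center <- random_aa_string(16)
    n <- sample(3:5, 1L)
    for (m in seq_len(n)) {
      s <- if (m == 1L) center else mutate_sites(center, 1 / 16)
      labels <- c(labels, sprintf("f%02d_m%d", f, m))
      seqs <- c(seqs, s)
      truth <- c(truth, sprintf("f%02d", f))
    }
  }
  aln <- stats::setNames(seqs, labels)
  tr <- neighbor_joining(p_distance_matrix(aln))
  groups <- cut_tree_groups(tr, 15L)
  expect_equal(mclust::adjustedRandIndex(groups[labels], truth), 1)

  # k = 1: single group; k = n: every leaf its own group
  expect_equal(length(unique(cut_tree_groups(tr, 1L))), 1L)
  gn <- cut_tree_groups(tr, length(aln))
  expect_equal(length(unique(gn)), length(aln))
  expect_error(cut_tree_groups(tr, length(aln) + 1L), "exceeds")
})
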