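test_that("identical sequences align at 100 percent", {
  r <- global_align_percent("ACDEFG", "ACDEFG")
  expect_equal(r$identity, 100)
  expect_equal(r$similarity, 100)
  expect_equal(r$coverage, 1)
  expect_error(global_align_percent("", "ACD"), "empty")
})

test_that("percent identity is symmetric on random pairs", {
  set.seed(51)
  for (i in 1:100) {
    a <- random_aa_string(sample(5:40, 1L))
    b <- random_aa_string(sample(5:40, 1L))
    fab <- global_align_percent(a, b)
    fba <- global_align_percent(b, a)
    expect_equal(fab$identity, fba$identity)
    expect_equal(fab$score, fba$score)
  }
})

test_that("alignment scores equal exhaustive enumeration on short pairs", {
  set.seed(52)
  mat <- blosum62_test()
  for (i in 1:60) {
    a <- random_aa_string(sample(1:6, 1L))
    b <- random_aa_string(sample(1:6, 1L))
    r <- global_align_percent(a, b)
    all_al <- enum_alignments(a, b, mat)
    best <- max(all_al[, 1L])
    expect_equal(r$score, best)
    # returned identity is realized by some optimal alignment
    opt <- all_al[all_al[, 1L] == best, , drop = FALSE]
    ids <- 100 * opt[, 2L] / opt[, 3L]
    expect_true(any(abs(ids - r$identity) < 1e-9))
  }
})

test_that("planted divergence shows up as ~90 percent identity", {
  set.seed(53)
  for (i in 1:10) {
    ref <- random_aa_string(200)
    q <- mutate_sites(ref, 0.10)
    r <- global_align_percent(q, ref)
    # substitution-only divergence: identity tracks the untouched fraction
    p_mut <- 0.10
    se <- sqrt(p_mut * (1 - p_mut) / 200)
    expect_lt(abs(r$identity / 100 - (1 - p_mut)), 4 * se)
  }
})

test_that("similarity matrices are complete, bounded and ordered", {
  set.seed(54)
  refs <- data.frame(id = c("r1", "r2", "r3"), species = "At",
                     sequence = vapply(rep(60, 3), random_aa_string,
                                       character(1L)))
  db <- reference_db(refs, c(r1 = "G1", r2 = "G1", r3 = "G2"))
  queries <- data.frame(id = c("q1", "r1"), species = "Cr",
                        sequence = c(random_aa_string(50),
                                     refs$sequence[1L]))
  m <- build_similarity_matrix(queries, db, ref_order = c("r3", "r1", "r2"))
  expect_equal(dim(m$similarity), c(2L, 3L))
  expect_equal(colnames(m$similarity), c("r3", "r1", "r2"))
  expect_true(all(m$similarity >= 0 & m$similarity <= 100))
  # duplicate id disambiguated by prefixing
  expect_true("q:r1" %in% rownames(m$similarity))
  # the copied reference aligns to itself at 100
  expect_equal(m$identity["q:r1", "r1"], 100)

  # 1x1 identity case
  m1 <- build_similarity_matrix(queries[2L, ], db)
  expect_equal(unname(m1$similarity[1L, "r1"]), 100)
})

test_that("group assignment applies thresholds and tie rules", {
  set.seed(55)
  base <- random_aa_string(80)
  refs <- data.frame(id = c("a7", "b2"), species = "At",
                     sequence = c(base, base))
  db <- reference_db(refs, c(a7 = "G7", b2 = "G2"))
  queries <- data.frame(id = "q1", species = "Cr", sequence = base)
  m <- build_similarity_matrix(queries, db)
  asn <- assign_groups(m, db)
  # perfect tie on similarity and identity: lexicographically smaller id
  expect_equal(asn$best_ref, "a7")
  expect_equal(asn$group, "G7")

  # random unrelated sequences stay unassigned at default thresholds
  set.seed(56)
  refs2 <- data.frame(id = "ref1", species = "At",
                      sequence = random_aa_string(300))
  db2 <- reference_db(refs2, c(ref1 = "G1"))
  rand_q <- data.frame(id = sprintf("q%02d", 1:40), species = "Zz",
                       sequence = vapply(rep(300, 40), random_aa_string,
                                         character(1L)))
  m2 <- build_similarity_matrix(rand_q, db2)
  asn2 <- assign_groups(m2, db2)
  expect_true(all(is.na(asn2$group)))
})

test_that("orthology fraction counts covered reference members", {
  refs <- data.frame(id = sprintf("r%d", 1:9), species = "At",
                     sequence = strrep("A", 30L))
  db <- reference_db(refs, stats::setNames(rep("G7", 9L), refs$id))
  asn <- data.frame(query_id = sprintf("q%d", 1:7),
                    best_ref = sprintf("r%d", 1:7),
                    similarity = 90, identity = 90, coverage = 1,
                    group = "G7", stringsAsFactors = FALSE)
  of <- group_orthology_fraction(db, asn)
  expect_equal(round(of$percent, 1), 77.8)
  # no assignments -> 0; every member covered -> 100
  asn0 <- asn[0L, ]
  expect_equal(group_orthology_fraction(db, asn0)$percent, 0)
  asn9 <- data.frame(query_id = sprintf("q%d", 1:9),
                     best_ref = sprintf("r%d", 1:9),
                     similarity = 90, identity = 90, coverage = 1,
                     group = "G7", stringsAsFactors = FALSE)
  expect_equal(group_orthology_fraction(db, asn9)$percent, 100)
})

test_that("homolog families are recovered from evolved sequences", {
  # synthetic families at moderate divergence: the generating family is
  # recovered for (nearly) every query at default thresholds
  set.seed(57)
  n_fam <- 12L
  refs <- list(); queries <- list(); truth <- character(0)
  for (f in seq_len(n_fam)) {
    anc <- random_aa_string(150)
    fam <- evolve_family(anc, "(ref:0.1,query:0.1);")
    refs[[f]] <- data.frame(id = sprintf("ref%02d", f), species = "At",
                            sequence = fam[["ref"]])
    queries[[f]] <- data.frame(id = sprintf("q%02d", f), species = "Cr",
                               sequence = fam[["query"]])
    truth <- c(truth, sprintf("G%d", f))
  }
  refdf <- do.call(rbind, refs)
  db <- reference_db(refdf, stats::setNames(truth, refdf$id))
  m <- build_similarity_matrix(do.call(rbind, queries), db)
  asn <- assign_groups(m, db)
  expect_gte(mean(asn$group == truth, na.rm = TRUE), 0.99)
  expect_true(all(!is.na(asn$group)))
})
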