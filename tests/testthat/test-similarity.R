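balanced4 <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")

test_that("identical normalized profiles score 1 on any tree", {
  set.seed(11)
  for (i in 1:5) {
    tr <- random_tree(sample(4:20, 1))
    p <- abundance_profile("p", random_profile(tr))
    expect_equal(pairwise_similarity(p, p, tr, decay = runif(1)), 1,
                 tolerance = 1e-12)
  }
})

test_that("disjoint support with decay 0 scores 0", {
  a <- abundance_profile("a", c(t1 = 0.5, t2 = 0.5))
  b <- abundance_profile("b", c(t3 = 0.5, t4 = 0.5))
  expect_equal(pairwise_similarity(a, b, balanced4, decay = 0), 0)
})

test_that("4-leaf balanced tree example matches the recursion oracle", {
  a <- c(t1 = 0.5, t2 = 0.5, t3 = 0, t4 = 0)
  b <- c(t1 = 0, t2 = 0.5, t3 = 0.25, t4 = 0.25)
  # decay = 1: all residual reaches the root unattenuated; the oracle
  # evaluates to 1 (full-propagation degeneracy)
  expect_equal(oracle_similarity(a, b, balanced4, 1), 1)
  expect_equal(pairwise_similarity(a, b, balanced4, decay = 1), 1)
  # decay = 0.5: leaf match 0.5 at t2, halved residuals meet at the root
  expect_equal(oracle_similarity(a, b, balanced4, 0.5), 0.625)
  expect_equal(pairwise_similarity(a, b, balanced4, decay = 0.5), 0.625)
})

test_that("similarity is symmetric, bounded, and matches the oracle", {
  set.seed(42)
  for (i in 1:50) {
    tr <- random_tree(sample(4:16, 1))
    a <- random_profile(tr)
    b <- random_profile(tr)
    d <- runif(1)
    sab <- pairwise_similarity(a, b, tr, decay = d)
    expect_identical(sab, pairwise_similarity(b, a, tr, decay = d))
    expect_gte(sab, 0)
    expect_lte(sab, 1)
    expect_equal(sab, oracle_similarity(a, b, tr, d), tolerance = 1e-12)
  }
})

test_that("similarity is non-decreasing in decay", {
  set.seed(7)
  for (i in 1:20) {
    tr <- random_tree(10)
    a <- random_profile(tr)
    b <- random_profile(tr)
    s <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
      pairwise_similarity(a, b, tr, decay = d)
    }, numeric(1))
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("invalid profiles are rejected with context", {
  a <- abundance_profile("a", c(t1 = 0.5, t2 = 0.5))
  bad <- abundance_profile("weird", c(t1 = 0.5, tX = 0.5))
  expect_error(pairwise_similarity(a, bad, balanced4), "tX")
  expect_error(pairwise_similarity(a, bad, balanced4), "weird")
  expect_error(abundance_profile("u", c(t1 = 0.4, t2 = 0.4)),
               "not normalized")
  expect_error(abundance_profile("n", c(t1 = -0.1, t2 = 1.1)),
               "nonnegative")
  expect_equal(sum(abundance_profile("ok", c(t1 = 2, t2 = 6),
                                     normalize = TRUE)$abundance), 1)
})

test_that("multifurcations are resolved with zero-length branches", {
  tr <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  p <- prepare_tree(tr)
  expect_true(ape::is.binary(p))
  a <- abundance_profile("a", c(t1 = 1))
  b <- abundance_profile("b", c(t2 = 1))
  s <- pairwise_similarity(a, b, tr, decay = 0.5)
  # each residual crosses one unit-length edge (scale 0.5) plus possibly a
  # zero-length resolution edge (scale 1) before meeting: min(0.5, 0.5)
  expect_equal(s, 0.5)
})

test_that("similarity_matrix equals independent pairwise calls", {
  set.seed(3)
  tr <- random_tree(8)
  profs <- lapply(1:5, function(i) {
    abundance_profile(paste0("s", i), random_profile(tr))
  })
  m <- similarity_matrix(profs, tr, decay = 0.5)
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(m[i, j],
                   pairwise_similarity(profs[[i]], profs[[j]], tr, 0.5),
                   tolerance = 1e-12)
    }
  }
  expect_equal(diag(m), setNames(rep(1, 5), paste0("s", 1:5)))
})

test_that("similarity_matrix is deterministic in the worker count", {
  set.seed(4)
  tr <- random_tree(12)
  profs <- lapply(1:10, function(i) {
    abundance_profile(paste0("s", i), random_profile(tr))
  })
  m1 <- similarity_matrix(profs, tr, workers = 1)
  m4 <- similarity_matrix(profs, tr, workers = 4)
  expect_identical(m1, m4)
})

test_that("identical profiles give an all-ones matrix", {
  tr <- balanced4
  p <- c(t1 = 0.25, t2 = 0.25, t3 = 0.25, t4 = 0.25)
  profs <- lapply(1:3, function(i) abundance_profile(paste0("s", i), p))
  m <- similarity_matrix(profs, tr)
  expect_equal(unname(m), matrix(1, 3, 3))
})

test_that("duplicate sample ids are rejected", {
  tr <- balanced4
  p <- c(t1 = 0.5, t2 = 0.5)
  profs <- list(abundance_profile("s1", p), abundance_profile("s1", p))
  expect_error(similarity_matrix(profs, tr), "duplicate")
})

test_that("threshold_network keeps the diagonal and cuts below t", {
  m <- matrix(c(1, 0.65, 0.75, 0.85,
                0.65, 1, 0.85, 0.65,
                0.75, 0.85, 1, 0.75,
                0.85, 0.65, 0.75, 1), 4, 4)
  dimnames(m) <- list(letters[1:4], letters[1:4])
  t0 <- threshold_network(m, 0)
  expect_identical(t0, m)
  t8 <- threshold_network(m, 0.8)
  off <- t8[upper.tri(t8)]
  expect_true(all(off %in% c(0, 0.85)))
  expect_equal(sum(off == 0.85), sum(m[upper.tri(m)] == 0.85))
  expect_equal(diag(t8), diag(m))
  t1 <- threshold_network(m, 1)
  expect_true(all(t1[upper.tri(t1)] == 0))
  expect_error(threshold_network(m, 1.5), "\\[0, 1\\]")
})
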