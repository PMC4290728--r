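ref6 <- function(per_class = 2) reference_clusters(even_labels(per_class))

test_that("all metrics equal 1 when detected equals the reference", {
  ref <- ref6()
  fm <- f_measure(ref, ref)
  expect_equal(fm, list(precision = 1, recall = 1, f = 1))
  expect_equal(pr_metric(ref, ref), 1)
  expect_equal(f_score(ref, ref), 1)
})

test_that("metrics are invariant to cluster relabeling and order", {
  labels <- even_labels(3)
  ref <- reference_clusters(labels)
  det <- community(rev(setNames(ref$clusters,
                                paste0("blob", seq_along(ref$clusters)))),
                   sample_ids = ref$sample_ids)
  expect_equal(f_measure(det, ref)$f, 1)
  expect_equal(pr_metric(det, ref), 1)
  expect_equal(f_score(det, ref), 1)
})

test_that("one giant cluster fails the affinity match against 6 classes", {
  ref <- ref6(2)
  det <- community(list(all = ref$sample_ids), sample_ids = ref$sample_ids)
  # affinity of the 12-sample cluster with each 2-sample class:
  # |C n R|^2 / (|C| |R|) = 4 / 24 = 1/6 < 0.25
  fm <- f_measure(det, ref, omega = 0.25)
  expect_equal(fm, list(precision = 0, recall = 0, f = 0))
})

test_that("one matched plus one garbage cluster halves the precision", {
  ref <- ref6(2)
  garbage <- vapply(ref$clusters, `[`, "", 1)[2:6]  # one sample per class
  det <- community(list(good = ref$clusters[[1]],
                        junk = unname(garbage)),
                   unassigned = setdiff(ref$sample_ids,
                                        c(ref$clusters[[1]], garbage)),
                   sample_ids = ref$sample_ids)
  fm <- f_measure(det, ref, omega = 0.25)
  expect_equal(fm$precision, 1 / 2)
  expect_equal(fm$recall, 1 / 6)
  expect_equal(fm$f, 2 * (1 / 2) * (1 / 6) / (1 / 2 + 1 / 6))
})

test_that("pair PR matches hand enumeration on a 6-sample toy", {
  labels <- even_labels(1)[1:6, ]
  labels$habitat <- rep(c("gut", "skin", "oral"), each = 2)
  labels$gender <- "male"
  ref <- reference_clusters(labels)  # 3 classes of 2
  ids <- labels$sample_id
  # detected merges the first two classes
  det <- community(list(m = ids[1:4], o = ids[5:6]), sample_ids = ids)
  # reference pairs: 3; detected pairs: C(4,2) + 1 = 7; shared: 3
  p <- 3 / 7
  r <- 1
  expect_equal(pr_metric(det, ref), 2 * p * r / (p + r))
  expect_equal(pr_metric(det, ref), oracle_pr(det, ref))
})

test_that("all-singleton detection scores 0 pair PR", {
  ref <- ref6(2)
  det <- community(as.list(setNames(ref$sample_ids, ref$sample_ids)),
                   sample_ids = ref$sample_ids)
  expect_equal(pr_metric(det, ref), 0)
})

test_that("pair PR equals the brute-force oracle on random instances", {
  set.seed(61)
  for (i in 1:20) {
    labels <- even_labels(2)
    ids <- labels$sample_id
    k <- sample(2:5, 1)
    assign <- sample.int(k, length(ids), replace = TRUE)
    det <- community(split(ids, assign), sample_ids = ids)
    ref <- reference_clusters(labels)
    expect_equal(pr_metric(det, ref), oracle_pr(det, ref),
                 tolerance = 1e-12)
  }
})

test_that("F-score: merging two equal classes gives 2/3 on them", {
  labels <- even_labels(2)[1:8, ]  # 4 classes x 2
  ref <- reference_clusters(labels)
  ids <- labels$sample_id
  det <- community(list(merged = ids[1:4],
                        c3 = ids[5:6], c4 = ids[7:8]),
                   sample_ids = ids)
  # classes 1 and 2: best F1 = 2 * (1/2 * 1) / (1/2 + 1) = 2/3 each
  expect_equal(f_score(det, ref),
               (2 * (2 / 3) + 2 * (2 / 3) + 2 * 1 + 2 * 1) / 8)
})

test_that("a reference class missed entirely contributes 0", {
  ref <- ref6(2)
  det <- community(ref$clusters[1:5],
                   unassigned = ref$clusters[[6]],
                   sample_ids = ref$sample_ids)
  expect_equal(f_score(det, ref), 5 * 2 / 12)
  expect_equal(f_measure(det, ref)$recall, 5 / 6)
})

test_that("metric outputs stay within [0, 1] on random communities", {
  set.seed(62)
  for (i in 1:25) {
    labels <- even_labels(sample(1:3, 1))
    ids <- labels$sample_id
    k <- sample(2:6, 1)
    det <- community(split(ids, sample.int(k, length(ids), replace = TRUE)),
                     sample_ids = ids)
    ref <- reference_clusters(labels)
    fm <- f_measure(det, ref)
    for (v in c(fm$precision, fm$recall, fm$f, pr_metric(det, ref),
                f_score(det, ref))) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("composition table tallies meta-classes with dominant labels", {
  labels <- data.frame(
    sample_id = sprintf("g%d", 1:5),
    habitat = "gut", gender = "male", stringsAsFactors = FALSE)
  det <- community(list(c1 = labels$sample_id))
  tab <- composition_table(det, labels)
  expect_equal(unname(tab["c1", "male_gut"]), 5L)
  expect_equal(sum(tab), 5L)
  expect_equal(attr(tab, "dominant"), "male_gut")

  # perfect clustering of a planted 6-class cohort is diagonal
  labels6 <- even_labels(2)
  ref <- reference_clusters(labels6)
  tab6 <- composition_table(ref, labels6)
  expect_equal(unname(diag(tab6[metaclust:::META_CLASSES, ])),
               rep(2L, 6))
  expect_equal(sum(tab6), 12L)

  expect_error(
    composition_table(community(list(a = "mystery")), labels),
    "mystery")
})

test_that("composition counts overlapping samples in every cluster", {
  labels <- even_labels(2)
  ids <- labels$sample_id
  det <- community(list(a = ids[1:3], b = ids[3:5]), sample_ids = ids[1:5])
  tab <- composition_table(det, labels)
  expect_equal(unname(rowSums(tab)), c(3L, 3L))
})

test_that("gender variation splits within-cluster pairs correctly", {
  ids <- c("m1", "m2", "f1", "f2")
  labels <- data.frame(sample_id = ids, habitat = "gut",
                       gender = c("male", "male", "female", "female"),
                       stringsAsFactors = FALSE)
  m <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 1
  m["m1", "m2"] <- m["m2", "m1"] <- 0.9
  m["m1", "f1"] <- m["f1", "m1"] <- 0.8

  two_males <- community(list(c1 = c("m1", "m2")), sample_ids = ids,
                         unassigned = c("f1", "f2"))
  gv <- gender_variation(two_males, m, labels)
  expect_equal(gv$same_gender_mean, 0.9)
  expect_true(is.na(gv$opposite_gender_mean))

  mixed_pair <- community(list(c1 = c("m1", "f1")), sample_ids = ids,
                          unassigned = c("m2", "f2"))
  gv2 <- gender_variation(mixed_pair, m, labels)
  expect_true(is.na(gv2$same_gender_mean))
  expect_equal(gv2$opposite_gender_mean, 0.8)

  # 4-sample mixed cluster: hand enumeration of the 6 pairs
  all4 <- community(list(c1 = ids), sample_ids = ids)
  gv3 <- gender_variation(all4, m, labels)
  expect_equal(gv3$same_gender_mean, mean(c(0.9, m["f1", "f2"])))
  expect_equal(gv3$opposite_gender_mean, mean(c(0.8, 0.5, 0.5, 0.5)))
})

test_that("unknown label levels are rejected", {
  bad <- data.frame(sample_id = "s1", habitat = "lung", gender = "male")
  expect_error(meta_labels(bad), "lung")
  bad2 <- data.frame(sample_id = "s1", habitat = "gut", gender = "other")
  expect_error(meta_labels(bad2), "other")
})
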