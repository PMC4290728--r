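# Communities, meta-class reference clusters and the three evaluation
# metrics (f-measure, pair-based PR, F-score), plus habitat/gender
# composition and gender-variation summaries.

HABITATS <- c("gut", "skin", "oral")
GENDERS <- c("male", "female")
# canonical meta-class order: gut/skin/oral for males, then for females
META_CLASSES <- c(t(outer(GENDERS, HABITATS, paste, sep = "_")))

#' Construct a community (a set of possibly-overlapping clusters)
#'
#' @param clusters Named list of character vectors of sample ids; clusters
#'   may overlap.
#' @param unassigned Character vector of samples belonging to no cluster.
#' @param sample_ids Full sample universe; defaults to the union of
#'   clusters and unassigned.
#' @return A `community` object.
#' @export
community <- function(clusters, unassigned = character(),
                      sample_ids = NULL) {
  stopifnot(is.list(clusters))
  clusters <- lapply(clusters, as.character)
  if (is.null(names(clusters)) && length(clusters)) {
    names(clusters) <- paste0("cluster", seq_along(clusters))
  }
  covered <- unique(c(unlist(clusters, use.names = FALSE), unassigned))
  if (is.null(sample_ids)) {
    sample_ids <- covered
  } else if (!setequal(covered, sample_ids)) {
    stop("clusters plus unassigned must cover exactly the sample universe")
  }
  structure(list(clusters = clusters,
                 unassigned = as.character(unassigned),
                 sample_ids = as.character(sample_ids)),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d clusters over %d samples (%d unassigned)\n",
              length(x$clusters), length(x$sample_ids),
              length(x$unassigned)))
  if (length(x$clusters)) {
    cat("  sizes:", paste(lengths(x$clusters), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a hard partition to a community
#'
#' Each non-noise label becomes one cluster; noise samples are unassigned.
#'
#' @param p A [new_partition()] object.
#' @return A [community()].
#' @export
as_community <- function(p) {
  stopifnot(inherits(p, "partition"))
  keep <- p$labels != -1L
  clusters <- split(p$ids[keep], p$labels[keep])
  names(clusters) <- paste0("cluster", names(clusters))
  community(clusters, unassigned = p$ids[!keep], sample_ids = p$ids)
}

#' Validate a meta-label table
#'
#' Meta-labels attach a body habitat (gut, skin, oral) and a host gender
#' (male, female) to every sample; their combination defines one of six
#' meta-classes used as reference clusters.
#'
#' @param labels Data frame with columns `sample_id`, `habitat`, `gender`.
#' @return The validated data frame with an added `meta_class` column
#'   (factor with the six canonical levels, gender before habitat).
#' @export
meta_labels <- function(labels) {
  need <- c("sample_id", "habitat", "gender")
  if (!is.data.frame(labels) || !all(need %in% names(labels))) {
    stop("labels must be a data frame with columns sample_id, habitat, gender")
  }
  if (anyDuplicated(labels$sample_id)) stop("duplicate sample ids in labels")
  bad <- setdiff(unique(labels$habitat), HABITATS)
  if (length(bad)) stop(sprintf("unknown habitat '%s'", bad[1L]))
  bad <- setdiff(unique(labels$gender), GENDERS)
  if (length(bad)) stop(sprintf("unknown gender '%s'", bad[1L]))
  labels$meta_class <- factor(paste(labels$gender, labels$habitat, sep = "_"),
                              levels = META_CLASSES)
  labels
}

#' Reference clusters from meta-labels
#'
#' Groups samples sharing a meta-class (habitat x gender) into one
#' reference cluster; empty meta-classes are dropped.
#'
#' @param labels Meta-label table (see [meta_labels()]).
#' @return A [community()] whose clusters are the populated meta-classes.
#' @export
reference_clusters <- function(labels) {
  labels <- meta_labels(labels)
  cl <- split(as.character(labels$sample_id), labels$meta_class)
  cl <- cl[lengths(cl) > 0L]
  community(cl, sample_ids = as.character(labels$sample_id))
}

# neighbourhood affinity |A n B|^2 / (|A| |B|)
.affinity <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

.check_universe <- function(detected, reference) {
  stopifnot(inherits(detected, "community"), inherits(reference, "community"))
  if (!setequal(detected$sample_ids, reference$sample_ids)) {
    stop("detected and reference communities cover different samples")
  }
}

#' Cluster-level f-measure against reference clusters
#'
#' A detected cluster matches a reference cluster when their neighbourhood
#' affinity `|C_p n C_r|^2 / (|C_p| |C_r|)` reaches `omega`. Precision is
#' the fraction of detected clusters matching some reference cluster,
#' recall the fraction of reference clusters matched by some detected
#' cluster, and f their harmonic mean (0 when both are 0).
#'
#' @param detected,reference [community()] objects over the same samples.
#' @param omega Affinity threshold in `[0, 1]` (default 0.25).
#' @return List with elements `precision`, `recall`, `f`.
#' @export
f_measure <- function(detected, reference, omega = 0.25) {
  .check_universe(detected, reference)
  if (!length(detected$clusters)) stop("detected community has no clusters")
  if (!is.numeric(omega) || omega < 0 || omega > 1) {
    stop("omega must be in [0, 1]")
  }
  dc <- detected$clusters
  rc <- reference$clusters
  aff <- vapply(dc, function(C) {
    vapply(rc, .affinity, numeric(1), a = C)
  }, numeric(length(rc)))
  aff <- matrix(aff, nrow = length(rc))  # rows: reference, cols: detected
  precision <- mean(apply(aff, 2L, max) >= omega)
  recall <- mean(apply(aff, 1L, max) >= omega)
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f = f)
}

# logical co-membership over the upper triangle of the pair matrix;
# under overlap a pair counts once if it shares >= 1 cluster
.pair_comembership <- function(comm, ids) {
  n <- length(ids)
  co <- matrix(FALSE, n, n)
  for (C in comm$clusters) {
    idx <- match(C, ids)
    co[idx, idx] <- TRUE
  }
  co[upper.tri(co)]
}

#' Pair-based PR metric
#'
#' Treats clustering as pairwise co-membership prediction: a sample pair is
#' co-clustered when it shares at least one cluster (each pair counted
#' once, also under overlap). Returns the harmonic mean of pair precision
#' and pair recall of the detected co-memberships against the reference
#' ones; 0 when either side has no co-clustered pairs.
#'
#' @param detected,reference [community()] objects over the same samples.
#' @return A value in `[0, 1]`.
#' @export
pr_metric <- function(detected, reference) {
  .check_universe(detected, reference)
  ids <- detected$sample_ids
  if (length(ids) < 2L) stop("need at least 2 samples")
  dp <- .pair_comembership(detected, ids)
  rp <- .pair_comembership(reference, ids)
  if (!sum(dp) || !sum(rp)) return(0)
  tp <- sum(dp & rp)
  precision <- tp / sum(dp)
  recall <- tp / sum(rp)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Size-weighted best-match F-score
#'
#' For each reference cluster, the F1 of its best-matching detected cluster
#' (precision `|C_p n C_r| / |C_p|`, recall `|C_p n C_r| / |C_r|`); the
#' score is the reference-size-weighted mean, so it measures whether
#' samples of one meta-class end up grouped together.
#'
#' @param detected,reference [community()] objects over the same samples.
#' @return A value in `[0, 1]`.
#' @export
f_score <- function(detected, reference) {
  .check_universe(detected, reference)
  if (!length(detected$clusters)) stop("detected community has no clusters")
  n <- length(reference$sample_ids)
  f1 <- function(C, R) {
    i <- length(intersect(C, R))
    if (i == 0L) return(0)
    p <- i / length(C)
    r <- i / length(R)
    2 * p * r / (p + r)
  }
  total <- 0
  for (R in reference$clusters) {
    best <- max(vapply(detected$clusters, f1, numeric(1), R = R))
    total <- total + length(R) / n * best
  }
  total
}

#' Meta-class composition of detected clusters
#'
#' Contingency counts of cluster membership by meta-class (habitat x
#' gender); overlapping samples are counted in each cluster they belong
#' to, so row sums equal cluster sizes.
#'
#' @param detected A [community()].
#' @param labels Meta-label table covering every clustered sample.
#' @return Integer matrix (clusters x 6 meta-classes) with a `dominant`
#'   attribute naming each cluster's most frequent meta-class.
#' @export
composition_table <- function(detected, labels) {
  stopifnot(inherits(detected, "community"))
  labels <- meta_labels(labels)
  tab <- matrix(0L, length(detected$clusters), length(META_CLASSES),
                dimnames = list(names(detected$clusters), META_CLASSES))
  for (ci in seq_along(detected$clusters)) {
    C <- detected$clusters[[ci]]
    idx <- match(C, labels$sample_id)
    if (anyNA(idx)) {
      stop(sprintf("sample '%s' has no meta-labels", C[which(is.na(idx))[1L]]))
    }
    tab[ci, ] <- as.integer(table(labels$meta_class[idx]))
  }
  attr(tab, "dominant") <- META_CLASSES[max.col(tab, ties.method = "first")]
  tab
}

#' Within-cluster similarity split by gender agreement
#'
#' For each detected cluster, the mean similarity over unordered
#' within-cluster sample pairs with the same host gender and with opposite
#' gender. A side without any pair is reported as `NA` (absent), not 0.
#'
#' @param detected A [community()].
#' @param m Similarity matrix covering the clustered samples.
#' @param labels Meta-label table.
#' @return Data frame with columns `cluster`, `n`, `same_gender_mean`,
#'   `opposite_gender_mean`.
#' @export
gender_variation <- function(detected, m, labels) {
  stopifnot(inherits(detected, "community"))
  assert_similarity(m, require_names = TRUE)
  labels <- meta_labels(labels)
  out <- data.frame(cluster = names(detected$clusters),
                    n = lengths(detected$clusters),
                    same_gender_mean = NA_real_,
                    opposite_gender_mean = NA_real_,
                    row.names = NULL)
  for (ci in seq_along(detected$clusters)) {
    C <- detected$clusters[[ci]]
    if (length(C) < 2L) next
    g <- labels$gender[match(C, labels$sample_id)]
    sub <- m[C, C, drop = FALSE]
    same <- outer(g, g, "==")[upper.tri(sub)]
    vals <- sub[upper.tri(sub)]
    if (any(same)) out$same_gender_mean[ci] <- mean(vals[same])
    if (any(!same)) out$opposite_gender_mean[ci] <- mean(vals[!same])
  }
  out
}

#' Score a detected community against meta-class references
#'
#' Convenience wrapper computing the three metrics and, when a similarity
#' matrix is supplied, the composition and gender-variation summaries.
#'
#' @param detected A [community()].
#' @param labels Meta-label table defining the reference clusters.
#' @param m Optional similarity matrix for [gender_variation()].
#' @param omega Affinity threshold for [f_measure()].
#' @return List with `f_measure` (precision/recall/f), `pr_metric`,
#'   `f_score`, `composite` (mean of f, PR and F-score), `composition`,
#'   and `gender_variation` (when `m` is given).
#' @export
evaluate_communities <- function(detected, labels, m = NULL, omega = 0.25) {
  reference <- reference_clusters(labels)
  fm <- f_measure(detected, reference, omega = omega)
  pr <- pr_metric(detected, reference)
  fs <- f_score(detected, reference)
  out <- list(
    f_measure = fm,
    pr_metric = pr,
    f_score = fs,
    composite = mean(c(fm$f, pr, fs)),
    composition = composition_table(detected, labels))
  if (!is.null(m)) out$gender_variation <- gender_variation(detected, m, labels)
  out
}
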