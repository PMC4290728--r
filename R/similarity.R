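#' Construct an abundance profile
#'
#' An abundance profile holds the relative abundances of one metagenomic
#' sample over the leaf taxa of a shared phylogenetic tree. Profiles must be
#' L1-normalized (abundances sum to 1) before they can be compared; pass
#' `normalize = TRUE` to normalize on construction.
#'
#' @param id Sample identifier (single string).
#' @param abundance Named nonnegative numeric vector; names are leaf taxa.
#' @param normalize If `TRUE`, divide by the total. If `FALSE` (default)
#'   the profile must already sum to 1 within `1e-9`.
#' @return An object of class `abundance_profile`: a list with elements
#'   `id` and `abundance`.
#' @examples
#' p <- abundance_profile("s1", c(t1 = 3, t2 = 1), normalize = TRUE)
#' sum(p$abundance)  # 1
#' @export
abundance_profile <- function(id, abundance, normalize = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.null(names(abundance)) || anyNA(names(abundance)) ||
      any(names(abundance) == "")) {
    stop("abundance vector must be fully named by leaf taxa")
  }
  if (anyDuplicated(names(abundance))) {
    stop("duplicate taxon names in abundance vector")
  }
  abundance <- as.numeric0(abundance)
  if (anyNA(abundance)) stop("abundance contains missing values")
  if (any(abundance < 0)) stop("abundance values must be nonnegative")
  total <- sum(abundance)
  if (normalize) {
    if (total <= 0) stop("cannot normalize an all-zero profile")
    abundance <- abundance / total
  } else if (abs(total - 1) > 1e-9) {
    stop(sprintf(
      "profile '%s' is not normalized (sum = %.6g); pass normalize = TRUE",
      id, total))
  }
  structure(list(id = id, abundance = abundance),
            class = "abundance_profile")
}

# keep names while coercing
as.numeric0 <- function(x) {
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

as_abundance_profile <- function(x, id = "sample") {
  if (inherits(x, "abundance_profile")) return(x)
  abundance_profile(id, x)
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> '%s': %d taxa, total %.6f\n",
              x$id, length(x$abundance), sum(x$abundance)))
  invisible(x)
}

#' Prepare a phylogenetic tree for similarity scoring
#'
#' Validates and, where needed, binarizes a rooted tree. Multifurcations are
#' resolved deterministically with zero-length branches (the scoring
#' recursion assumes two children per internal node); missing branch lengths
#' become 0, so the corresponding edges do not attenuate propagated
#' abundance.
#'
#' @param tree An [ape::phylo] object (e.g. from [ape::read.tree()]).
#' @return A binary `phylo` object with a complete `edge.length` vector.
#' @export
prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) stop("tree leaf names must be unique")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  tree
}

# Postorder index of a prepared tree: edges sorted so that every child is
# visited before its parent, plus per-parent edge groups and the decay scale
# decay^branch.length per edge (0^0 := 1, so zero-length edges never block).
.tree_index <- function(tree, decay) {
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  bl <- po$edge.length
  scale <- ifelse(bl == 0, 1, decay^bl)
  parents <- unique(edge[, 1L])
  list(
    ntip = length(tree$tip.label),
    nnode = length(tree$tip.label) + tree$Nnode,
    tip_label = tree$tip.label,
    child = edge[, 2L],
    parent_of_edge = edge[, 1L],
    parents = parents,
    edges_by_parent = split(seq_len(nrow(edge)),
                            factor(edge[, 1L], levels = parents)),
    scale = scale
  )
}

# map a profile's abundances onto tree leaves (missing taxa -> 0)
.leaf_vector <- function(profile, tip_label) {
  ab <- profile$abundance
  unknown <- setdiff(names(ab), tip_label)
  if (length(unknown)) {
    stop(sprintf("taxon '%s' of sample '%s' is not a leaf of the tree",
                 unknown[1L], profile$id))
  }
  out <- numeric(length(tip_label))
  idx <- match(names(ab), tip_label)
  out[idx] <- ab
  out
}

#' Phylogenetic structure similarity between two samples
#'
#' Scores two normalized abundance profiles on their shared tree by the
#' maximum common component: at every leaf the common abundance is the
#' smaller of the two samples' abundances; unmatched (residual) abundance
#' propagates towards the root, attenuated by `decay^branch.length` per
#' edge, and at each internal node the common abundance is the smaller of
#' the two samples' arriving residuals. The similarity is the total common
#' abundance accumulated over all nodes, a value in `[0, 1]` that equals 1
#' for identical profiles.
#'
#' `decay` tunes how much credit is given to abundance shared only through
#' deeper ancestry: `decay = 0` scores leaf-level overlap only (along
#' nonzero-length edges nothing propagates), while `decay = 1` lets all
#' residual mass reach the root unattenuated, which makes the score
#' degenerate (identically 1 for any two normalized profiles) and is
#' therefore not the default.
#'
#' @param a,b [abundance_profile] objects (or named numeric vectors that sum
#'   to 1) over leaves of `tree`.
#' @param tree A rooted tree ([ape::phylo]); binarized via [prepare_tree()].
#' @param decay Residual propagation factor in `[0, 1]`; per edge the
#'   residual is scaled by `decay^branch.length`. Default `0.5`.
#' @return Similarity in `[0, 1]`, symmetric in `a` and `b`.
#' @examples
#' tr <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
#' a <- abundance_profile("a", c(t1 = 0.5, t2 = 0.5))
#' b <- abundance_profile("b", c(t2 = 0.5, t3 = 0.25, t4 = 0.25))
#' pairwise_similarity(a, b, tr)          # 0.625
#' pairwise_similarity(a, a, tr)          # 1
#' @export
pairwise_similarity <- function(a, b, tree, decay = 0.5) {
  a <- as_abundance_profile(a, "a")
  b <- as_abundance_profile(b, "b")
  .check_decay(decay)
  tree <- prepare_tree(tree)
  ti <- .tree_index(tree, decay)
  va <- .leaf_vector(a, ti$tip_label)
  vb <- .leaf_vector(b, ti$tip_label)
  .similarity_core(va, vb, ti)
}

.check_decay <- function(decay) {
  if (!is.numeric(decay) || length(decay) != 1L || is.na(decay) ||
      decay < 0 || decay > 1) {
    stop("decay must be a single value in [0, 1]")
  }
}

# scalar postorder pass for one pair of leaf-abundance vectors
.similarity_core <- function(va, vb, ti) {
  resA <- numeric(ti$nnode)
  resB <- numeric(ti$nnode)
  cm <- pmin(va, vb)
  sim <- sum(cm)
  resA[seq_len(ti$ntip)] <- va - cm
  resB[seq_len(ti$ntip)] <- vb - cm
  for (pi in seq_along(ti$parents)) {
    p <- ti$parents[pi]
    accA <- 0
    accB <- 0
    for (k in ti$edges_by_parent[[pi]]) {
      ch <- ti$child[k]
      accA <- accA + ti$scale[k] * resA[ch]
      accB <- accB + ti$scale[k] * resB[ch]
    }
    m <- min(accA, accB)
    sim <- sim + m
    resA[p] <- accA - m
    resB[p] <- accB - m
  }
  min(max(sim, 0), 1)
}

#' Pairwise similarity matrix over a set of samples
#'
#' Computes [pairwise_similarity()] for every sample pair and assembles the
#' symmetric similarity matrix (diagonal 1). Rows of the result double as
#' feature vectors for the base clusterers and, later in the workflow, the
#' same matrix container carries the consensus matrix.
#'
#' The computation is row-parallel; results are identical for any `workers`
#' value.
#'
#' @param profiles Either a list of [abundance_profile] objects or a numeric
#'   matrix (samples x taxa, rownames = sample ids, colnames = taxa); matrix
#'   rows must each sum to 1 (use `normalize = TRUE` otherwise).
#' @param tree A rooted tree over the taxa.
#' @param decay Propagation factor, see [pairwise_similarity()].
#' @param workers Number of worker processes (forked; >1 has no effect on
#'   the result, only on wall time).
#' @param normalize L1-normalize matrix rows before scoring.
#' @return An N x N symmetric numeric matrix with sample ids as dimnames,
#'   values in `[0, 1]`, unit diagonal.
#' @export
similarity_matrix <- function(profiles, tree, decay = 0.5, workers = 1L,
                              normalize = FALSE) {
  .check_decay(decay)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("workers must be a positive integer")
  tree <- prepare_tree(tree)
  ti <- .tree_index(tree, decay)

  if (is.matrix(profiles)) {
    A <- profiles
    if (is.null(rownames(A))) stop("abundance matrix must have sample rownames")
    if (normalize) {
      rs <- rowSums(A)
      if (any(rs <= 0)) stop("cannot normalize an all-zero profile row")
      A <- A / rs
    }
    ids <- rownames(A)
    plist <- lapply(seq_len(nrow(A)), function(i) {
      abundance_profile(ids[i], A[i, ])
    })
  } else {
    plist <- lapply(profiles, as_abundance_profile)
    ids <- vapply(plist, function(p) p$id, character(1))
  }
  n <- length(plist)
  if (n < 2L) stop("need at least 2 profiles")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id '%s'", ids[anyDuplicated(ids)]))
  }
  L <- t(vapply(plist, .leaf_vector, numeric(ti$ntip),
                tip_label = ti$tip_label))

  row_fun <- function(i) .similarity_row(L[i, ], L, ti)
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), row_fun, mc.cores = workers)
  } else {
    lapply(seq_len(n), row_fun)
  }
  m <- do.call(rbind, rows)
  m <- (m + t(m)) / 2          # enforce exact symmetry
  diag(m) <- 1
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(ids, ids)
  m
}

# one row against all samples at once: the postorder pass is vectorized
# over the N partner samples (columns), so the inner loop is over tree
# nodes only
.similarity_row <- function(vi, L, ti) {
  n <- nrow(L)
  RA <- matrix(vi, nrow = ti$ntip, ncol = n)
  RB <- t(L)
  cm <- pmin(RA, RB)
  sim <- colSums(cm)
  resA <- matrix(0, ti$nnode, n)
  resB <- matrix(0, ti$nnode, n)
  resA[seq_len(ti$ntip), ] <- RA - cm
  resB[seq_len(ti$ntip), ] <- RB - cm
  for (pi in seq_along(ti$parents)) {
    p <- ti$parents[pi]
    accA <- numeric(n)
    accB <- numeric(n)
    for (k in ti$edges_by_parent[[pi]]) {
      ch <- ti$child[k]
      accA <- accA + ti$scale[k] * resA[ch, ]
      accB <- accB + ti$scale[k] * resB[ch, ]
    }
    m <- pmin(accA, accB)
    sim <- sim + m
    resA[p, ] <- accA - m
    resB[p, ] <- accB - m
  }
  sim
}

#' Sparsify a similarity network by edge thresholding
#'
#' Off-diagonal entries below `t` are set to 0; the diagonal and symmetry
#' are preserved. Used to tune network coverage (the workflow sweeps
#' thresholds around 0.7-0.9).
#'
#' @param m Similarity matrix (symmetric, values in `[0, 1]`).
#' @param t Threshold in `[0, 1]`.
#' @return The thresholded matrix.
#' @export
threshold_network <- function(m, t) {
  assert_similarity(m)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1) {
    stop("threshold t must be a single value in [0, 1]")
  }
  d <- diag(m)
  m[m < t] <- 0
  diag(m) <- d
  m
}

# shared validator for similarity/consensus matrices
assert_similarity <- function(m, tol = 1e-8, require_names = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix")
  if (nrow(m) == 0L) stop("empty similarity matrix")
  if (nrow(m) != ncol(m)) stop("similarity matrix must be square")
  if (anyNA(m)) stop("similarity matrix contains missing values")
  if (max(abs(m - t(m))) > tol) stop("similarity matrix is not symmetric")
  if (min(m) < -tol || max(m) > 1 + tol) {
    stop("similarity values must lie in [0, 1]")
  }
  if (require_names &&
      (is.null(rownames(m)) || anyDuplicated(rownames(m)))) {
    stop("similarity matrix needs unique sample-id dimnames")
  }
  invisible(m)
}
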