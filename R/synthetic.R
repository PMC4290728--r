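# Synthetic fixtures with planted ground truth: block-structured similarity
# matrices and tree-structured abundance profiles with meta-class labels.

#' Apportion a sample total over the six meta-classes
#'
#' Splits `n` samples over the meta-classes proportionally to the empirical
#' human-microbiome distribution of 1920 samples over habitat x gender
#' (gut/skin/oral by male: 331, 698, 366; by female: 130, 262, 133), using
#' largest-remainder rounding so the counts sum exactly to `n`.
#'
#' @param n Total number of samples.
#' @param classes Number of leading meta-classes to use (<= 6).
#' @return Integer vector of length `classes` summing to `n`.
#' @examples
#' meta_class_sizes(120)  # 21 44 23 8 16 8
#' @export
meta_class_sizes <- function(n = 120L, classes = 6L) {
  ref <- c(331, 698, 366, 130, 262, 133)
  classes <- as.integer(classes)
  if (classes < 1L || classes > 6L) stop("classes must be in 1..6")
  w <- ref[seq_len(classes)]
  exact <- n * w / sum(w)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Planted-partition similarity matrix
#'
#' Generates a block-structured similarity matrix: within-block entries are
#' drawn `Normal(mu_in, sigma)`, between-block entries `Normal(mu_out,
#' sigma)`, clipped to `[0, 1]`, symmetrized, with unit diagonal.
#'
#' @param sizes Integer vector of block sizes.
#' @param mu_in,mu_out Within/between-block similarity means (`mu_in >
#'   mu_out`, both in `[0, 1]`).
#' @param sigma Nonnegative noise standard deviation.
#' @param seed Integer seed; the matrix is reproducible from it.
#' @return List with `matrix` (the similarity matrix, sample ids `S001`,
#'   ...) and `truth` (list with `sizes`, per-sample `block`, and the
#'   generator parameters).
#' @export
planted_similarity <- function(sizes, mu_in = 0.9, mu_out = 0.2,
                               sigma = 0.05, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("block sizes must be positive")
  if (!all(c(mu_in, mu_out) >= 0 & c(mu_in, mu_out) <= 1)) {
    stop("mu_in and mu_out must lie in [0, 1]")
  }
  if (mu_in <= mu_out) stop("mu_in must exceed mu_out")
  if (sigma < 0) stop("sigma must be nonnegative")
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n, mu_out, sigma), n, n)
  for (b in seq_along(sizes)) {
    idx <- which(block == b)
    m[idx, idx] <- stats::rnorm(length(idx)^2, mu_in, sigma)
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m <- pmin(pmax(m, 0), 1)
  diag(m) <- 1
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  names(block) <- ids
  list(matrix = m,
       truth = list(sizes = sizes, block = block, mu_in = mu_in,
                    mu_out = mu_out, sigma = sigma, seed = seed))
}

#' Tree-structured abundance profiles with meta-class structure
#'
#' Emulates a habitat/gender-structured metagenomic cohort: a random
#' bifurcating tree with exponential branch lengths; one sparse Dirichlet
#' center per meta-class (concentration `center_alpha` over the leaves, so
#' a few taxa dominate each class, as in real communities); and per sample
#' a Dirichlet draw around its class center with precision `dispersion`.
#' Larger `dispersion` concentrates samples near their center, raising
#' within-class similarity.
#'
#' @param n_leaves Number of leaf taxa.
#' @param classes Number of meta-classes (<= 6).
#' @param sizes Samples per class; defaults to [meta_class_sizes()] of 120.
#' @param dispersion Positive Dirichlet precision of the within-class draw.
#' @param center_alpha Symmetric Dirichlet concentration of the class
#'   centers.
#' @param seed Integer seed.
#' @return List with `tree` ([ape::phylo]), `abundance` (N x n_leaves
#'   matrix, rows normalized), `labels` (meta-label data frame with
#'   sample_id/habitat/gender), and `class` (named integer vector of true
#'   class ids).
#' @export
synth_profiles <- function(n_leaves = 64L, classes = 6L, sizes = NULL,
                           dispersion = 400, center_alpha = 0.1,
                           seed = 1L) {
  classes <- as.integer(classes)
  if (classes < 1L || classes > 6L) stop("classes must be in 1..6")
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be positive")
  }
  if (is.null(sizes)) sizes <- meta_class_sizes(120L, classes)
  sizes <- as.integer(sizes)
  if (length(sizes) != classes || any(sizes < 1L)) {
    stop("sizes must give one positive count per class")
  }
  set.seed(seed)
  tree <- ape::rtree(n_leaves, br = function(n) stats::rexp(n))
  centers <- vapply(seq_len(classes), function(k) {
    c0 <- stats::rgamma(n_leaves, shape = center_alpha)
    c0 / sum(c0)
  }, numeric(n_leaves))

  n <- sum(sizes)
  cls <- rep(seq_len(classes), sizes)
  A <- t(vapply(cls, function(k) {
    x <- stats::rgamma(n_leaves, shape = pmax(centers[, k] * dispersion,
                                              1e-8))
    x / sum(x)
  }, numeric(n_leaves)))
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(A) <- list(ids, tree$tip.label)
  names(cls) <- ids

  mc <- strsplit(META_CLASSES[cls], "_", fixed = TRUE)
  labels <- data.frame(
    sample_id = ids,
    habitat = vapply(mc, `[`, character(1), 2L),
    gender = vapply(mc, `[`, character(1), 1L),
    stringsAsFactors = FALSE)
  list(tree = tree, abundance = A, labels = labels, class = cls)
}
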