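# Independent reference implementations used to cross-check the package.
# They deliberately use different algorithmic styles (explicit recursion,
# triple loops, scalar arithmetic) from the production code.

# --- phylogenetic similarity: explicit recursion over the tree ------------

# adjacency of an ape tree: children and branch lengths per internal node
.oracle_children <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nn)
  bl <- vector("list", nn)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0, nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[k, 2])
    bl[[p]] <- c(bl[[p]], el[k])
  }
  list(children = ch, brlen = bl)
}

# returns list(sim = accumulated common abundance, resA, resB = residuals
# leaving node `node` towards its parent, before edge scaling)
.oracle_walk <- function(node, tree, adj, va, vb, decay) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    cm <- min(va[node], vb[node])
    return(list(sim = cm, resA = va[node] - cm, resB = vb[node] - cm))
  }
  kids <- adj$children[[node]]
  lens <- adj$brlen[[node]]
  accA <- 0; accB <- 0; sim <- 0
  for (i in seq_along(kids)) {
    sub <- .oracle_walk(kids[i], tree, adj, va, vb, decay)
    s <- if (lens[i] == 0) 1 else decay^lens[i]
    accA <- accA + s * sub$resA
    accB <- accB + s * sub$resB
    sim <- sim + sub$sim
  }
  cm <- min(accA, accB)
  list(sim = sim + cm, resA = accA - cm, resB = accB - cm)
}

oracle_similarity <- function(a, b, tree, decay) {
  tip <- tree$tip.label
  va <- vb <- numeric(length(tip))
  va[match(names(a), tip)] <- a
  vb[match(names(b), tip)] <- b
  root <- length(tip) + 1L
  .oracle_walk(root, tree, .oracle_children(tree), va, vb, decay)$sim
}

random_profile <- function(tree, sparsity = 0.5) {
  tip <- tree$tip.label
  x <- stats::rgamma(length(tip), 1) * (stats::runif(length(tip)) < sparsity)
  if (sum(x) == 0) x[sample(length(x), 1)] <- 1
  x <- x / sum(x)
  names(x) <- tip
  x
}

random_tree <- function(n) ape::rtree(n, br = function(k) stats::rexp(k))

# --- consensus: brute-force triple loop -----------------------------------

oracle_consensus <- function(partitions) {
  ids <- partitions[[1]]$ids
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cnt <- 0
      for (p in partitions) {
        li <- p$labels[match(ids[i], p$ids)]
        lj <- p$labels[match(ids[j], p$ids)]
        if (li != -1 && lj != -1 && li == lj) cnt <- cnt + 1
      }
      w[i, j] <- cnt / length(partitions)
    }
  }
  diag(w) <- 1
  w
}

random_ensemble <- function(n, n_part, noise_prob = 0.1) {
  ids <- sprintf("s%02d", seq_len(n))
  lapply(seq_len(n_part), function(p) {
    k <- sample(2:5, 1)
    lab <- sample.int(k, n, replace = TRUE)
    lab[stats::runif(n) < noise_prob] <- -1L
    new_partition(ids, lab, algorithm = "random", seed = p)
  })
}

# --- symmetric NMF: scalar double loops -----------------------------------

oracle_kl_objective <- function(W, H, beta) {
  n <- nrow(W); K <- ncol(H)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- 0
      for (z in seq_len(K)) p <- p + H[i, z] * H[j, z]
      lt <- if (W[i, j] == 0) 0 else W[i, j] * log(max(p, 1e-12))
      total <- total - (lt - p)
    }
  }
  total + beta * sum(H)
}

oracle_update_H <- function(W, H, beta) {
  n <- nrow(W); K <- ncol(H)
  out <- H
  for (i in seq_len(n)) {
    for (z in seq_len(K)) {
      num <- 0
      for (j in seq_len(n)) {
        p <- 0
        for (l in seq_len(K)) p <- p + H[i, l] * H[j, l]
        num <- num + W[i, j] * H[j, z] / max(p, 1e-12)
      }
      den <- max(sum(H[, z]) + 0.5 * beta, 1e-12)
      out[i, z] <- H[i, z] / 2 + 0.5 * H[i, z] * num / den
    }
  }
  out
}

random_W <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  w <- (a + t(a)) / 2
  diag(w) <- 1
  dimnames(w) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  w
}

# --- DBSCAN: breadth-first reference with an explicit visited set ---------

oracle_dbscan <- function(d, eps, min_pts) {
  n <- nrow(d)
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbors, length, integer(1)) >= min_pts
  label <- rep(NA_integer_, n)
  cl <- 0L
  for (start in seq_len(n)) {
    if (!is.na(label[start]) || !is_core[start]) next
    cl <- cl + 1L
    queue <- start
    label[start] <- cl
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nb in neighbors[[cur]]) {
        if (is.na(label[nb])) {
          label[nb] <- cl
          if (is_core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  label[is.na(label)] <- -1L
  label
}

# --- pair-based PR: direct enumeration over all sample pairs --------------

oracle_pr <- function(detected, reference) {
  ids <- detected$sample_ids
  pairs <- utils::combn(ids, 2)
  in_same <- function(comm, a, b) {
    any(vapply(comm$clusters,
               function(C) a %in% C && b %in% C, logical(1)))
  }
  dp <- apply(pairs, 2, function(p) in_same(detected, p[1], p[2]))
  rp <- apply(pairs, 2, function(p) in_same(reference, p[1], p[2]))
  if (!sum(dp) || !sum(rp)) return(0)
  prec <- sum(dp & rp) / sum(dp)
  rec <- sum(dp & rp) / sum(rp)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# --- misc fixtures --------------------------------------------------------

# perfectly separated planted similarity matrix ({0,1} blocks)
block_matrix <- function(sizes) {
  lab <- rep(seq_along(sizes), sizes)
  m <- outer(lab, lab, "==") * 1
  diag(m) <- 1
  ids <- sprintf("S%03d", seq_along(lab))
  dimnames(m) <- list(ids, ids)
  list(matrix = m, block = stats::setNames(lab, ids))
}

# labels over a universe split evenly into the six meta-classes
even_labels <- function(per_class = 2) {
  mc <- metaclust:::META_CLASSES
  n <- 6 * per_class
  parts <- strsplit(rep(mc, each = per_class), "_")
  data.frame(
    sample_id = sprintf("x%02d", seq_len(n)),
    habitat = vapply(parts, `[`, character(1), 2),
    gender = vapply(parts, `[`, character(1), 1),
    stringsAsFactors = FALSE)
}

composite_score <- function(report) report$composite
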