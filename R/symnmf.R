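# Identification phase: symmetric NMF of the consensus matrix under a
# generalized Kullback-Leibler cost with L1 sparsity, solved by damped
# multiplicative updates, followed by membership thresholding.

.EPS <- 1e-12

#' Sparsity-regularized KL objective of a symmetric factorization
#'
#' Evaluates the cost
#' \deqn{-\sum_{ij} [W_{ij} \log (HH^T)_{ij} - (HH^T)_{ij}]
#'       + \beta \sum_{iz} h_{iz},}
#' i.e. the generalized KL divergence between `W` and `H %*% t(H)` with the
#' `W`-only constant dropped, plus an L1 penalty that encourages each sample
#' to belong to few clusters. Logarithm arguments are floored at `1e-12`
#' and `0 * log(.)` is taken as 0.
#'
#' @param W Symmetric nonnegative matrix (consensus or similarity).
#' @param H N x K nonnegative membership matrix.
#' @param beta Nonnegative L1 sparsity weight.
#' @return The scalar objective value.
#' @export
kl_objective <- function(W, H, beta = 1) {
  .check_WH(W, H, beta)
  P <- tcrossprod(H)
  lt <- W * log(pmax(P, .EPS))
  lt[W == 0] <- 0
  -(sum(lt) - sum(P)) + beta * sum(H)
}

.check_WH <- function(W, H, beta) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (!is.matrix(H)) stop("H must be a matrix")
  if (nrow(H) != nrow(W)) stop("W and H dimensions disagree")
  if (anyNA(H) || min(H) < 0) stop("H must be nonnegative and finite")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("beta must be a single nonnegative value")
  }
  invisible(NULL)
}

#' One damped multiplicative update of the membership matrix
#'
#' Applies, elementwise,
#' \deqn{h_{iz} \leftarrow \frac{h_{iz}}{2} + \frac{1}{2}\,
#'   \frac{h_{iz} \sum_j W_{ij} h_{jz} / (HH^T)_{ij}}
#'        {\sum_j h_{jz} + \beta/2},}
#' the multiplicative rule for the [kl_objective()] cost averaged with the
#' current iterate (damping keeps the objective non-increasing for the
#' symmetric factorization). Zero entries stay zero; denominators are
#' floored at `1e-12`, so the update never divides by zero.
#'
#' @inheritParams kl_objective
#' @return The updated nonnegative matrix, same shape as `H`.
#' @export
update_H <- function(W, H, beta = 1) {
  .check_WH(W, H, beta)
  P <- pmax(tcrossprod(H), .EPS)
  num <- (W / P) %*% H
  den <- pmax(colSums(H) + 0.5 * beta, .EPS)
  out <- 0.5 * H + 0.5 * H * sweep(num, 2L, den, "/")
  dimnames(out) <- dimnames(H)
  out
}

#' Factorize a consensus matrix by symmetric KL-NMF
#'
#' Iterates [update_H()] until the L1 change `||H_l - H_{l-1}||_1` drops
#' below `rho` or `max_iter` is reached. To escape poor local minima the
#' algorithm restarts from `restarts` random initializations and keeps the
#' run with the lowest final cost; when an explicit `init` is supplied (the
#' "ensemble-initial" variant, e.g. from [init_from_partition()]) a single
#' run starts there instead.
#'
#' The first restart is deterministic and spectrally informed (an
#' NNDSVD-style start built from the `K` leading eigenpairs of `W`; see
#' Details); the remaining restarts draw entries i.i.d. uniform on
#' `(0, 1]` scaled so `mean(H %*% t(H)) == mean(W)`, putting the start on
#' the data's scale. Everything is reproducible from `seed`.
#'
#' @details
#' Purely random restarts occasionally all land in merged-cluster local
#' minima on strongly block-structured consensus matrices; seeding one
#' restart from the nonnegative parts of the leading scaled eigenvectors
#' (the symmetric analogue of NNDSVD initialization) makes the solver
#' reliable there, while the lowest-cost selection still lets any random
#' restart win when it does better.
#'
#' @param W Symmetric nonnegative matrix (typically from
#'   [build_consensus()]).
#' @param K Number of clusters, `2 <= K <= N`.
#' @param beta L1 sparsity weight (default 1).
#' @param rho Convergence tolerance on the L1 change of `H` (default 1e-6).
#' @param max_iter Iteration cap per restart (default 200).
#' @param restarts Number of random restarts (default 10).
#' @param seed Integer seed.
#' @param init Optional N x K starting matrix; forces a single restart.
#' @return An object of class `symnmf_fit`: `H` (with sample rownames),
#'   `cost_trace` (objective per iteration of the selected run, starting at
#'   the initial cost), `iterations`, `converged`, `restart` (index of the
#'   selected run), `restart_costs`, `K`, `beta`.
#' @export
factorize <- function(W, K, beta = 1, rho = 1e-6, max_iter = 200L,
                      restarts = 10L, seed = 1L, init = NULL) {
  assert_similarity(W, tol = 1e-8)
  n <- nrow(W)
  K <- as.integer(K)
  if (is.na(K) || K < 2L || K > n) {
    stop(sprintf("K = %d out of range [2, %d]", K, n))
  }
  if (rho <= 0) stop("rho must be positive")
  max_iter <- as.integer(max_iter)
  if (!is.null(init)) {
    if (!is.matrix(init) || any(dim(init) != c(n, K)) || min(init) < 0) {
      stop("init must be a nonnegative N x K matrix")
    }
    restarts <- 1L
  }
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("restarts must be >= 1")

  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, restarts)

  best <- NULL
  restart_costs <- numeric(restarts)
  for (r in seq_len(restarts)) {
    H <- if (!is.null(init)) {
      init
    } else if (r == 1L) {
      .init_spectral(W, K)
    } else {
      set.seed(restart_seeds[r])
      H0 <- matrix(stats::runif(n * K, min = .Machine$double.eps, max = 1),
                   n, K)
      mw <- mean(W)
      if (mw > 0) H0 * sqrt(mw / mean(tcrossprod(H0))) else H0 * sqrt(.EPS)
    }
    trace <- kl_objective(W, H, beta)
    converged <- FALSE
    iters <- 0L
    for (l in seq_len(max_iter)) {
      Hn <- update_H(W, H, beta)
      delta <- sum(abs(Hn - H))
      H <- Hn
      iters <- l
      trace <- c(trace, kl_objective(W, H, beta))
      if (delta < rho) {
        converged <- TRUE
        break
      }
    }
    cost <- trace[length(trace)]
    restart_costs[r] <- cost
    if (is.null(best) || cost < best$cost) {
      best <- list(H = H, cost = cost, trace = trace, iterations = iters,
                   converged = converged, restart = r)
    }
  }

  rownames(best$H) <- rownames(W)
  colnames(best$H) <- paste0("cluster", seq_len(K))
  structure(
    list(H = best$H, cost_trace = best$trace, iterations = best$iterations,
         converged = best$converged, restart = best$restart,
         restart_costs = restart_costs, K = K, beta = beta),
    class = "symnmf_fit")
}

#' @export
print.symnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<symnmf_fit> N = %d, K = %d, beta = %g: cost %.6g after %d iterations (%s), restart %d/%d\n",
    nrow(x$H), x$K, x$beta, x$cost_trace[length(x$cost_trace)],
    x$iterations, if (x$converged) "converged" else "iteration cap",
    x$restart, length(x$restart_costs)))
  invisible(x)
}

# NNDSVD-style deterministic start: for each of the K leading eigenpairs
# of W take the dominant nonnegative part of the scaled eigenvector; zeros
# are floored at a small positive value so the multiplicative updates can
# still grow them.
.init_spectral <- function(W, K) {
  e <- eigen(W, symmetric = TRUE)
  n <- nrow(W)
  H <- matrix(0, n, K)
  for (k in seq_len(K)) {
    v <- e$vectors[, k]
    lam <- max(e$values[k], 0)
    vp <- pmax(v, 0)
    vn <- pmax(-v, 0)
    part <- if (sum(vp^2) >= sum(vn^2)) vp else vn
    H[, k] <- sqrt(lam) * part
  }
  f <- 1e-3 * max(H, .EPS)
  H[H < f] <- f
  H
}

#' Membership matrix from a hard partition
#'
#' Builds a starting indicator matrix for the "ensemble-initial" variant of
#' [factorize()]: entry `(i, z)` is 1 when sample `i` belongs to cluster
#' `z` of the partition and a small floor (`1e-3`) otherwise. The floor is
#' required because multiplicative updates lock exact zeros in place; extra
#' columns (when `K` exceeds the partition's cluster count) are all-floor.
#'
#' @param p A [new_partition()]; noise samples get an all-floor row.
#' @param K Number of columns (must be at least the number of clusters).
#' @param floor Value used for non-membership entries.
#' @return An N x K matrix with the partition's sample ids as rownames.
#' @export
init_from_partition <- function(p, K, floor = 1e-3) {
  stopifnot(inherits(p, "partition"))
  K <- as.integer(K)
  cl <- sort(unique(p$labels[p$labels != -1L]))
  if (length(cl) > K) {
    stop(sprintf("partition has %d clusters but K = %d", length(cl), K))
  }
  H <- matrix(floor, length(p$ids), K)
  for (z in seq_along(cl)) {
    H[p$labels == cl[z], z] <- 1
  }
  rownames(H) <- p$ids
  colnames(H) <- paste0("cluster", seq_len(K))
  H
}

#' Threshold soft memberships into (possibly overlapping) clusters
#'
#' A sample joins cluster `z` when its membership weight reaches `tau`; a
#' sample may satisfy this for several clusters (overlap) or for none
#' (unassigned). With `normalize = TRUE` each row is first scaled to unit
#' maximum, making the rule scale-invariant: `tau = 0.5` then reads "at
#' least half as strong as the sample's best cluster". All-zero rows are
#' always unassigned; empty clusters are dropped with a warning.
#'
#' @param H Nonnegative membership matrix (rownames = sample ids), or a
#'   `symnmf_fit`.
#' @param tau Positive membership threshold.
#' @param normalize Scale each row to unit maximum before thresholding.
#' @return A [community()] object.
#' @export
threshold_membership <- function(H, tau = 0.5, normalize = FALSE) {
  if (inherits(H, "symnmf_fit")) H <- H$H
  if (!is.matrix(H) || anyNA(H) || min(H) < 0) {
    stop("H must be a nonnegative matrix")
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("tau must be positive")
  }
  ids <- rownames(H)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(H)))
  Hn <- H
  if (normalize) {
    rmax <- apply(H, 1L, max)
    pos <- rmax > 0
    Hn[pos, ] <- H[pos, , drop = FALSE] / rmax[pos]
  }
  member <- Hn >= tau
  clusters <- lapply(seq_len(ncol(H)), function(z) ids[member[, z]])
  names(clusters) <- colnames(H) %||% paste0("cluster", seq_len(ncol(H)))
  empty <- lengths(clusters) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d empty cluster(s): %s", sum(empty),
                    paste(names(clusters)[empty], collapse = ", ")),
            call. = FALSE)
    clusters <- clusters[!empty]
  }
  unassigned <- ids[rowSums(member) == 0L]
  community(clusters, unassigned = unassigned, sample_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
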