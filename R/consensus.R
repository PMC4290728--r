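#' Build the consensus matrix from a base clustering ensemble
#'
#' Entry `(i, j)` is the number of base clustering results in which samples
#' `i` and `j` were assigned to the same cluster, divided by the total
#' number of base clustering results. Noise samples (`label -1`) co-cluster
#' with nobody in that partition (noise means "unassigned", not a shared
#' cluster). The diagonal is fixed at 1 so the consensus matrix is a valid
#' similarity matrix for the factorization stage.
#'
#' @param partitions List of [new_partition()] objects over the same
#'   samples (at least 2). Partitions whose ids are a reordering of the
#'   first partition's ids are aligned automatically; different id sets are
#'   an error.
#' @return Symmetric N x N matrix in `[0, 1]` with unit diagonal and the
#'   shared sample ids as dimnames.
#' @examples
#' p1 <- new_partition(c("a", "b", "c"), c(1, 1, 2))
#' p2 <- new_partition(c("a", "b", "c"), c(1, 2, 2))
#' build_consensus(list(p1, p2))["a", "b"]  # 0.5
#' @export
build_consensus <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 2L) {
    stop("need at least 2 partitions")
  }
  ids <- partitions[[1L]]$ids
  n <- length(ids)
  w <- matrix(0, n, n)
  for (p in partitions) {
    if (!setequal(p$ids, ids) || length(p$ids) != n) {
      stop("partitions cover different sample sets")
    }
    lab <- p$labels[match(ids, p$ids)]
    assigned <- lab != -1L
    co <- outer(lab, lab, "==") & outer(assigned, assigned, "&")
    w <- w + co
  }
  w <- w / length(partitions)
  diag(w) <- 1
  dimnames(w) <- list(ids, ids)
  w
}
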