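#' Construct a partition (one base clustering result)
#'
#' @param ids Character vector of sample ids.
#' @param labels Integer cluster labels, one per sample; `-1` marks noise
#'   (unassigned) samples.
#' @param algorithm,params,seed Provenance: which algorithm produced the
#'   partition, with what parameters and seed.
#' @return A `partition` object.
#' @export
new_partition <- function(ids, labels, algorithm = "unknown",
                          params = list(), seed = NA_integer_) {
  stopifnot(is.character(ids), length(ids) == length(labels))
  if (anyDuplicated(ids)) stop("duplicate sample ids in partition")
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("partition labels must not be missing")
  structure(
    list(ids = ids, labels = labels,
         algorithm = algorithm, params = params, seed = seed),
    class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(x$labels[x$labels != -1L]))
  cat(sprintf("<partition> %s (%s): %d samples, %d clusters, %d noise\n",
              x$algorithm,
              paste(names(x$params), unlist(x$params),
                    sep = "=", collapse = ", "),
              length(x$ids), k, sum(x$labels == -1L)))
  invisible(x)
}

#' Run a single base clusterer on a similarity network
#'
#' The four families mirror the generation phase of the ensemble workflow:
#' `em` (Gaussian mixture with diagonal covariance, fitted by EM from a
#' seed-dependent start), `kmeans`, `hierarchical` (average linkage) and
#' `density` (DBSCAN-style). Vector-space algorithms (`em`, `kmeans`)
#' consume the rows of the similarity matrix as sample feature vectors;
#' distance-based ones use `1 - m`.
#'
#' @param m Similarity matrix with sample-id dimnames.
#' @param algorithm One of `"em"`, `"kmeans"`, `"hierarchical"`, `"density"`.
#' @param params Named list: `k` (number of clusters) for
#'   `em`/`kmeans`/`hierarchical`; `eps` and `min_pts` for `density`.
#' @param seed Integer seed; the result is deterministic given
#'   `(m, algorithm, params, seed)`.
#' @return A [new_partition()] object; `density` may emit `-1` (noise) for
#'   unreachable samples. An `em` run that collapses to a singular mixture
#'   raises an error (callers such as [generate_ensemble()] log and skip it).
#' @export
run_base_clusterer <- function(m, algorithm, params, seed = 1L) {
  assert_similarity(m, require_names = TRUE)
  algorithm <- match.arg(algorithm, c("em", "kmeans", "hierarchical", "density"))
  n <- nrow(m)
  ids <- rownames(m)

  if (algorithm %in% c("em", "kmeans", "hierarchical")) {
    k <- params$k
    if (is.null(k) || !is.numeric(k) || length(k) != 1L) {
      stop("params$k is required for ", algorithm)
    }
    k <- as.integer(k)
    if (k < 2L || k > n) stop(sprintf("k = %d out of range [2, %d]", k, n))
  }

  labels <- switch(algorithm,
    kmeans = {
      set.seed(seed)
      stats::kmeans(m, centers = params$k, nstart = 10L,
                    iter.max = 100L)$cluster
    },
    em = .em_cluster(m, params$k, seed),
    hierarchical = {
      hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
      stats::cutree(hc, k = params$k)
    },
    density = {
      if (is.null(params$eps) || is.null(params$min_pts)) {
        stop("params$eps and params$min_pts are required for density")
      }
      .dbscan(1 - m, eps = params$eps, min_pts = params$min_pts)
    })

  new_partition(ids, unname(labels), algorithm = algorithm,
                params = params, seed = seed)
}

# EM Gaussian mixture on similarity-row features, diagonal-family
# covariances. The feature dimension equals the sample count, so an
# unconstrained diagonal model (VVI) is near-singular on small or
# thresholded networks; the fit therefore starts from a seed-dependent
# single-start k-means partition, regularizes with mclust's conjugate
# prior, and falls back from VVI to the spherical diagonal model (EII)
# when the unconstrained fit degenerates. A run where both models
# degenerate (NA memberships) errors out.
#
# mclust resolves the prior function ("defaultPrior") and the per-model
# workers ("meVVI", "meEII") by name in the calling environment, hence the
# explicit importFrom below.
#' @importFrom mclust defaultPrior me meVVI meEII unmap priorControl
.em_cluster <- function(m, k, seed) {
  set.seed(seed)
  start <- stats::kmeans(m, centers = k, nstart = 1L, iter.max = 50L)$cluster
  z <- mclust::unmap(start, groups = seq_len(k))
  for (model in c("VVI", "EII")) {
    fit <- tryCatch(
      mclust::me(data = m, modelName = model, z = z,
                 prior = mclust::priorControl()),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$z) && !anyNA(fit$z)) {
      return(max.col(fit$z, ties.method = "first"))
    }
  }
  stop("EM mixture fit degenerated (singular covariance)")
}

# Classic DBSCAN on a precomputed distance matrix. Core points have at
# least min_pts neighbours within eps (self included); clusters grow from
# cores through their eps-neighbourhoods; non-core points reached from a
# core become border members of its cluster; everything else is noise (-1).
.dbscan <- function(d, eps, min_pts) {
  n <- nrow(d)
  within <- d <= eps
  core <- rowSums(within) >= min_pts
  labels <- rep.int(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      p <- frontier[1L]
      frontier <- frontier[-1L]
      for (q in which(within[p, ])) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) frontier <- c(frontier, q)
        }
      }
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

#' Ensemble configuration for the generation phase
#'
#' Expands an algorithm/parameter/seed grid into the explicit list of base
#' clustering runs. The default grid runs `em` and `kmeans` at
#' `k = 6, ..., 10` with 3 seeds each, hierarchical average linkage at the
#' same `k`, and density-based clustering at `eps = 0.1, 0.2, 0.3` with
#' `min_pts = 4`.
#'
#' @param k Integer vector of cluster numbers for em/kmeans/hierarchical.
#' @param n_seeds Seeds per (algorithm, k) cell for the stochastic
#'   algorithms (em, kmeans).
#' @param eps Numeric vector of density reachability radii.
#' @param min_pts Core-point neighbourhood size for density clustering.
#' @param algorithms Subset of the four base families to include.
#' @param seed Master seed from which per-run seeds are derived.
#' @return An `ensemble_config`: a list of run specifications, each with
#'   `algorithm`, `params`, `seed`.
#' @export
ensemble_config <- function(k = 6:10, n_seeds = 3L,
                            eps = c(0.1, 0.2, 0.3), min_pts = 4L,
                            algorithms = c("em", "kmeans", "hierarchical",
                                           "density"),
                            seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE,
                          choices = c("em", "kmeans", "hierarchical",
                                      "density"))
  if (length(k) == 0L && any(algorithms != "density")) {
    stop("empty parameter grid: no k values")
  }
  set.seed(seed)
  runs <- list()
  add <- function(algorithm, params, run_seed) {
    runs[[length(runs) + 1L]] <<- list(algorithm = algorithm,
                                       params = params, seed = run_seed)
  }
  for (alg in intersect(c("em", "kmeans"), algorithms)) {
    for (kk in k) {
      for (s in seq_len(n_seeds)) {
        add(alg, list(k = as.integer(kk)),
            sample.int(.Machine$integer.max, 1L))
      }
    }
  }
  if ("hierarchical" %in% algorithms) {
    for (kk in k) add("hierarchical", list(k = as.integer(kk)), 0L)
  }
  if ("density" %in% algorithms) {
    for (e in eps) add("density", list(eps = e, min_pts = as.integer(min_pts)),
                       0L)
  }
  if (length(runs) < 2L) stop("ensemble configuration yields fewer than 2 runs")
  structure(runs, class = "ensemble_config")
}

#' Generate the base clustering ensemble
#'
#' Runs every base clusterer in the configuration on the similarity
#' network. Individual failures (e.g. a degenerate EM fit) are reported as
#' warnings and skipped; fewer than 2 surviving results is an error.
#'
#' @param m Similarity matrix with sample-id dimnames.
#' @param cfg An [ensemble_config()] (or any list of run specifications).
#' @param verbose Emit a message per completed run.
#' @return List of [new_partition()] objects, in configuration order.
#' @export
generate_ensemble <- function(m, cfg, verbose = FALSE) {
  assert_similarity(m, require_names = TRUE)
  if (!length(cfg)) stop("empty ensemble configuration")
  partitions <- list()
  for (run in cfg) {
    p <- tryCatch(
      run_base_clusterer(m, run$algorithm, run$params, run$seed),
      error = function(e) {
        warning(sprintf("base run %s(%s) failed and was skipped: %s",
                        run$algorithm,
                        paste(names(run$params), unlist(run$params),
                              sep = "=", collapse = ","),
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(p)) {
      partitions[[length(partitions) + 1L]] <- p
      if (verbose) {
        message(sprintf("  %s(%s) -> %d clusters", run$algorithm,
                        paste(names(run$params), unlist(run$params),
                              sep = "=", collapse = ","),
                        length(unique(p$labels[p$labels != -1L]))))
      }
    }
  }
  if (length(partitions) < 2L) {
    stop("fewer than 2 base clustering results survived")
  }
  partitions
}
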