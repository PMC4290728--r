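#' Configure the full clustering pipeline
#'
#' Collects every tunable of the workflow in one validated object so each
#' run is auditable. Supply either `abundance` + `tree` (profiles are
#' scored on the tree) or a precomputed `similarity`; `labels` enables the
#' evaluation stage. Inputs may be in-memory objects or file paths in the
#' package's TSV/Newick formats.
#'
#' @param abundance Abundance matrix (samples x taxa) or TSV path.
#' @param tree [ape::phylo] or Newick path (required with `abundance`).
#' @param similarity Similarity matrix or TSV path (alternative input).
#' @param labels Meta-label data frame or TSV path (optional).
#' @param decay Similarity propagation factor, see [pairwise_similarity()].
#' @param edge_threshold Network sparsification threshold, see
#'   [threshold_network()].
#' @param ensemble An [ensemble_config()]; defaults to the standard grid
#'   seeded from `seed`.
#' @param K Number of consensus clusters (default 6, one per meta-class).
#' @param beta L1 sparsity weight of the factorization.
#' @param tau Membership threshold (applied to row-max-normalized `H`).
#' @param rho,max_iter,restarts Factorization stopping controls.
#' @param workers Similarity computation workers.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory where every intermediate is written.
#' @param verbose Log each stage with parameters and timing.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(abundance = NULL, tree = NULL,
                            similarity = NULL, labels = NULL,
                            decay = 0.5, edge_threshold = 0.7,
                            ensemble = NULL, K = 6L, beta = 1,
                            tau = 0.5, rho = 1e-6, max_iter = 200L,
                            restarts = 10L, workers = 1L, seed = 1L,
                            out_dir = NULL, verbose = TRUE) {
  if (is.null(similarity) && (is.null(abundance) || is.null(tree))) {
    stop("supply either a similarity matrix or abundance + tree")
  }
  .check_decay(decay)
  if (edge_threshold < 0 || edge_threshold > 1) {
    stop("edge_threshold must lie in [0, 1]")
  }
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be at least 2")
  if (beta < 0) stop("beta must be nonnegative")
  if (tau <= 0) stop("tau must be positive")
  if (rho <= 0) stop("rho must be positive")
  seed <- as.integer(seed)
  if (is.null(ensemble)) ensemble <- ensemble_config(seed = seed)
  structure(
    list(abundance = abundance, tree = tree, similarity = similarity,
         labels = labels, decay = decay, edge_threshold = edge_threshold,
         ensemble = ensemble, K = K, beta = beta, tau = tau, rho = rho,
         max_iter = as.integer(max_iter), restarts = as.integer(restarts),
         workers = as.integer(workers), seed = seed, out_dir = out_dir,
         verbose = isTRUE(verbose)),
    class = "pipeline_config")
}

.stage <- function(name, cfg, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  if (cfg$verbose) {
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full ensemble clustering pipeline
#'
#' Chains all stages: similarity (when profiles are given), network
#' thresholding, base clustering ensemble, consensus matrix, symmetric
#' KL-NMF, membership thresholding, and (when labels are given) evaluation
#' against the meta-class reference clusters. When `cfg$out_dir` is set,
#' every intermediate is written in the package's text formats.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `similarity`, `network`, `ensemble`, `consensus`,
#'   `fit` (the `symnmf_fit`), `community`, and `report` (evaluation
#'   results, `NULL` without labels).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  labels <- cfg$labels
  if (is.character(labels)) labels <- read_labels(labels)
  if (!is.null(labels)) labels <- meta_labels(labels)

  m <- .stage("similarity", cfg, {
    if (!is.null(cfg$similarity)) {
      if (is.character(cfg$similarity)) {
        read_similarity(cfg$similarity)
      } else {
        assert_similarity(cfg$similarity, require_names = TRUE)
        cfg$similarity
      }
    } else {
      ab <- if (is.character(cfg$abundance)) {
        read_abundance(cfg$abundance)
      } else {
        cfg$abundance
      }
      tr <- if (is.character(cfg$tree)) ape::read.tree(cfg$tree) else cfg$tree
      similarity_matrix(ab, tr, decay = cfg$decay, workers = cfg$workers)
    }
  })
  if (!is.null(labels) && !setequal(rownames(m), labels$sample_id)) {
    stop("pipeline stage 'similarity' failed: meta-labels do not cover the samples")
  }

  net <- .stage("threshold", cfg, threshold_network(m, cfg$edge_threshold))
  ens <- .stage("ensemble", cfg,
                generate_ensemble(net, cfg$ensemble, verbose = cfg$verbose))
  W <- .stage("consensus", cfg, build_consensus(ens))
  fit <- .stage("factorize", cfg, {
    set.seed(cfg$seed)
    nmf_seed <- sample.int(.Machine$integer.max, 1L)
    factorize(W, K = cfg$K, beta = cfg$beta, rho = cfg$rho,
              max_iter = cfg$max_iter, restarts = cfg$restarts,
              seed = nmf_seed)
  })
  if (cfg$verbose) {
    message(sprintf("  restart costs: %s",
                    paste(sprintf("%.4g", fit$restart_costs),
                          collapse = ", ")))
  }
  comm <- .stage("membership", cfg,
                 threshold_membership(fit, tau = cfg$tau, normalize = TRUE))

  report <- NULL
  if (!is.null(labels)) {
    report <- .stage("evaluate", cfg,
                     evaluate_communities(comm, labels, m = m))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_similarity(m, file.path(cfg$out_dir, "similarity.tsv"))
    write_similarity(net, file.path(cfg$out_dir, "network.tsv"))
    write_ensemble(ens, file.path(cfg$out_dir, "base"))
    write_similarity(W, file.path(cfg$out_dir, "consensus.tsv"))
    utils::write.table(
      data.frame(sample_id = rownames(fit$H), fit$H, check.names = FALSE),
      file.path(cfg$out_dir, "H.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_community(comm, file.path(cfg$out_dir, "clusters.tsv"))
    if (!is.null(report)) {
      rep_json <- report
      rep_json$composition <- as.data.frame(as.table(report$composition))
      names(rep_json$composition) <- c("cluster", "meta_class", "count")
      jsonlite::write_json(rep_json, file.path(cfg$out_dir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }

  list(similarity = m, network = net, ensemble = ens, consensus = W,
       fit = fit, community = comm, report = report)
}
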