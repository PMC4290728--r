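# Readers and writers for the plain-text formats the pipeline consumes:
# square similarity TSV, abundance TSV, Newick trees, meta-label TSV,
# partition TSV and community TSV. Every writer's output is re-readable by
# the matching reader.

#' Read / write a similarity (or consensus) matrix
#'
#' The on-disk format is a TSV with a header row and an index column of
#' sample ids holding the full square matrix. Reading validates squareness,
#' symmetry (within `1e-8`), the `[0, 1]` range, and rejects missing cells
#' with row/column context.
#'
#' @param path File path.
#' @return `read_similarity()` returns the validated numeric matrix.
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in '%s' is not square (%d x %d)", path,
                 nrow(m), ncol(m)))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column sample ids disagree")
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  assert_similarity(m, tol = 1e-8, require_names = TRUE)
  m
}

#' @param m Similarity matrix with sample-id dimnames.
#' @rdname read_similarity
#' @export
write_similarity <- function(m, path) {
  assert_similarity(m, require_names = TRUE)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table
#'
#' Rows are samples, columns taxa (header row of taxon names matching the
#' tree leaves). Rows are L1-normalized on load unless `normalize = FALSE`.
#'
#' @param path File path.
#' @param normalize Normalize each row to sum 1.
#' @return Numeric matrix, samples x taxa.
#' @export
read_abundance <- function(path, normalize = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (anyNA(m) || any(m < 0)) {
    stop("abundance table must be nonnegative with no missing values")
  }
  if (normalize) {
    rs <- rowSums(m)
    if (any(rs <= 0)) {
      stop(sprintf("sample '%s' has zero total abundance",
                   rownames(m)[which(rs <= 0)[1L]]))
    }
    m <- m / rs
  }
  m
}

#' @param m Abundance matrix (samples x taxa).
#' @rdname read_abundance
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample meta-labels
#'
#' TSV with columns `sample_id`, `habitat` (gut/skin/oral) and `gender`
#' (male/female); unknown levels and duplicate ids are rejected.
#'
#' @param path File path.
#' @return Validated meta-label data frame (see [meta_labels()]).
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta_labels(df)
}

#' @param labels Meta-label data frame.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[c("sample_id", "habitat", "gender")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a partition
#'
#' TSV `sample_id <TAB> cluster_id` with `-1` marking noise samples.
#'
#' @param path File path.
#' @param algorithm,params,seed Provenance attached on read.
#' @return `read_partition()` returns a [new_partition()].
#' @export
read_partition <- function(path, algorithm = "file", params = list(),
                           seed = NA_integer_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cluster_id") %in% names(df))) {
    stop("partition file needs columns sample_id and cluster_id")
  }
  new_partition(as.character(df$sample_id), df$cluster_id,
                algorithm = algorithm, params = params, seed = seed)
}

#' @param p A [new_partition()].
#' @rdname read_partition
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  utils::write.table(
    data.frame(sample_id = p$ids, cluster_id = p$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble to a directory
#'
#' One `partition_XXX.tsv` per base result plus a `manifest.json` of
#' provenance records (algorithm, parameters, seed, file).
#'
#' @param partitions List of [new_partition()] objects.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ensemble <- function(partitions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", length(partitions))
  for (i in seq_along(partitions)) {
    f <- sprintf("partition_%03d.tsv", i)
    write_partition(partitions[[i]], file.path(dir, f))
    manifest[[i]] <- list(file = f,
                          algorithm = partitions[[i]]$algorithm,
                          params = partitions[[i]]$params,
                          seed = partitions[[i]]$seed)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @param dir Ensemble directory written by [write_ensemble()].
#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  lapply(manifest, function(rec) {
    read_partition(file.path(dir, rec$file),
                   algorithm = rec$algorithm,
                   params = rec$params,
                   seed = rec$seed %||% NA_integer_)
  })
}

#' Read / write a community
#'
#' TSV `sample_id <TAB> cluster_id`; a sample belonging to several clusters
#' appears on several rows, unassigned samples once with cluster `-1`.
#'
#' @param path File path.
#' @return `read_community()` returns a [community()].
#' @export
read_community <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cluster_id") %in% names(df))) {
    stop("community file needs columns sample_id and cluster_id")
  }
  keep <- df$cluster_id != -1
  clusters <- split(as.character(df$sample_id[keep]), df$cluster_id[keep])
  names(clusters) <- paste0("cluster", names(clusters))
  community(clusters,
            unassigned = as.character(df$sample_id[!keep]),
            sample_ids = unique(as.character(df$sample_id)))
}

#' @param comm A [community()].
#' @rdname read_community
#' @export
write_community <- function(comm, path) {
  stopifnot(inherits(comm, "community"))
  rows <- data.frame(sample_id = character(), cluster_id = integer())
  for (z in seq_along(comm$clusters)) {
    C <- comm$clusters[[z]]
    if (length(C)) {
      rows <- rbind(rows, data.frame(sample_id = C, cluster_id = z))
    }
  }
  if (length(comm$unassigned)) {
    rows <- rbind(rows, data.frame(sample_id = comm$unassigned,
                                   cluster_id = -1L))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
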