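# Scaffold-aware train/test splitting: Butina sphere-exclusion clustering
# on Tanimoto distance over 2048-bit radius-2 Morgan fingerprints, plus the
# nearest-neighbour similarity diagnostic used to stratify held-out
# performance by structural novelty.

#' Pairwise Tanimoto similarity between fingerprint matrices
#'
#' @param fp_a n_a x bits 0/1 matrix
#' @param fp_b n_b x bits 0/1 matrix (defaults to fp_a)
#' @return n_a x n_b similarity matrix; two all-zero fingerprints have
#'   similarity 0
#' @export
tanimoto_matrix <- function(fp_a, fp_b = fp_a) {
  fp_a <- as.matrix(fp_a); fp_b <- as.matrix(fp_b)
  stopifnot(ncol(fp_a) == ncol(fp_b))
  common <- fp_a %*% t(fp_b)
  ra <- rowSums(fp_a); rb <- rowSums(fp_b)
  denom <- outer(ra, rb, "+") - common
  sim <- ifelse(denom > 0, common / denom, 0)
  sim
}

#' Butina sphere-exclusion clustering
#'
#' Classic Butina clustering on Tanimoto distance (1 - similarity):
#' candidate centroids are ordered by their number of neighbours within the
#' distance cutoff (ties broken by lower input index); each centroid
#' greedily claims all still-unassigned compounds within the cutoff.
#'
#' Note the cutoff is a Tanimoto \emph{distance} threshold (the convention
#' of the reference scaffold splitter), not a similarity: cutoff 0.70
#' merges compounds whose similarity is at least 0.30.
#'
#' @param fp n x bits 0/1 fingerprint matrix
#' @param cutoff Tanimoto distance cutoff in (0,1)
#' @return integer cluster assignment per compound (1-based, clusters
#'   numbered in formation order)
#' @export
butina_cluster <- function(fp, cutoff = 0.70) {
  n <- nrow(fp)
  stopifnot(n >= 1, cutoff > 0, cutoff < 1)
  sim <- tanimoto_matrix(fp)
  within <- (1 - sim) <= cutoff
  diag(within) <- TRUE
  n_nbrs <- rowSums(within)
  ord <- order(-n_nbrs, seq_len(n)) # ties -> lower input index first
  assign <- rep(NA_integer_, n)
  cl <- 0L
  for (i in ord) {
    if (!is.na(assign[i])) next
    cl <- cl + 1L
    members <- which(within[i, ] & is.na(assign))
    assign[members] <- cl
  }
  assign
}

#' Assign whole Butina clusters to train/test
#'
#' Whole clusters are assigned to the training side largest-first (ties by
#' lower cluster id) until the training side reaches (1 - test_fraction) of
#' the compounds; remaining clusters form the test side. Deterministic.
#'
#' @param cluster_assignments integer vector from [butina_cluster()]
#' @param test_fraction target test proportion in (0,1)
#' @param keys optional key14 identifiers aligned with the assignments
#' @return object of class SplitResult: list(train_idx, test_idx,
#'   train_keys, test_keys, cluster_assignments, test_fraction)
#' @export
cluster_split <- function(cluster_assignments, test_fraction = 0.2,
                          keys = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(cluster_assignments)
  sizes <- table(cluster_assignments)
  if (length(sizes) == 1L) {
    stop("all compounds fall into one cluster; use a smaller cutoff")
  }
  ids <- as.integer(names(sizes))
  ord <- ids[order(-as.integer(sizes), ids)]
  target <- (1 - test_fraction) * n
  train_clusters <- integer(0)
  total <- 0
  for (cid in ord) {
    size <- as.integer(sizes[as.character(cid)])
    if (total + size <= target) {
      train_clusters <- c(train_clusters, cid)
      total <- total + size
    }
  }
  train_idx <- which(cluster_assignments %in% train_clusters)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(
    list(train_idx = train_idx, test_idx = test_idx,
         train_keys = if (!is.null(keys)) keys[train_idx],
         test_keys = if (!is.null(keys)) keys[test_idx],
         cluster_assignments = cluster_assignments,
         test_fraction = test_fraction),
    class = "SplitResult"
  )
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("<SplitResult> %d train / %d test (%d clusters)\n",
              length(x$train_idx), length(x$test_idx),
              length(unique(x$cluster_assignments))))
  invisible(x)
}

#' Mean of the k highest Tanimoto similarities to the training set
#'
#' The structural-novelty diagnostic for a held-out compound: its mean
#' similarity to its k nearest training neighbours.
#'
#' @param fp_test n_test x bits fingerprint matrix
#' @param fp_train n_train x bits fingerprint matrix (non-empty)
#' @param k number of nearest neighbours (default 3); if k exceeds the
#'   training size, all training compounds are used with a warning
#' @return numeric vector of length n_test, values in [0,1]
#' @export
nn_similarity_to_train <- function(fp_test, fp_train, k = 3L) {
  if (nrow(fp_train) == 0) stop("training set is empty")
  if (k > nrow(fp_train)) {
    warning("k exceeds training size; using all ", nrow(fp_train),
            " training compounds")
    k <- nrow(fp_train)
  }
  sim <- tanimoto_matrix(fp_test, fp_train)
  apply(sim, 1, function(s) mean(sort(s, decreasing = TRUE)[seq_len(k)]))
}

#' Persist a SplitResult as JSON
#' @param split SplitResult
#' @param path output path
#' @param cutoff the Butina distance cutoff used (recorded)
#' @export
write_split <- function(split, path, cutoff = NA_real_) {
  jsonlite::write_json(
    list(cutoff = cutoff, test_fraction = split$test_fraction,
         cluster_assignments = split$cluster_assignments,
         train_idx = split$train_idx, test_idx = split$test_idx,
         train_keys = split$train_keys, test_keys = split$test_keys),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
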