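# Hierarchical clustering of actives with automatic level selection by the
# Kelley penalty, followed by pooling of tiny clusters into a special class
# and recursive splitting of oversized ones.

#' Agglomerative clustering of a distance matrix
#'
#' Thin validated wrapper around [stats::hclust()].
#'
#' @param d square symmetric distance matrix with zero diagonal and
#'   compound ids as dimnames.
#' @param linkage agglomeration method (default `average`; any
#'   [stats::hclust()] method is accepted).
#' @return an `hclust` tree.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  check_distance_matrix(d)
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Select the number of clusters by the Kelley penalty
#'
#' For every cut level with `k` clusters the average spread is the mean,
#' over clusters with at least two members, of their mean pairwise
#' distance. Spreads are min-max normalized onto \[1, N-1\] across levels
#' and penalized by the cluster count: `penalty(k) = normalized_spread(k) +
#' k`. The `k` minimizing the penalty is returned, ties going to the
#' smaller `k`. When every level has the same spread (e.g. all-equal
#' distances) the criterion is uninformative and 1 is returned with a
#' warning.
#'
#' @param hc an `hclust` tree over the items of `d`.
#' @param d the distance matrix the tree was built from.
#' @return integer number of clusters.
#' @export
kelley_level <- function(hc, d) {
  n <- nrow(d)
  if (n < 3L) stopf("Kelley level selection needs at least 3 items")
  ks <- seq_len(n - 1L)
  spread <- vapply(ks, function(k) {
    memb <- stats::cutree(hc, k = k)
    sizes <- table(memb)
    multi <- as.integer(names(sizes)[sizes >= 2L])
    mean(vapply(multi, function(cl) {
      idx <- which(memb == cl)
      mean(d[idx, idx][upper.tri(diag(length(idx)))])
    }, numeric(1L)))
  }, numeric(1L))
  rng <- range(spread)
  if (diff(rng) < 1e-12) {
    warnf("all cut levels have equal spread; Kelley criterion is uninformative")
    return(1L)
  }
  norm <- 1 + (n - 2) * (spread - rng[1L]) / diff(rng)
  penalty <- norm + ks
  ks[which.min(penalty)]
}

new_clustering <- function(method, clusters, special_class = character(0L),
                           parameters = list()) {
  if (is.null(names(clusters)) || any(names(clusters) == "")) {
    names(clusters) <- sprintf("cluster_%02d", seq_along(clusters))
  }
  all_ids <- c(unlist(clusters, use.names = FALSE), special_class)
  if (anyDuplicated(all_ids)) stopf("cluster assignment duplicates compounds")
  structure(list(method = method, clusters = clusters,
                 special_class = special_class, parameters = parameters),
            class = "pharm_clustering")
}

#' @export
print.pharm_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<%s clustering: %d clusters (%s members)%s>\n",
              x$method, length(x$clusters),
              if (length(sizes)) paste(range(sizes), collapse = "-") else "0",
              if (length(x$special_class))
                sprintf(", special class of %d", length(x$special_class))
              else ""))
  invisible(x)
}

#' Pool tiny clusters and split oversized ones
#'
#' Clusters with fewer than `min_size` members (singletons and doubletons
#' by default) are merged into a special class that takes no part in model
#' building. Clusters exceeding `max_size` are re-clustered recursively
#' with the same linkage/Kelley machinery, at most `max_splits` times.
#'
#' @param clusters named list of compound-id vectors partitioning the input.
#' @param d distance matrix over all ids (used for re-clustering).
#' @param min_size minimum retained cluster size (default 3).
#' @param max_size clusters above this size are split; `NULL` disables
#'   splitting.
#' @param max_splits recursion depth for splitting (default 4).
#' @param linkage linkage for re-clustering.
#' @param method label recorded on the result.
#' @return a `pharm_clustering`.
#' @export
postprocess_clusters <- function(clusters, d, min_size = 3L, max_size = NULL,
                                 max_splits = 4L, linkage = "average",
                                 method = "unknown") {
  split_one <- function(ids, depth) {
    if (is.null(max_size) || length(ids) <= max_size || depth >= max_splits) {
      return(list(ids))
    }
    sub <- d[ids, ids, drop = FALSE]
    hc <- hierarchical_cluster(sub, linkage)
    k <- suppressWarnings(kelley_level(hc, sub))
    if (k <= 1L) k <- 2L  # an oversized cluster must be split somehow
    memb <- stats::cutree(hc, k = k)
    unlist(lapply(split(ids, memb), split_one, depth = depth + 1L),
           recursive = FALSE)
  }
  out <- unlist(lapply(clusters, split_one, depth = 0L), recursive = FALSE)
  small <- lengths(out) < min_size
  special <- unlist(out[small], use.names = FALSE) %||% character(0L)
  kept <- out[!small]
  names(kept) <- sprintf("cluster_%02d", seq_along(kept))
  new_clustering(method, kept, special_class = as.character(special),
                 parameters = list(min_size = min_size, max_size = max_size,
                                   max_splits = max_splits, linkage = linkage))
}

#' Cluster compounds from fingerprints
#'
#' Computes Soergel distances, builds an average-linkage tree, cuts it at
#' the Kelley level and post-processes the clusters (see
#' [postprocess_clusters()]). The default `max_size` is 20% of the input
#' set, so a single dominating cluster is split up.
#'
#' @param fps named list of fingerprints (one per compound, single kind).
#' @param method label for the clustering (`m2d`, `p3d`, ...); defaults to
#'   the fingerprint kind.
#' @param min_size,max_size,max_splits,linkage see [postprocess_clusters()].
#' @return a `pharm_clustering`.
#' @export
cluster_compounds <- function(fps, method = NULL, min_size = 3L,
                              max_size = NULL, max_splits = 4L,
                              linkage = "average") {
  if (length(fps) < 3L) stopf("need at least 3 compounds to cluster")
  method <- method %||% tolower(fps[[1L]]$kind)
  d <- soergel_matrix(fps)
  if (is.null(max_size)) max_size <- ceiling(0.2 * length(fps))
  hc <- hierarchical_cluster(d, linkage)
  k <- kelley_level(hc, d)
  memb <- stats::cutree(hc, k = k)
  clusters <- split(rownames(d), memb)
  postprocess_clusters(clusters, d, min_size = min_size, max_size = max_size,
                       max_splits = max_splits, linkage = linkage,
                       method = method)
}

#' Build a clustering from user-supplied assignments
#'
#' Stands in for a manual (chemotype) classification: the caller supplies
#' the compound-to-cluster map and no automatic post-processing is applied
#' beyond pooling clusters below `min_size`.
#'
#' @param assignments data frame with columns `compound_id` and
#'   `cluster_name`.
#' @param min_size clusters below this size go to the special class.
#' @return a `pharm_clustering` with method `manual`.
#' @export
manual_clustering <- function(assignments, min_size = 1L) {
  required <- c("compound_id", "cluster_name")
  if (!all(required %in% names(assignments))) {
    stopf("assignments need columns %s", paste(required, collapse = ", "))
  }
  clusters <- split(as.character(assignments$compound_id),
                    as.character(assignments$cluster_name))
  small <- lengths(clusters) < min_size
  new_clustering("manual", clusters[!small],
                 special_class = unlist(clusters[small], use.names = FALSE) %||%
                   character(0L),
                 parameters = list(min_size = min_size))
}

#' All compound ids covered by a clustering
#' @param clustering a `pharm_clustering`.
#' @param include_special include the special class (default `TRUE`).
#' @return character vector of ids.
#' @export
clustering_ids <- function(clustering, include_special = TRUE) {
  ids <- unlist(clustering$clusters, use.names = FALSE)
  if (include_special) ids <- c(ids, clustering$special_class)
  as.character(ids)
}
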