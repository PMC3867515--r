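# Serialization: hypotheses and clusterings as JSON, hit matrices as CSV.

#' @rdname hypothesis_io
#' @export
hypothesis_to_list <- function(h) {
  list(hyp_id = h$hyp_id, feature_types = h$ftypes,
       coords = unname(apply(h$coords, 1L, as.numeric, simplify = FALSE)),
       dist = unname(apply(h$dist, 1L, as.numeric, simplify = FALSE)),
       tolerance_rmsd = h$tolerance_rmsd,
       source_cluster = h$source_cluster,
       match_rate = h$match_rate, selectivity = h$selectivity)
}

#' @rdname hypothesis_io
#' @export
hypothesis_from_list <- function(x) {
  coords <- if (is.matrix(x$coords)) x$coords
            else do.call(rbind, lapply(x$coords, unlist))
  new_hypothesis(x$hyp_id, unlist(x$feature_types), coords,
                 tolerance_rmsd = x$tolerance_rmsd %||% 2,
                 source_cluster = x$source_cluster %||% NA_character_,
                 match_rate = x$match_rate %||% NA_real_,
                 selectivity = x$selectivity %||% NA_real_)
}

#' Hypothesis serialization
#'
#' Hypotheses are stored as JSON carrying the feature types, the reference
#' coordinates, the derived inter-feature distance matrix (Angstroms), the
#' RMSD tolerance, the provenance cluster and the quality scores.
#'
#' @param hypotheses named list of `pharm_hypothesis`.
#' @param path JSON file path.
#' @param h,x a single hypothesis / its list form.
#' @return `read_hypotheses_json()` returns a named list of
#'   `pharm_hypothesis`.
#' @name hypothesis_io
#' @export
write_hypotheses_json <- function(hypotheses, path) {
  jsonlite::write_json(lapply(hypotheses, hypothesis_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname hypothesis_io
#' @export
read_hypotheses_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  out <- lapply(raw, hypothesis_from_list)
  if (is.null(names(out)) || any(names(out) == "")) {
    names(out) <- vapply(out, `[[`, character(1L), "hyp_id")
  }
  out
}

#' Hit-matrix CSV round trip
#'
#' Compound rows, hypothesis columns, 0/1 entries.
#'
#' @param hm a `hit_matrix`.
#' @param path CSV file path.
#' @return `read_hit_matrix()` returns a `hit_matrix`.
#' @name hit_matrix_io
#' @export
write_hit_matrix <- function(hm, path) {
  m <- unclass(hm) * 1L
  df <- data.frame(compound_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname hit_matrix_io
#' @export
read_hit_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE]) == 1
  rownames(m) <- df$compound_id
  class(m) <- c("hit_matrix", class(m))
  m
}

#' Clustering JSON round trip
#'
#' @param clustering a `pharm_clustering`.
#' @param path JSON file path.
#' @return `read_clustering_json()` returns a `pharm_clustering`.
#' @name clustering_io
#' @export
write_clustering_json <- function(clustering, path) {
  jsonlite::write_json(
    list(method = clustering$method, clusters = clustering$clusters,
         special_class = clustering$special_class,
         parameters = clustering$parameters),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname clustering_io
#' @export
read_clustering_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  new_clustering(x$method, lapply(x$clusters, as.character),
                 as.character(x$special_class %||% character(0L)),
                 parameters = x$parameters %||% list())
}
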