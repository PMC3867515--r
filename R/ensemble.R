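# Ensemble screening: hit matrices, confusion statistics (MCC, accuracy,
# recall), exhaustive search for the best linear combination of hypotheses
# under hit-once / hit-twice classification, optimization curves, and the
# random-combination and single universal-hypothesis benchmarks.

#' Screen compounds against a set of hypotheses
#'
#' @param hypotheses named list of `pharm_hypothesis`.
#' @param features `feature_table` with the compounds' conformer features.
#' @param compound_ids compounds to screen (default: all in `features`).
#' @return logical hit matrix (compounds x hypotheses) of class
#'   `hit_matrix`; compounds with no features get an all-false row with a
#'   warning.
#' @export
screen <- function(hypotheses, features, compound_ids = NULL) {
  if (!length(hypotheses)) stopf("no hypotheses to screen against")
  if (is.null(names(hypotheses))) {
    names(hypotheses) <- vapply(hypotheses, `[[`, character(1L), "hyp_id")
  }
  ids <- compound_ids %||% unique(features$compound_id)
  hm <- matrix(FALSE, length(ids), length(hypotheses),
               dimnames = list(ids, names(hypotheses)))
  by_comp <- split(features, features$compound_id)
  for (i in seq_along(ids)) {
    f <- by_comp[[ids[i]]]
    if (is.null(f) || !nrow(f)) {
      warnf("compound %s has no conformer features; all-false row", ids[i])
      next
    }
    for (j in seq_along(hypotheses)) {
      hm[i, j] <- match_hypothesis(hypotheses[[j]], f)$match
    }
  }
  class(hm) <- c("hit_matrix", class(hm))
  hm
}

#' Classify compounds from their hit rows
#'
#' `hit_once` flags a compound active when at least one hypothesis in the
#' combination matches it; `hit_twice` requires at least two.
#'
#' @param hits logical matrix (or single row) of hits.
#' @param mode `hit_once` or `hit_twice`.
#' @return character vector of predicted labels (`active` / `inactive`).
#' @export
classify_hits <- function(hits, mode = c("hit_once", "hit_twice")) {
  mode <- match.arg(mode)
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1L)
  if (!ncol(hits)) stopf("empty hit rows")
  need <- if (mode == "hit_once") 1L else 2L
  ifelse(rowSums(hits) >= need, "active", "inactive")
}

#' Confusion matrix from predicted and true labels
#'
#' @param predictions,truth character vectors over `active` / `inactive`.
#' @return list with integer counts `TP`, `FP`, `TN`, `FN` of class
#'   `confusion_matrix`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stopf("predictions and truth differ in length")
  }
  ok <- c("active", "inactive")
  if (!all(predictions %in% ok) || !all(truth %in% ok)) {
    stopf("labels must be 'active' or 'inactive'")
  }
  structure(list(
    TP = sum(predictions == "active" & truth == "active"),
    FP = sum(predictions == "active" & truth == "inactive"),
    TN = sum(predictions == "inactive" & truth == "inactive"),
    FN = sum(predictions == "inactive" & truth == "active")
  ), class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in \[-1, 1\];
#' defined as 0 when any denominator factor vanishes.
#'
#' @param cm a `confusion_matrix` (or list with TP/FP/TN/FN).
#' @return numeric scalar.
#' @export
mcc <- function(cm) {
  den <- (cm$TP + cm$FP) * (cm$TP + cm$FN) * (cm$TN + cm$FP) * (cm$TN + cm$FN)
  if (den == 0) return(0)
  (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(den)
}

#' Classification accuracy
#' @param cm a `confusion_matrix`.
#' @return `(TP+TN) / (TP+FP+TN+FN)`.
#' @export
accuracy <- function(cm) {
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stopf("empty confusion matrix")
  (cm$TP + cm$TN) / total
}

#' Recall (sensitivity)
#' @param cm a `confusion_matrix` with at least one true active.
#' @return `TP / (TP+FN)`.
#' @export
recall <- function(cm) {
  if (cm$TP + cm$FN == 0) stopf("recall undefined without actives")
  cm$TP / (cm$TP + cm$FN)
}

#' All three screening statistics at once
#' @param cm a `confusion_matrix`.
#' @return list with `mcc`, `accuracy`, `recall`.
#' @export
screening_stats <- function(cm) {
  list(mcc = mcc(cm), accuracy = accuracy(cm), recall = recall(cm))
}

# Stats of one combination on one labelled compound set.
.pair_stats <- function(hm, combo, mode, actives, inactives) {
  ids <- c(actives, inactives)
  missing <- setdiff(ids, rownames(hm))
  if (length(missing)) stopf("hit matrix lacks compounds: %s",
                             paste(utils::head(missing, 3L), collapse = ", "))
  pred <- classify_hits(hm[ids, combo, drop = FALSE], mode)
  truth <- c(rep("active", length(actives)), rep("inactive", length(inactives)))
  confusion(pred, truth)
}

#' Evaluate a combination of hypotheses on a paired test set
#'
#' Restricts the hit matrix to the combination's columns, classifies under
#' the given hit mode, and computes MCC/accuracy/recall separately on the
#' actives-vs-decoys and actives-vs-assumed-inactives sets; the reported
#' statistics are the elementwise average of the two.
#'
#' @param hm a `hit_matrix`.
#' @param combo character vector of hypothesis ids (columns of `hm`).
#' @param mode `hit_once` or `hit_twice`.
#' @param pair a `test_set_pair`.
#' @return list of class `combination_result` with `hyp_ids`, `hit_mode`,
#'   `cm_decoys`, `cm_assumed`, `stats_vs_decoys`, `stats_vs_assumed`,
#'   `stats_avg`.
#' @export
evaluate_combination <- function(hm, combo, mode = c("hit_once", "hit_twice"),
                                 pair) {
  mode <- match.arg(mode)
  combo <- as.character(combo)
  if (!length(combo)) stopf("empty combination")
  if (!all(combo %in% colnames(hm))) stopf("unknown hypothesis id in combination")
  cm_d <- .pair_stats(hm, combo, mode, pair$actives, pair$decoys)
  cm_a <- .pair_stats(hm, combo, mode, pair$actives, pair$assumed_inactives)
  s_d <- screening_stats(cm_d)
  s_a <- screening_stats(cm_a)
  avg <- Map(function(a, b) (a + b) / 2, s_d, s_a)
  structure(list(hyp_ids = sort(combo), hit_mode = mode,
                 cm_decoys = cm_d, cm_assumed = cm_a,
                 stats_vs_decoys = s_d, stats_vs_assumed = s_a,
                 stats_avg = avg),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination of %d hypotheses (%s): MCC %.3f, accuracy %.3f, recall %.3f>\n",
              length(x$hyp_ids), x$hit_mode, x$stats_avg$mcc,
              x$stats_avg$accuracy, x$stats_avg$recall))
  invisible(x)
}

#' Best combination of a given length (exhaustive)
#'
#' Enumerates every k-subset of the hypothesis columns and returns the one
#' maximizing the averaged metric; ties go to the lexicographically
#' smallest sorted id set. Workloads above `budget` subsets are refused
#' with a pointer to [greedy_combination()].
#'
#' @param hm a `hit_matrix`.
#' @param pair a `test_set_pair`.
#' @param metric `mcc`, `accuracy` or `recall`.
#' @param mode `hit_once` or `hit_twice`.
#' @param k combination length.
#' @param budget maximum number of subsets to enumerate (default 5e6).
#' @return the winning `combination_result`, with the optimized metric in
#'   its `optimized_metric` element.
#' @export
best_combination <- function(hm, pair, metric = c("mcc", "accuracy", "recall"),
                             mode = c("hit_once", "hit_twice"), k,
                             budget = 5e6) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  n <- ncol(hm)
  if (k < 1L || k > n) stopf("k must be between 1 and %d", n)
  if (choose(n, k) > budget) {
    stopf("%s subsets exceed the enumeration budget (%g); consider greedy_combination()",
          format(choose(n, k), big.mark = ","), budget)
  }
  best <- NULL
  best_score <- -Inf
  best_key <- ""
  cols <- sort(colnames(hm))
  utils::combn(cols, k, FUN = function(combo) {
    res <- evaluate_combination(hm, combo, mode, pair)
    score <- res$stats_avg[[metric]]
    key <- paste(res$hyp_ids, collapse = "\r")
    if (score > best_score + 1e-12 ||
        (abs(score - best_score) <= 1e-12 && key < best_key)) {
      best <<- res
      best_score <<- score
      best_key <<- key
    }
    NULL
  }, simplify = FALSE)
  best$optimized_metric <- metric
  best
}

#' Greedy forward selection of a combination (non-exhaustive)
#'
#' Fallback for workloads beyond the exhaustive budget: adds at each step
#' the hypothesis improving the averaged metric the most. Clearly labelled
#' non-exhaustive; its result carries `search = "greedy"`.
#'
#' @inheritParams best_combination
#' @return a `combination_result`.
#' @export
greedy_combination <- function(hm, pair, metric = c("mcc", "accuracy", "recall"),
                               mode = c("hit_once", "hit_twice"), k) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  combo <- character(0L)
  for (step in seq_len(k)) {
    rest <- sort(setdiff(colnames(hm), combo))
    scores <- vapply(rest, function(h) {
      evaluate_combination(hm, c(combo, h), mode, pair)$stats_avg[[metric]]
    }, numeric(1L))
    combo <- c(combo, rest[which.max(scores)])
  }
  res <- evaluate_combination(hm, combo, mode, pair)
  res$optimized_metric <- metric
  res$search <- "greedy"
  res
}

#' Optimization curve over combination lengths
#'
#' Runs [best_combination()] for every length from 1 to `k_max` and
#' reports the per-length best score plus the global optimum.
#'
#' @inheritParams best_combination
#' @param k_max largest combination length.
#' @return data frame with columns `k`, `score`, `combination`
#'   (id strings separated by `+`), with attribute `best` holding the
#'   global-optimum `combination_result` and `best_k` its length.
#' @export
optimization_curve <- function(hm, pair, metric = c("mcc", "accuracy", "recall"),
                               mode = c("hit_once", "hit_twice"), k_max,
                               budget = 5e6) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (k_max > ncol(hm)) stopf("k_max exceeds the number of hypotheses")
  results <- lapply(seq_len(k_max), function(k) {
    best_combination(hm, pair, metric, mode, k, budget = budget)
  })
  scores <- vapply(results, function(r) r$stats_avg[[metric]], numeric(1L))
  curve <- data.frame(
    k = seq_len(k_max), score = scores,
    combination = vapply(results, function(r)
      paste(r$hyp_ids, collapse = "+"), character(1L)),
    stringsAsFactors = FALSE)
  i_best <- which.max(scores)  # first (smallest k) at the maximum
  attr(curve, "best") <- results[[i_best]]
  attr(curve, "best_k") <- i_best
  curve
}

#' Random-combination benchmark
#'
#' Draws `n_draws` uniform k-subsets of the hypotheses, evaluates each on
#' the pair, and reports the mean and SD of the averaged metric together
#' with the percent gain of the optimized combination over the random
#' mean: `gain = 100 * (optimized - mean) / mean`.
#'
#' @inheritParams best_combination
#' @param n_draws number of random combinations (default 10).
#' @param seed RNG seed.
#' @param optimized optimized score to compare against; computed via
#'   [best_combination()] when omitted.
#' @return list with `mean`, `sd`, `gain_percent`, `scores`, `optimized`.
#' @export
random_benchmark <- function(hm, pair, metric = c("mcc", "accuracy", "recall"),
                             mode = c("hit_once", "hit_twice"), k,
                             n_draws = 10L, seed = NULL, optimized = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (k > ncol(hm)) stopf("k exceeds the number of hypotheses")
  scores <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
    combo <- sample(colnames(hm), k)
    evaluate_combination(hm, combo, mode, pair)$stats_avg[[metric]]
  }, numeric(1L)))
  if (is.null(optimized)) {
    optimized <- best_combination(hm, pair, metric, mode, k)$stats_avg[[metric]]
  }
  list(mean = mean(scores), sd = stats::sd(scores),
       gain_percent = benchmark_gain(optimized, mean(scores)),
       scores = scores, optimized = optimized)
}

#' Percent gain of an optimized score over a random-mean score
#'
#' @param optimized,random_mean scores on the same metric.
#' @return `100 * (optimized - random_mean) / random_mean`.
#' @export
benchmark_gain <- function(optimized, random_mean) {
  100 * (optimized - random_mean) / random_mean
}

#' Single universal hypothesis benchmark
#'
#' Picks one representative per cluster -- the medoid ("centroid": minimum
#' total Soergel distance to its cluster, ties to the smallest id) or a
#' seeded random member -- and develops a single hypothesis from those
#' picks treated as one pseudo-cluster.
#'
#' @param clustering a `pharm_clustering`.
#' @param features `feature_table` covering the picked compounds.
#' @param d distance matrix over the clustered compounds (for medoids).
#' @param pick `centroid` or `random`.
#' @param seed RNG seed for random picks.
#' @param background optional background `feature_table` for selectivity.
#' @param ... passed to [generate_hypotheses()].
#' @return a `pharm_hypothesis`, or `NULL` when no candidate survives
#'   (reported via a warning); the picks are attached as attribute
#'   `picks`.
#' @export
universal_hypothesis <- function(clustering, features, d,
                                 pick = c("centroid", "random"), seed = NULL,
                                 background = NULL, ...) {
  pick <- match.arg(pick)
  if (length(clustering$clusters) < 2L) stopf("need at least 2 clusters")
  picks <- vapply(clustering$clusters, function(ids) {
    if (length(ids) == 1L) return(ids)
    if (pick == "centroid") cluster_medoid(ids, d)
    else with_seed(seed, sample(ids, 1L))
  }, character(1L))
  rf <- features[features$compound_id %in% picks, , drop = FALSE]
  cand <- generate_hypotheses(rf, cluster_id = "universal",
                              background = background, ...)
  best <- select_best(cand)
  if (is.null(best)) {
    warnf("no universal hypothesis met the match-rate requirement")
    return(NULL)
  }
  attr(best, "picks") <- picks
  best
}

#' Medoid of a cluster under a distance matrix
#'
#' The member minimizing the total distance to the others; ties break to
#' the smallest id.
#'
#' @param ids cluster member ids.
#' @param d distance matrix.
#' @return single id.
#' @export
cluster_medoid <- function(ids, d) {
  ids <- sort(as.character(ids))
  tot <- rowSums(d[ids, ids, drop = FALSE])
  ids[which.min(tot)]
}
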