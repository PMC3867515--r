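cm <- function(TP, FN, TN, FP) structure(list(TP = TP, FP = FP, TN = TN,
                                              FN = FN),
                                         class = "confusion_matrix")

test_that("hit-mode classification follows the one/two-model rules", {
  expect_equal(classify_hits(c(TRUE, FALSE, FALSE), "hit_once"), "active")
  expect_equal(classify_hits(c(TRUE, FALSE, FALSE), "hit_twice"), "inactive")
  expect_equal(classify_hits(c(TRUE, TRUE, FALSE), "hit_twice"), "active")
  m <- rbind(a = c(TRUE, FALSE), b = c(FALSE, FALSE))
  expect_equal(unname(classify_hits(m, "hit_once")), c("active", "inactive"))
})

test_that("confusion counts are standard 2x2 counts", {
  pred <- c(rep("active", 3), rep("inactive", 2))
  truth <- c(rep("active", 3), rep("inactive", 2))
  c1 <- confusion(pred, truth)
  expect_equal(unclass(c1)[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  c2 <- confusion(rev(pred), truth)  # hand-counted mixed case
  expect_equal(c2$TP, 1L)
  expect_equal(c2$FN, 2L)
  expect_equal(c2$FP, 2L)
  expect_equal(c2$TN, 0L)
  inverted <- ifelse(truth == "active", "inactive", "active")
  c3 <- confusion(inverted, truth)
  expect_equal(c3$TP + c3$TN, 0L)
  expect_error(confusion("active", c("active", "inactive")), "length")
})

test_that("screening statistics have their textbook values", {
  expect_equal(mcc(cm(10, 0, 10, 0)), 1)
  expect_equal(mcc(cm(5, 5, 5, 5)), 0)
  expect_equal(mcc(cm(0, 10, 0, 10)), -1)
  expect_equal(mcc(cm(0, 0, 5, 0)), 0)  # degenerate denominator convention
  expect_equal(accuracy(cm(3, 0, 2, 0)), 1)
  expect_equal(recall(cm(3, 0, 2, 0)), 1)
  expect_error(recall(cm(0, 0, 5, 5)), "undefined")
  expect_error(accuracy(cm(0, 0, 0, 0)), "empty")
})

test_that("label inversion flips the sign of MCC exactly", {
  set.seed(7)
  for (i in 1:10) {
    truth <- sample(c("active", "inactive"), 30, replace = TRUE)
    pred <- sample(c("active", "inactive"), 30, replace = TRUE)
    inv <- ifelse(pred == "active", "inactive", "active")
    expect_equal(mcc(confusion(inv, truth)), -mcc(confusion(pred, truth)),
                 tolerance = 1e-12)
  }
})

test_that("screening produces the planted block hit pattern", {
  w <- generate_world(n_templates = 2, actives_per_template = 5,
                      n_inactives = 4, seed = 3)
  ids <- w$compounds$compound_id
  hm <- screen(w$templates, w$features, compound_ids = ids)
  for (i in seq_along(ids)) {
    own <- w$compounds$template[i]
    for (t in names(w$templates)) {
      expect_equal(unname(hm[ids[i], t]), !is.na(own) && own == t)
    }
  }
  # hit-matrix CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_hit_matrix(hm, path)
  expect_equal(unclass(read_hit_matrix(path))[, ], unclass(hm)[, ])
})

test_that("combination evaluation averages the two pair statistics", {
  hm <- random_hit_matrix(30, 4, seed = 5)
  pair <- pair_from_rows(hm)
  res <- evaluate_combination(hm, colnames(hm)[1:2], "hit_once", pair)
  for (metric in c("mcc", "accuracy", "recall")) {
    expect_equal(res$stats_avg[[metric]],
                 (res$stats_vs_decoys[[metric]] +
                    res$stats_vs_assumed[[metric]]) / 2)
  }
  # recall only involves actives, so the two pairs agree on it
  expect_equal(res$stats_vs_decoys$recall, res$stats_vs_assumed$recall)
  expect_error(evaluate_combination(hm, character(0), "hit_once", pair),
               "empty combination")
  expect_error(evaluate_combination(hm, "nope", "hit_once", pair), "unknown")
})

test_that("confusion matrices conserve the role sizes", {
  for (s in 1:10) {
    hm <- random_hit_matrix(24, 5, seed = s)
    pair <- pair_from_rows(hm)
    k <- sample(ncol(hm), 1)
    res <- evaluate_combination(hm, sample(colnames(hm), k),
                                sample(c("hit_once", "hit_twice"), 1), pair)
    expect_equal(res$cm_decoys$TP + res$cm_decoys$FN, length(pair$actives))
    expect_equal(res$cm_decoys$TN + res$cm_decoys$FP, length(pair$decoys))
    expect_equal(res$cm_assumed$TP + res$cm_assumed$FN, length(pair$actives))
    expect_equal(res$cm_assumed$TN + res$cm_assumed$FP,
                 length(pair$assumed_inactives))
  }
})

test_that("the exhaustive optimizer agrees with the naive enumerator", {
  for (s in 1:8) {
    set.seed(s)
    hm <- random_hit_matrix(sample(6:12, 1), sample(3:6, 1), seed = 100 + s)
    pair <- pair_from_rows(hm)
    metric <- sample(c("mcc", "accuracy", "recall"), 1)
    mode <- sample(c("hit_once", "hit_twice"), 1)
    for (k in seq_len(ncol(hm))) {
      got <- best_combination(hm, pair, metric, mode, k)
      want <- naive_best_combination(hm, pair$actives, pair$decoys,
                                     pair$assumed_inactives, metric, mode, k)
      expect_equal(got$stats_avg[[metric]], want$score, tolerance = 1e-12)
      expect_equal(got$hyp_ids, want$ids)
    }
  }
})

test_that("k equal to the pool size returns the full set", {
  hm <- random_hit_matrix(12, 4, seed = 2)
  pair <- pair_from_rows(hm)
  res <- best_combination(hm, pair, "mcc", "hit_once", k = 4)
  expect_setequal(res$hyp_ids, colnames(hm))
  expect_error(best_combination(hm, pair, "mcc", "hit_once", k = 2,
                                budget = 1), "budget")
})

test_that("hit-twice actives are a subset of hit-once actives", {
  for (s in 1:10) {
    hm <- random_hit_matrix(20, 5, seed = 200 + s)
    once <- classify_hits(hm, "hit_once") == "active"
    twice <- classify_hits(hm, "hit_twice") == "active"
    expect_true(all(!twice | once))
  }
})

test_that("adding a hypothesis under hit-once never loses actives", {
  for (s in 1:10) {
    hm <- random_hit_matrix(20, 5, seed = 300 + s)
    pair <- pair_from_rows(hm)
    combo <- sample(colnames(hm), 3)
    extra <- setdiff(colnames(hm), combo)[1]
    a <- evaluate_combination(hm, combo, "hit_once", pair)
    b <- evaluate_combination(hm, c(combo, extra), "hit_once", pair)
    expect_gte(b$cm_decoys$TP, a$cm_decoys$TP)
    expect_lte(b$cm_decoys$TN, a$cm_decoys$TN)
  }
})

test_that("the optimization curve is non-decreasing for hit-once recall", {
  for (s in 1:5) {
    hm <- random_hit_matrix(18, 5, seed = 400 + s)
    pair <- pair_from_rows(hm)
    curve <- optimization_curve(hm, pair, "recall", "hit_once",
                                k_max = ncol(hm))
    expect_true(all(diff(curve$score) >= -1e-12))
  }
  # k_max = 1 gives a single-point curve
  hm <- random_hit_matrix(12, 3, seed = 1)
  curve1 <- optimization_curve(hm, pair_from_rows(hm), "recall", "hit_once",
                               k_max = 1)
  expect_equal(nrow(curve1), 1L)
})

test_that("a covering set of planted hypotheses saturates the recall curve", {
  w <- generate_world(n_templates = 3, actives_per_template = 6,
                      n_inactives = 36, seed = 10)
  ids <- w$compounds$compound_id
  act <- ids[w$compounds$label == "active"]
  inact <- ids[w$compounds$label == "inactive"]
  hm <- screen(w$templates, w$features, compound_ids = ids)
  pair <- test_set_pair(act, inact[1:18], inact[19:36])
  curve <- optimization_curve(hm, pair, "recall", "hit_once", k_max = 3)
  expect_equal(curve$score[3], 1)
  expect_true(all(diff(curve$score) >= 0))
})

test_that("random benchmarks bracket the optimized score", {
  hm <- random_hit_matrix(21, 6, seed = 9)
  pair <- pair_from_rows(hm)
  opt <- best_combination(hm, pair, "mcc", "hit_once", k = 3)$stats_avg$mcc
  rb <- random_benchmark(hm, pair, "mcc", "hit_once", k = 3, n_draws = 10,
                         seed = 4)
  expect_true(all(rb$scores <= opt + 1e-12))
  expect_equal(rb$optimized, opt)
  expect_equal(rb$gain_percent,
               100 * (opt - mean(rb$scores)) / mean(rb$scores))
  # identical columns: zero spread
  same <- hm
  for (j in seq_len(ncol(same))) same[, j] <- hm[, 1]
  rb2 <- random_benchmark(same, pair, "recall", "hit_once", k = 2,
                          n_draws = 5, seed = 1)
  expect_equal(rb2$sd, 0)
  # optimized equal to the random mean: zero gain
  expect_equal(benchmark_gain(0.5, 0.5), 0)
})

test_that("medoid selection minimizes total distance with id tie-breaks", {
  d3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3["a", "b"] <- d3["b", "a"] <- 0.1
  d3["a", "c"] <- d3["c", "a"] <- 0.9
  d3["b", "c"] <- d3["c", "b"] <- 0.9
  # totals: a = 1.0, b = 1.0, c = 1.8 -> tie between a and b -> a
  expect_equal(cluster_medoid(c("a", "b", "c"), d3), "a")
  d3["a", "b"] <- d3["b", "a"] <- 0.2
  d3["a", "c"] <- d3["c", "a"] <- 0.3
  expect_equal(cluster_medoid(c("a", "b", "c"), d3), "a")  # strict minimum
})

test_that("universal hypothesis uses one pick per cluster", {
  # two clusters of compounds that share a common 4-feature core, so a
  # universal hypothesis mapping at least half of the picks exists
  ftypes <- c("A", "P", "R", "H")
  xyz <- matrix(c(0, 0, 0, 5, 0, 0, 2, 4, 0, 1, 1, 4), 4, 3, byrow = TRUE)
  set.seed(31)
  ids <- sprintf("u%02d", 1:6)
  feats <- do.call(rbind, lapply(seq_along(ids), function(i) {
    ft_from_points(ids[i], ftypes, xyz + matrix(rnorm(12, 0, 0.1), 4, 3))
  }))
  dm <- matrix(0.5, 6, 6, dimnames = list(ids, ids))
  dm[1:3, 1:3] <- 0.1; dm[4:6, 4:6] <- 0.1
  diag(dm) <- 0
  cl <- pharmensemble:::new_clustering("m2d", list(c1 = ids[1:3],
                                                   c2 = ids[4:6]))
  u <- universal_hypothesis(cl, feats, dm, pick = "centroid", seed = 1)
  expect_s3_class(u, "pharm_hypothesis")
  picks <- attr(u, "picks")
  expect_length(picks, 2L)
  expect_true(picks[1] %in% ids[1:3] && picks[2] %in% ids[4:6])
  expect_equal(unname(picks["c1"]), cluster_medoid(ids[1:3], dm))
  expect_gte(u$match_rate, 0.5)
  # seeded random picks reproduce exactly
  u1 <- universal_hypothesis(cl, feats, dm, pick = "random", seed = 5)
  u2 <- universal_hypothesis(cl, feats, dm, pick = "random", seed = 5)
  expect_identical(attr(u1, "picks"), attr(u2, "picks"))
  # single-member clusters: the pick is the member in either mode
  cl1 <- pharmensemble:::new_clustering("m2d", list(a = ids[1], b = ids[4]))
  ur <- universal_hypothesis(cl1, feats, dm, pick = "random", seed = 2)
  expect_setequal(unname(attr(ur, "picks")), c(ids[1], ids[4]))
})
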