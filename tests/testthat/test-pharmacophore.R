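# A compact reference geometry used throughout: 4 well-separated points.
ref4 <- function() {
  list(ftypes = c("A", "P", "R", "H"),
       xyz = matrix(c(0, 0, 0,
                      5, 0, 0,
                      2, 4, 0,
                      1, 1, 4), 4, 3, byrow = TRUE))
}

test_that("feature perception applies the documented pattern rules", {
  sdf <- read_structures(smiles = c(benzene = "c1ccccc1",
                                    mam = "C[NH3+]",
                                    hexane = "CCCCCC"))
  fb <- perceive_features(sdf[1], "benzene")
  expect_equal(fb$ftype, "R")               # one aromatic ring centroid
  # the centroid sits at the ring's geometric center
  g <- pharmensemble:::mol_graph(sdf[[1]])
  expect_equal(c(fb$x, fb$y, fb$z), unname(colMeans(g$xyz)), tolerance = 1e-6)
  fm <- perceive_features(sdf[2], "mam")
  expect_equal(fm$ftype, "P")               # single charged nitrogen
  fh <- perceive_features(sdf[3], "hexane")
  expect_gte(sum(fh$ftype == "H"), 1L)
  expect_equal(sum(fh$ftype %in% c("A", "D", "P", "R")), 0L)
})

test_that("hypothesis construction validates geometry and size", {
  r <- ref4()
  h <- new_hypothesis("h1", r$ftypes, r$xyz)
  expect_equal(diag(h$dist), rep(0, 4))
  expect_equal(h$dist, t(h$dist))
  expect_equal(h$dist[1, 2], 5)
  expect_error(new_hypothesis("h", c("A", "D", "R"), r$xyz[1:3, ]), "4-7")
  expect_error(new_hypothesis("h", rep("A", 8), matrix(rnorm(24), 8, 3)),
               "4-7")
})

test_that("Kabsch RMSD agrees with an independent Horn-quaternion fit", {
  set.seed(6)
  for (i in 1:20) {
    P <- matrix(rnorm(15), 5, 3)
    Q <- matrix(rnorm(15), 5, 3)
    expect_equal(pharmensemble:::kabsch_rmsd(P, Q), horn_rmsd(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("a hypothesis matches its own points with zero RMSD", {
  r <- ref4()
  h <- new_hypothesis("self", r$ftypes, r$xyz)
  ft <- ft_from_points("c1", r$ftypes, r$xyz)
  res <- match_hypothesis(h, ft)
  expect_true(res$match)
  expect_equal(res$rmsd, 0, tolerance = 1e-6)
})

test_that("a missing feature type can never match", {
  r <- ref4()
  h <- new_hypothesis("needsP", r$ftypes, r$xyz)
  # replace the P point with a D: type deficit
  ft <- ft_from_points("c1", c("A", "D", "R", "H"), r$xyz)
  res <- match_hypothesis(h, ft)
  expect_false(res$match)
  expect_equal(res$rmsd, Inf)
})

test_that("small jitters stay within tolerance, certified by the oracle", {
  r <- ref4()
  h <- new_hypothesis("h", r$ftypes, r$xyz)
  set.seed(13)
  for (i in 1:10) {
    jit <- r$xyz + matrix(runif(12, -0.3, 0.3), 4, 3)
    ft <- rigid_transform(ft_from_points("c", r$ftypes, jit), seed = i)
    res <- match_hypothesis(h, ft)
    ora <- oracle_min_rmsd(r$ftypes, r$xyz, ft$ftype,
                           as.matrix(ft[, c("x", "y", "z")]))
    expect_true(res$match)
    expect_lte(ora, 2)
    expect_equal(res$rmsd, ora, tolerance = 1e-6)
  }
})

test_that("matching is invariant under rigid motion of the conformer", {
  r <- ref4()
  h <- new_hypothesis("h", r$ftypes, r$xyz)
  base <- ft_from_points("c", r$ftypes,
                         r$xyz + matrix(0.2, 4, 3))
  r0 <- match_hypothesis(h, base)$rmsd
  for (s in 1:8) {
    moved <- rigid_transform(base, seed = s)
    expect_equal(match_hypothesis(h, moved)$rmsd, r0, tolerance = 1e-6)
  }
})

test_that("raising the tolerance never destroys a match", {
  r <- ref4()
  h <- new_hypothesis("h", r$ftypes, r$xyz)
  set.seed(3)
  for (i in 1:10) {
    jit <- r$xyz + matrix(rnorm(12, 0, 1), 4, 3)
    ft <- ft_from_points("c", r$ftypes, jit)
    tols <- c(0.5, 1, 2, 4, 8)
    matches <- vapply(tols, function(tt)
      match_hypothesis(h, ft, tolerance = tt)$match, logical(1))
    expect_true(all(diff(as.integer(matches)) >= 0))  # monotone in tolerance
  }
})

test_that("multi-conformer compounds match when any conformer fits", {
  r <- ref4()
  h <- new_hypothesis("h", r$ftypes, r$xyz)
  bad <- ft_from_points("c", r$ftypes, r$xyz * 3, conformer = 1L)
  good <- ft_from_points("c", r$ftypes, r$xyz, conformer = 2L)
  both <- rbind(bad, good)
  expect_false(match_hypothesis(h, bad)$match)
  expect_true(match_hypothesis(h, both)$match)
})

test_that("hypothesis generation scores match rates and selectivity", {
  r <- ref4()
  # two identical representatives: some candidate must reach rate 1.0
  ft <- rbind(ft_from_points("r1", r$ftypes, r$xyz),
              ft_from_points("r2", r$ftypes, r$xyz))
  cand <- generate_hypotheses(ft, cluster_id = "toy", seed = 1)
  expect_gt(length(cand), 0)
  expect_true(any(vapply(cand, `[[`, numeric(1), "match_rate") == 1))

  # mutually incompatible representatives: every candidate maps only its
  # own source (1/3 < 0.5), so no hypothesis survives
  ft2 <- rbind(ft_from_points("r1", r$ftypes, r$xyz),
               ft_from_points("r2", r$ftypes, r$xyz * 4),
               ft_from_points("r3", r$ftypes, r$xyz * 16))
  expect_length(generate_hypotheses(ft2, cluster_id = "bad", seed = 1), 0)

  # background = representatives themselves: selectivity = 1 - match_rate
  cand3 <- generate_hypotheses(ft, cluster_id = "toy", background = ft,
                               seed = 1)
  for (h in cand3) {
    expect_equal(h$selectivity, 1 - h$match_rate, tolerance = 1e-12)
  }
})

test_that("best-hypothesis selection ranks lexicographically", {
  mk <- function(id, k, rate, sel) {
    set.seed(nchar(id))
    h <- new_hypothesis(id, rep(c("A", "D", "P", "R", "H"), 2)[1:k],
                        pharmensemble:::.random_geometry(k),
                        match_rate = rate, selectivity = sel)
    h
  }
  # more features beat a higher rate
  expect_equal(select_best(list(mk("a", 4, 0.9, 1), mk("b", 5, 0.6, 1)))$hyp_id,
               "b")
  # equal features: higher rate wins
  expect_equal(select_best(list(mk("a", 5, 0.8, 1), mk("b", 5, 0.6, 1)))$hyp_id,
               "a")
  # equal features and rate: higher selectivity wins
  expect_equal(select_best(list(mk("a", 5, 0.8, 0.4),
                                mk("b", 5, 0.8, 0.9)))$hyp_id, "b")
  # full tie: deterministic smallest id
  expect_equal(select_best(list(mk("b", 5, 0.8, 0.9),
                                mk("a", 5, 0.8, 0.9)))$hyp_id, "a")
  expect_null(select_best(list()))
})

test_that("hypothesis JSON serialization round-trips", {
  r <- ref4()
  h <- new_hypothesis("h1", r$ftypes, r$xyz, source_cluster = "cl",
                      match_rate = 0.75, selectivity = 0.9)
  path <- withr::local_tempfile(fileext = ".json")
  write_hypotheses_json(list(h1 = h), path)
  back <- read_hypotheses_json(path)[["h1"]]
  expect_equal(back$ftypes, h$ftypes)
  expect_equal(back$dist, h$dist, tolerance = 1e-12)
  expect_equal(back$match_rate, 0.75)
  # a round-tripped hypothesis still matches its origin geometry
  expect_true(match_hypothesis(back, ft_from_points("c", r$ftypes,
                                                    r$xyz))$match)
})
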