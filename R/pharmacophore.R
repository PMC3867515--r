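# Pharmacophore hypotheses: typed feature points with a reference geometry,
# matched against conformer feature clouds by type-consistent assignment
# plus least-squares (Kabsch) superposition under an RMSD tolerance.

FEATURE_TYPES <- c("A", "D", "H", "P", "R")

#' Build a feature table
#'
#' The feature table is the interchange format for conformer features: one
#' row per feature point, with columns `compound_id`, `conformer`, `ftype`
#' (A = H-bond acceptor, D = H-bond donor, H = hydrophobic group, P =
#' positively charged group, R = aromatic ring) and Cartesian coordinates
#' `x`, `y`, `z` in Angstroms.
#'
#' @param compound_id,conformer,ftype,x,y,z column vectors (recycled).
#' @return data frame of class `feature_table`.
#' @export
feature_table <- function(compound_id, conformer = 1L, ftype, x, y, z) {
  ft <- data.frame(compound_id = as.character(compound_id),
                   conformer = as.integer(conformer),
                   ftype = as.character(ftype),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_feature_table(ft)
}

validate_feature_table <- function(ft) {
  need <- c("compound_id", "conformer", "ftype", "x", "y", "z")
  if (!all(need %in% names(ft))) {
    stopf("feature table needs columns %s", paste(need, collapse = ", "))
  }
  bad <- !ft$ftype %in% FEATURE_TYPES
  if (any(bad)) stopf("unknown feature types: %s",
                      paste(unique(ft$ftype[bad]), collapse = ", "))
  if (any(!is.finite(as.matrix(ft[, c("x", "y", "z")])))) {
    stopf("feature coordinates must be finite")
  }
  class(ft) <- unique(c("feature_table", class(ft)))
  ft
}

#' Construct a pharmacophore hypothesis
#'
#' A hypothesis is an ordered list of 4-7 typed features with a reference
#' geometry; the derived inter-feature distance matrix (Angstroms) is what
#' gets serialized and used for assignment pruning during matching.
#'
#' @param hyp_id identifier.
#' @param ftypes character vector of feature types (length 4-7).
#' @param coords numeric matrix (length(ftypes) x 3) of reference
#'   coordinates in Angstroms.
#' @param tolerance_rmsd match tolerance in Angstroms (default 2).
#' @param source_cluster provenance cluster name.
#' @param match_rate,selectivity optional quality scores filled in by
#'   [generate_hypotheses()].
#' @return object of class `pharm_hypothesis`.
#' @export
new_hypothesis <- function(hyp_id, ftypes, coords, tolerance_rmsd = 2,
                           source_cluster = NA_character_,
                           match_rate = NA_real_, selectivity = NA_real_) {
  ftypes <- as.character(ftypes)
  k <- length(ftypes)
  if (k < 4L || k > 7L) stopf("a hypothesis has 4-7 features (got %d)", k)
  if (!all(ftypes %in% FEATURE_TYPES)) stopf("invalid feature types")
  coords <- as.matrix(coords)
  if (nrow(coords) != k || ncol(coords) != 3L || any(!is.finite(coords))) {
    stopf("coords must be a finite %d x 3 matrix", k)
  }
  structure(list(hyp_id = as.character(hyp_id), ftypes = ftypes,
                 coords = unname(coords),
                 dist = unname(as.matrix(stats::dist(coords))),
                 tolerance_rmsd = tolerance_rmsd,
                 source_cluster = source_cluster,
                 match_rate = match_rate, selectivity = selectivity),
            class = "pharm_hypothesis")
}

#' @export
print.pharm_hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis %s: %s, tol %.1f A%s%s>\n", x$hyp_id,
              paste(x$ftypes, collapse = ""), x$tolerance_rmsd,
              if (!is.na(x$match_rate))
                sprintf(", match rate %.2f", x$match_rate) else "",
              if (!is.na(x$selectivity))
                sprintf(", selectivity %.2f", x$selectivity) else ""))
  invisible(x)
}

# Optimal superposition RMSD between paired point sets (rows aligned),
# via the Kabsch/SVD rotation with reflection correction.
kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  s <- svd(crossprod(P, Q))
  sgn <- sign(det(s$u %*% t(s$v)))
  dvec <- c(1, 1, sgn)
  rot <- s$v %*% diag(dvec) %*% t(s$u)
  diff <- Q %*% rot  # not needed explicitly; use trace identity instead
  e <- sum(P^2) + sum(Q^2) - 2 * sum(s$d * dvec)
  sqrt(max(0, e) / nrow(P))
}

# Backtracking search over type-consistent injective assignments of
# hypothesis features to conformer points. Partial assignments are pruned
# when any pairwise distance differs from the hypothesis by more than
# 2 * tol; full assignments are scored by Kabsch RMSD.
.match_conformer <- function(h, pts_types, pts_xyz, tol) {
  k <- length(h$ftypes)
  cand <- lapply(h$ftypes, function(tt) which(pts_types == tt))
  if (any(lengths(cand) == 0L)) return(Inf)
  pd <- as.matrix(stats::dist(pts_xyz))
  best <- Inf
  assign <- integer(k)
  recurse <- function(i) {
    if (i > k) {
      r <- kabsch_rmsd(h$coords, pts_xyz[assign, , drop = FALSE])
      if (r < best) best <<- r
      return(invisible(NULL))
    }
    for (p in cand[[i]]) {
      if (p %in% assign[seq_len(i - 1L)]) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (abs(h$dist[i, j] - pd[p, assign[j]]) > 2 * tol) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[i] <<- p
      recurse(i + 1L)
    }
    invisible(NULL)
  }
  recurse(1L)
  best
}

#' Match a hypothesis against a compound's conformer features
#'
#' A conformer matches when some type-consistent injective assignment of
#' hypothesis features to its feature points superposes (least-squares,
#' Kabsch) within the RMSD tolerance; a compound matches if any of its
#' conformers does. Assignments whose pairwise distances deviate from the
#' hypothesis distance matrix by more than twice the tolerance are pruned
#' before superposition.
#'
#' @param h a `pharm_hypothesis`.
#' @param features `feature_table` rows for one compound (any number of
#'   conformers).
#' @param tolerance override of the hypothesis tolerance (Angstroms).
#' @return list with `match` (logical) and `rmsd` (best RMSD across
#'   conformers; `Inf` when no assignment exists).
#' @export
match_hypothesis <- function(h, features, tolerance = NULL) {
  tol <- tolerance %||% h$tolerance_rmsd
  best <- Inf
  for (cf in split(seq_len(nrow(features)), features$conformer)) {
    r <- .match_conformer(h, features$ftype[cf],
                          as.matrix(features[cf, c("x", "y", "z")]), tol)
    if (r < best) best <- r
  }
  list(match = is.finite(best) && best <= tol, rmsd = best)
}

# --- feature perception on 3D structures --------------------------------

#' Perceive pharmacophore features on a conformer
#'
#' Applies documented open pattern rules to a ChemmineR SDF record with 3D
#' (or planar 2D) coordinates: `R` = centroid of each aromatic ring; `P` =
#' positively charged or protonatable sp3 amine nitrogen (not adjacent to
#' a carbonyl); `D` = uncharged N/O bearing at least one hydrogen; `A` =
#' uncharged N/O with a free lone pair (charged and donor-committed
#' nitrogens excluded); `H` = centroid of each connected group of two or
#' more saturated carbons with no heteroatom neighbors.
#'
#' @param mol ChemmineR `SDF`/`SDFset` (first record) with coordinates.
#' @param compound_id id recorded in the output.
#' @param conformer conformer index recorded in the output.
#' @return a `feature_table` (zero rows, with a warning, if no feature is
#'   found).
#' @export
perceive_features <- function(mol, compound_id = "compound", conformer = 1L) {
  g <- mol_graph(mol)
  n <- length(g$element)
  rows <- list()
  add <- function(ftype, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      compound_id = compound_id, conformer = as.integer(conformer),
      ftype = ftype, x = xyz[1L], y = xyz[2L], z = xyz[3L],
      stringsAsFactors = FALSE)
  }
  for (ring in g$aromatic_rings) {
    add("R", colMeans(g$xyz[ring, , drop = FALSE]))
  }
  has_carbonyl_neighbor <- vapply(seq_len(n), function(i) {
    nb <- which(g$adj[i, ] & g$element == "C")
    any(vapply(nb, function(cc) {
      any(g$order[cc, ] == 2 & g$element %in% c("O", "N"))
    }, logical(1L)))
  }, logical(1L))
  is_p <- g$element == "N" &
    (g$charge > 0 |
       (!g$aromatic & g$degree > 0 &
          apply(g$order, 1L, function(o) all(o[o > 0] == 1)) &
          !has_carbonyl_neighbor))
  for (i in which(is_p)) add("P", g$xyz[i, ])
  is_d <- g$element %in% c("N", "O") & g$charge == 0 & g$implicit_h > 0 & !is_p
  for (i in which(is_d)) add("D", g$xyz[i, ])
  is_a <- g$element %in% c("N", "O") & g$charge <= 0 & !is_p & !is_d
  for (i in which(is_a)) add("A", g$xyz[i, ])
  hydrophobe <- g$element == "C" & !g$aromatic &
    vapply(seq_len(n), function(i) {
      all(g$element[g$adj[i, ]] == "C")
    }, logical(1L))
  if (any(hydrophobe)) {
    comp <- .components(g$adj, which(hydrophobe))
    for (grp in comp) {
      if (length(grp) >= 2L) add("H", colMeans(g$xyz[grp, , drop = FALSE]))
    }
  }
  if (!length(rows)) {
    warnf("no pharmacophore features perceived for %s", compound_id)
    return(feature_table(character(0L), integer(0L), character(0L),
                         numeric(0L), numeric(0L), numeric(0L)))
  }
  validate_feature_table(do.call(rbind, rows))
}

# Connected components of the subgraph induced by `nodes`.
.components <- function(adj, nodes) {
  comps <- list()
  left <- nodes
  while (length(left)) {
    frontier <- left[1L]
    comp <- frontier
    left <- left[-1L]
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(i)
        intersect(which(adj[i, ]), left))))
      comp <- c(comp, nb)
      left <- setdiff(left, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# --- hypothesis generation ----------------------------------------------

#' Generate candidate hypotheses from cluster representatives
#'
#' Candidates are k-tuples of feature points (k descending through
#' `k_range`) drawn from each representative's conformers. Each candidate
#' is scored by its match rate over the representatives (fraction of
#' representative compounds it maps); candidates mapping at least
#' `min_match_rate` of them (half, by default) are retained, with
#' selectivity `1 -` the fraction of the background set matched. With
#' `early_stop` (the default) enumeration stops at the largest k that
#' yields any retained candidate, which is the stratum [select_best()]
#' would pick from anyway.
#'
#' @param rep_features `feature_table` for the representative compounds.
#' @param cluster_id provenance label stamped on candidates.
#' @param background optional `feature_table` of background compounds
#'   (typically inactives) for the selectivity score.
#' @param rate_features optional `feature_table` of the full population the
#'   match rate is computed over (e.g. every cluster member); defaults to
#'   the representatives themselves.
#' @param k_range feature counts to try (default 4:7; searched from the
#'   largest down).
#' @param min_match_rate retention threshold (default 0.5).
#' @param tolerance match tolerance in Angstroms (default 2).
#' @param max_candidates enumeration cap per representative and k; beyond
#'   it, a seeded uniform sample of tuples is scored (default 5000).
#' @param early_stop stop after the first k with retained candidates.
#' @param seed RNG seed for above-cap sampling.
#' @return list of `pharm_hypothesis` candidates (possibly empty: the
#'   cluster then yields no hypothesis).
#' @export
generate_hypotheses <- function(rep_features, cluster_id = "cluster",
                                background = NULL, rate_features = NULL,
                                k_range = 4:7,
                                min_match_rate = 0.5, tolerance = 2,
                                max_candidates = 5000L, early_stop = TRUE,
                                seed = 1L) {
  rep_ids <- unique(rep_features$compound_id)
  if (length(rep_ids) < 2L) stopf("need at least 2 representatives")
  if (is.null(rate_features)) rate_features <- rep_features
  cand_by_comp <- split(rep_features, rep_features$compound_id)
  by_comp <- split(rate_features, rate_features$compound_id)
  bg_by_comp <- if (!is.null(background) && nrow(background))
    split(background, background$compound_id) else list()
  out <- list()
  for (k in sort(unique(k_range), decreasing = TRUE)) {
    for (rid in rep_ids) {
      rf <- cand_by_comp[[rid]]
      for (cf in split(seq_len(nrow(rf)), rf$conformer)) {
        n <- length(cf)
        if (n < k) next
        combos <- utils::combn(n, k, simplify = FALSE)
        if (length(combos) > max_candidates) {
          combos <- with_seed(seed, combos[sample.int(length(combos),
                                                      max_candidates)])
        }
        for (ci in seq_along(combos)) {
          idx <- cf[combos[[ci]]]
          h <- new_hypothesis(
            hyp_id = sprintf("%s|%s|cf%s|k%d|%04d", cluster_id, rid,
                             rf$conformer[cf[1L]], k, ci),
            ftypes = rf$ftype[idx],
            coords = as.matrix(rf[idx, c("x", "y", "z")]),
            tolerance_rmsd = tolerance, source_cluster = cluster_id)
          hits <- vapply(by_comp, function(f)
            match_hypothesis(h, f)$match, logical(1L))
          rate <- mean(hits)
          if (rate < min_match_rate) next
          h$match_rate <- rate
          h$selectivity <- if (length(bg_by_comp)) {
            1 - mean(vapply(bg_by_comp, function(f)
              match_hypothesis(h, f)$match, logical(1L)))
          } else 1
          out[[length(out) + 1L]] <- h
        }
      }
    }
    if (early_stop && length(out)) break
  }
  out
}

#' Select the best hypothesis among candidates
#'
#' Lexicographic ranking: more features first, then higher match rate,
#' then higher selectivity, then the (deterministic) smaller id.
#'
#' @param candidates list of scored `pharm_hypothesis` objects (all with
#'   match rate at or above the retention threshold).
#' @return the winning `pharm_hypothesis`, or `NULL` for an empty list.
#' @export
select_best <- function(candidates) {
  if (!length(candidates)) return(NULL)
  ord <- order(vapply(candidates, function(h) length(h$ftypes), numeric(1L)),
               vapply(candidates, function(h) h$match_rate, numeric(1L)),
               vapply(candidates, function(h) h$selectivity %||% 0,
                      numeric(1L)),
               decreasing = TRUE)
  top <- candidates[ord]
  # among full ties on the numeric criteria, take the smallest id
  h1 <- top[[1L]]
  ties <- Filter(function(h) {
    length(h$ftypes) == length(h1$ftypes) &&
      isTRUE(all.equal(h$match_rate, h1$match_rate)) &&
      isTRUE(all.equal(h$selectivity, h1$selectivity))
  }, top)
  ids <- vapply(ties, `[[`, character(1L), "hyp_id")
  ties[[order(ids)[1L]]]
}

#' Build one hypothesis per cluster
#'
#' Runs [generate_hypotheses()] + [select_best()] for every cluster with at
#' least two representatives; clusters whose candidates all fall below the
#' match-rate threshold yield no hypothesis and are listed in the
#' `failed_clusters` attribute. When `members` supplies the full cluster
#' memberships, candidate match rates are computed over every cluster
#' member rather than over the representatives alone.
#'
#' @param reps named list of per-cluster representative id vectors (see
#'   [representatives()]).
#' @param features `feature_table` covering the representatives (and
#'   background).
#' @param background optional background compound ids for selectivity.
#' @param members optional named list (same names as `reps`) of full
#'   cluster memberships used as the match-rate population.
#' @param ... passed to [generate_hypotheses()].
#' @return named list of `pharm_hypothesis` (one per successful cluster),
#'   with attribute `failed_clusters`.
#' @export
build_cluster_hypotheses <- function(reps, features, background = NULL,
                                     members = NULL, ...) {
  bg_ft <- if (!is.null(background))
    features[features$compound_id %in% background, , drop = FALSE]
  out <- list()
  failed <- character(0L)
  for (cl in names(reps)) {
    rf <- features[features$compound_id %in% reps[[cl]], , drop = FALSE]
    if (length(unique(rf$compound_id)) < 2L) {
      failed <- c(failed, cl)
      next
    }
    mf <- if (!is.null(members) && !is.null(members[[cl]]))
      features[features$compound_id %in% members[[cl]], , drop = FALSE]
    cand <- generate_hypotheses(rf, cluster_id = cl, background = bg_ft,
                                rate_features = mf, ...)
    best <- select_best(cand)
    if (is.null(best)) failed <- c(failed, cl) else out[[cl]] <- best
  }
  attr(out, "failed_clusters") <- failed
  out
}
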