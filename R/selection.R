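# Diversity-based selection: sphere exclusion over a distance matrix,
# cluster representatives, most-diverse subsets, and assembly of the three
# paired test-set schemes (random / diverse / populated actives, each
# paired with true decoys and with assumed inactives).

#' Sphere-exclusion diversity selection
#'
#' Repeatedly picks a seed item uniformly at random from the not-yet
#' excluded pool, adds it to the selection, and excludes every item within
#' `radius` of it; stops when the pool is exhausted or `n_target` items are
#' selected. If the pool runs out before `n_target` is met, the selection
#' is padded with the excluded items farthest from the current selection
#' (max-min distance); padded ids are flagged in the `padded` attribute.
#'
#' @param ids character vector of item ids (must index `d`).
#' @param d distance matrix with ids in its dimnames.
#' @param radius exclusion radius (default 0.5, on Soergel scale).
#' @param n_target optional target size.
#' @param seed RNG seed for the random initialization.
#' @param start optional id forced to be the first pick.
#' @return character vector of selected ids, with attribute `padded`.
#' @export
sphere_exclusion <- function(ids, d, radius = 0.5, n_target = NULL,
                             seed = NULL, start = NULL) {
  ids <- as.character(ids)
  if (!length(ids)) {
    warnf("sphere exclusion on an empty pool")
    return(structure(character(0L), padded = character(0L)))
  }
  if (radius < 0) stopf("radius must be non-negative")
  dd <- d[ids, ids, drop = FALSE]
  with_seed(seed, {
    pool <- ids
    picked <- character(0L)
    if (!is.null(start)) {
      if (!start %in% pool) stopf("start item %s not in pool", start)
      picked <- start
      pool <- pool[dd[start, pool] > radius]
    }
    while (length(pool) && (is.null(n_target) || length(picked) < n_target)) {
      s <- pool[sample.int(length(pool), 1L)]
      picked <- c(picked, s)
      pool <- pool[dd[s, pool] > radius]
    }
    padded <- character(0L)
    if (!is.null(n_target) && length(picked) < n_target) {
      rest <- setdiff(ids, picked)
      while (length(picked) < n_target && length(rest)) {
        mind <- apply(dd[rest, picked, drop = FALSE], 1L, min)
        far <- rest[which.max(mind)]
        picked <- c(picked, far)
        padded <- c(padded, far)
        rest <- setdiff(rest, far)
      }
    }
    structure(picked, padded = padded)
  })
}

#' Most diverse subset of a fixed size
#'
#' Operationalizes "the n most diverse compounds" as sphere exclusion whose
#' radius is grown by bisection until the selection size matches `n`; when
#' no radius yields exactly `n`, the closest selection from above is
#' trimmed to its first `n` picks (which are mutually separated) or padded
#' by the max-min rule.
#'
#' @param ids pool of item ids.
#' @param d distance matrix.
#' @param n requested subset size.
#' @param seed RNG seed.
#' @return character vector of `n` ids.
#' @export
most_diverse <- function(ids, d, n, seed = NULL) {
  ids <- as.character(ids)
  if (n > length(ids)) {
    stopf("requested %d items from a pool of %d", n, length(ids))
  }
  if (n == length(ids)) return(ids)
  lo <- 0; hi <- max(d[ids, ids]) + 1e-9
  best <- NULL
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    sel <- sphere_exclusion(ids, d, radius = mid, seed = seed)
    if (length(sel) == n) return(as.character(sel))
    if (length(sel) > n) {
      lo <- mid
      best <- sel  # oversized: its prefix is still mutually separated
    } else {
      hi <- mid
    }
  }
  if (!is.null(best)) return(as.character(best[seq_len(n)]))
  as.character(sphere_exclusion(ids, d, radius = 0, n_target = n, seed = seed))
}

#' Per-cluster representative selection
#'
#' A cluster of size `n` receives `max(min_reps, round(n * reps_per_50 /
#' 50))` representatives, chosen by sphere exclusion (radius 0.5) within
#' the cluster. The default rate of 0.94 representatives per 50 compounds
#' gives 10 representatives for a 533-member cluster. Clusters smaller than
#' their quota contribute all members.
#'
#' @param clustering a `pharm_clustering`.
#' @param d distance matrix over the clustered compounds.
#' @param reps_per_50 representatives per 50 cluster members.
#' @param min_reps minimum per-cluster quota (default 4).
#' @param radius sphere-exclusion radius (default 0.5).
#' @param seed RNG seed.
#' @return named list (per cluster) of representative id vectors.
#' @export
representatives <- function(clustering, d, reps_per_50 = 0.94, min_reps = 4L,
                            radius = 0.5, seed = NULL) {
  if (!length(clustering$clusters)) stopf("clustering has no clusters")
  out <- list()
  for (i in seq_along(clustering$clusters)) {
    ids <- clustering$clusters[[i]]
    quota <- max(min_reps, round(length(ids) * reps_per_50 / 50))
    out[[names(clustering$clusters)[i]]] <-
      if (quota >= length(ids)) ids
      else as.character(sphere_exclusion(ids, d, radius = radius,
                                         n_target = quota,
                                         seed = if (is.null(seed)) NULL
                                                else seed + i))
  }
  out
}

#' Construct a paired test set
#'
#' @param actives,decoys,assumed_inactives compound-id vectors with equal
#'   lengths and no overlap.
#' @param scheme one of `random`, `diverse`, `populated`.
#' @return a `test_set_pair`.
#' @export
test_set_pair <- function(actives, decoys, assumed_inactives,
                          scheme = c("random", "diverse", "populated")) {
  scheme <- match.arg(scheme)
  actives <- as.character(actives)
  decoys <- as.character(decoys)
  assumed_inactives <- as.character(assumed_inactives)
  if (length(unique(c(length(actives), length(decoys),
                      length(assumed_inactives)))) != 1L) {
    stopf("test-set roles must have equal sizes (got %d/%d/%d)",
          length(actives), length(decoys), length(assumed_inactives))
  }
  all_ids <- c(actives, decoys, assumed_inactives)
  if (anyDuplicated(all_ids)) {
    stopf("a compound appears in two test-set roles")
  }
  structure(list(actives = actives, decoys = decoys,
                 assumed_inactives = assumed_inactives, scheme = scheme),
            class = "test_set_pair")
}

#' @export
print.test_set_pair <- function(x, ...) {
  cat(sprintf("<%s test-set pair: %d actives vs %d decoys / %d assumed inactives>\n",
              x$scheme, length(x$actives), length(x$decoys),
              length(x$assumed_inactives)))
  invisible(x)
}

# Largest-remainder apportionment of `n` among groups proportional to
# `sizes`; quotas never exceed the group sizes.
largest_remainder <- function(sizes, n) {
  raw <- n * sizes / sum(sizes)
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    frac <- raw - quota
    ord <- order(-frac, -sizes, names(sizes) %||% seq_along(sizes))
    take <- ord[seq_len(rem)]
    quota[take] <- quota[take] + 1
  }
  over <- quota > sizes
  while (any(over)) {          # push overflow to the fullest remaining groups
    excess <- sum(quota[over] - sizes[over])
    quota[over] <- sizes[over]
    room <- sizes - quota
    ord <- order(-room)
    for (i in ord) {
      if (excess == 0) break
      add <- min(excess, room[i])
      quota[i] <- quota[i] + add
      excess <- excess - add
    }
    over <- quota > sizes
  }
  quota
}

#' Assemble the three paired test-set schemes
#'
#' Builds one `test_set_pair` per scheme: `random` draws actives uniformly;
#' `diverse` takes the most diverse actives (sphere-exclusion/max-min over
#' the supplied distances); `populated` allocates per-cluster quotas
#' proportional to cluster sizes (largest-remainder rounding) and samples
#' within clusters. All three schemes share the same decoys (the most
#' diverse true inactives) and assumed inactives (the most diverse of the
#' assumed pool).
#'
#' @param actives_pool,decoys_pool,assumed_pool compound-id vectors (must
#'   be disjoint from each other and from any model-building
#'   representatives).
#' @param clustering a `pharm_clustering` used by the populated scheme.
#' @param d distance matrix covering all pools.
#' @param n_per_role compounds per role (default 200).
#' @param seed RNG seed.
#' @return named list of three `test_set_pair` objects.
#' @export
build_test_sets <- function(actives_pool, decoys_pool, assumed_pool,
                            clustering, d, n_per_role = 200L, seed = NULL) {
  pools <- list(actives = actives_pool, decoys = decoys_pool,
                assumed = assumed_pool)
  for (role in names(pools)) {
    if (length(pools[[role]]) < n_per_role) {
      stopf("%s pool has %d compounds; %d required", role,
            length(pools[[role]]), n_per_role)
    }
  }
  decoys <- if (length(decoys_pool) == n_per_role) as.character(decoys_pool)
            else most_diverse(decoys_pool, d, n_per_role, seed = seed)
  assumed <- if (length(assumed_pool) == n_per_role) as.character(assumed_pool)
             else most_diverse(assumed_pool, d, n_per_role, seed = seed)

  random_actives <- with_seed(seed, sample(as.character(actives_pool),
                                           n_per_role))
  diverse_actives <- if (length(actives_pool) == n_per_role)
    as.character(actives_pool)
  else most_diverse(actives_pool, d, n_per_role, seed = seed)

  in_pool <- lapply(clustering$clusters, intersect, y = actives_pool)
  in_pool <- in_pool[lengths(in_pool) > 0L]
  if (!length(in_pool)) stopf("no clustered actives available for the populated scheme")
  sizes <- lengths(clustering$clusters[names(in_pool)])
  avail <- lengths(in_pool)
  quota <- pmin(largest_remainder(sizes, n_per_role), avail)
  short <- n_per_role - sum(quota)
  if (short > 0) {  # clusters with spare members absorb the shortfall
    room <- avail - quota
    ord <- order(-room)
    for (i in ord) {
      if (short == 0) break
      add <- min(short, room[i])
      quota[i] <- quota[i] + add
      short <- short - add
    }
  }
  populated_actives <- with_seed(seed, unlist(
    lapply(seq_along(in_pool), function(i) {
      ids <- in_pool[[i]]
      if (quota[i] >= length(ids)) ids else sample(ids, quota[i])
    }), use.names = FALSE))

  list(
    random = test_set_pair(random_actives, decoys, assumed, "random"),
    diverse = test_set_pair(diverse_actives, decoys, assumed, "diverse"),
    populated = test_set_pair(populated_actives, decoys, assumed, "populated")
  )
}
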