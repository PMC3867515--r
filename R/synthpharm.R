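# Synthetic fixture generator: planted pharmacophore templates, active
# compounds obtained by jittering a template's feature points (plus
# spurious extra features), and inactive compounds guaranteed to violate
# every template. Every generated world is self-verified with the same
# match operation the pipeline uses.

# A random, well-spread template geometry: points in a box with a minimum
# pairwise separation so all inter-feature distances are chemically
# sensible (roughly 2.5-10 Angstroms).
.random_geometry <- function(k, box = 8, min_sep = 2.5) {
  repeat {
    xyz <- matrix(stats::runif(k * 3, 0, box), k, 3)
    if (k < 2L || min(stats::dist(xyz)) >= min_sep) return(xyz)
  }
}

# Distinct feature-type multisets across templates keep their fingerprints
# and match behavior well separated.
.template_types <- function(n_templates, k_range) {
  seen <- character(0L)
  out <- list()
  while (length(out) < n_templates) {
    k <- sample(k_range, 1L)
    types <- sort(sample(FEATURE_TYPES, k, replace = TRUE))
    key <- paste(types, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- sample(types)  # order within template free
  }
  out
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a planted pharmacophore world
#'
#' Plants `n_templates` pharmacophore templates (4-6 typed features with
#' distinct type multisets), then generates actives by jittering a
#' template's points with per-coordinate Gaussian noise plus `n_spurious`
#' extra features placed well away from the template, and inactives that
#' violate every template either by lacking a required feature type or by
#' a uniform distance distortion far beyond the tolerance. Each compound
#' is given a random rigid motion. The world is verified at generation
#' time: every active must match exactly its own template at the 2
#' Angstrom tolerance and no inactive may match any; failed draws are
#' retried with a fresh seed up to `max_retries` times.
#'
#' @param n_templates number of planted templates (default 3).
#' @param actives_per_template actives per template (default 10); a vector
#'   is recycled across templates, so skewed cluster sizes can be planted.
#' @param n_inactives total inactives (default twice the active count, so
#'   test-set roles can be filled with equal sizes).
#' @param noise_sigma per-coordinate jitter SD in Angstroms (default 0.2).
#' @param n_spurious spurious extra features per compound (default 1);
#'   spurious features persist across a compound's conformers and are
#'   placed so that no feature tuple containing one can superpose across
#'   compounds.
#' @param n_conformers conformers per compound (default 5), each an
#'   independently jittered copy of the parent geometry, mimicking a small
#'   conformational ensemble.
#' @param tolerance match tolerance used for verification (default 2).
#' @param template_k feature counts templates may take (default 4:6).
#' @param seed RNG seed; worlds are deterministic given a seed.
#' @param max_retries verification retries before giving up (default 10).
#' @return object of class `planted_world`: `templates` (list of
#'   `pharm_hypothesis`), `features` (a `feature_table`), `compounds`
#'   (data frame with `compound_id`, `label`, `template`, `ki_nM`),
#'   `memberships` (named id -> template map for actives), `seed`.
#' @export
generate_world <- function(n_templates = 3L, actives_per_template = 10L,
                           n_inactives = 2L * sum(rep_len(actives_per_template,
                                                          n_templates)),
                           noise_sigma = 0.2, n_spurious = 1L,
                           n_conformers = 5L, tolerance = 2,
                           template_k = 4:6, seed = 1L, max_retries = 10L) {
  stopifnot(n_templates >= 1L, all(actives_per_template >= 1L),
            n_inactives >= 0L,
            noise_sigma >= 0, n_spurious >= 0L, n_conformers >= 1L)
  actives_per_template <- rep_len(as.integer(actives_per_template),
                                  n_templates)
  for (attempt in seq_len(max_retries)) {
    world <- tryCatch(
      with_seed(seed + (attempt - 1L) * 100003L,
                .generate_world_once(n_templates, actives_per_template,
                                     n_inactives, noise_sigma,
                                     n_spurious, n_conformers,
                                     tolerance, template_k)),
      error = function(e) NULL)  # e.g. spurious placement ran out of room
    if (!is.null(world) && .verify_world(world, tolerance)) {
      world$seed <- seed
      class(world) <- "planted_world"
      return(world)
    }
  }
  stopf(paste("could not generate a verifiable world after %d attempts",
              "(n_templates=%d, noise_sigma=%.3g, n_spurious=%d)"),
        max_retries, n_templates, noise_sigma, n_spurious)
}

.generate_world_once <- function(n_templates, actives_per_template,
                                 n_inactives, noise_sigma, n_spurious,
                                 n_conformers, tolerance, template_k) {
  type_sets <- .template_types(n_templates, template_k)
  templates <- lapply(seq_len(n_templates), function(t) {
    k <- length(type_sets[[t]])
    new_hypothesis(sprintf("template_%d", t), type_sets[[t]],
                   .random_geometry(k), tolerance_rmsd = tolerance,
                   source_cluster = sprintf("planted_%d", t))
  })
  names(templates) <- vapply(templates, `[[`, character(1L), "hyp_id")

  rows <- list()
  compounds <- list()
  memberships <- character(0L)
  # emit one compound as a small ensemble of conformers; `conf_fn(j)` must
  # return list(ftypes, xyz) for conformer j
  emit <- function(id, conf_fn, label, template, ki) {
    for (j in seq_len(n_conformers)) {
      cf <- conf_fn(j)
      rot <- .random_rotation()
      xyz <- sweep(cf$xyz %*% rot, 2L, stats::runif(3, -20, 20), `+`)
      rows[[length(rows) + 1L]] <<- data.frame(
        compound_id = id, conformer = j, ftype = cf$ftypes,
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], stringsAsFactors = FALSE)
    }
    compounds[[length(compounds) + 1L]] <<- data.frame(
      compound_id = id, label = label, template = template, ki_nM = ki,
      stringsAsFactors = FALSE)
  }

  # Spurious features must be genuinely spurious: no feature tuple that
  # contains one may superpose onto another compound of the same template
  # pool. Distant points have a long lever arm -- a rigid fit can trade a
  # little template accuracy for a lot of spurious displacement -- so the
  # rejection test is the superposition itself: the full point set with
  # the new spurious feature must stay above 1.6x the match tolerance
  # against (i) the set with any previously planted same-type spurious
  # feature and (ii) the set with the spurious feature standing in for a
  # same-type template point.
  placed_spurious <- list()
  sample_spurious <- function(pool_key, base_xyz, tmpl_types) {
    center <- colMeans(base_xyz)
    guard <- 1.25 * tolerance
    for (try in 1:300) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- center + dir * stats::runif(1, 8, 13)
      ftype <- sample(FEATURE_TYPES, 1L)
      key <- paste(pool_key, ftype)
      prev <- placed_spurious[[key]]
      ok <- TRUE
      if (!is.null(prev)) {
        for (r in seq_len(nrow(prev))) {
          if (kabsch_rmsd(rbind(base_xyz, pos),
                          rbind(base_xyz, prev[r, ])) <= guard) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        for (j in which(tmpl_types == ftype)) {
          if (kabsch_rmsd(rbind(base_xyz[-j, , drop = FALSE], pos),
                          rbind(base_xyz[-j, , drop = FALSE],
                                base_xyz[j, ])) <= guard) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        placed_spurious[[key]] <<- rbind(prev, pos)
        return(list(ftype = ftype, pos = pos))
      }
    }
    stopf("could not place a spurious feature; world will be retried")
  }

  # A compound's spurious features persist across its conformers (they
  # stand for real substituents), so they are sampled once per compound
  # and jittered per conformer together with the template points.
  compound_geometry <- function(base_types, base_xyz, pool_key) {
    ftypes <- base_types
    xyz <- base_xyz
    for (s in seq_len(n_spurious)) {
      sp <- sample_spurious(pool_key, base_xyz, base_types)
      xyz <- rbind(xyz, sp$pos)
      ftypes <- c(ftypes, sp$ftype)
    }
    list(ftypes = ftypes, xyz = xyz)
  }

  jitter_conf <- function(geom) {
    n <- nrow(geom$xyz)
    list(ftypes = geom$ftypes,
         xyz = geom$xyz + matrix(stats::rnorm(n * 3, 0, noise_sigma), n, 3))
  }

  sizes <- rep_len(actives_per_template, n_templates)
  for (t in seq_len(n_templates)) {
    tmpl <- templates[[t]]
    for (a in seq_len(sizes[t])) {
      id <- sprintf("act_t%d_%03d", t, a)
      # log-uniform pseudo-Ki inside the active range (1-100 nM)
      ki <- 10^stats::runif(1, 0, 2)
      geom <- compound_geometry(tmpl$ftypes, tmpl$coords, tmpl$hyp_id)
      emit(id, function(j) jitter_conf(geom), "active", tmpl$hyp_id, ki)
      memberships[id] <- tmpl$hyp_id
    }
  }

  for (i in seq_len(n_inactives)) {
    id <- sprintf("inact_%03d", i)
    mode <- if (i %% 2L == 0L) "deficit" else "distort"
    base <- templates[[sample.int(n_templates, 1L)]]
    k <- nrow(base$coords)
    if (mode == "deficit") {
      # every conformer lacks one type the source template requires
      drop_type <- sample(unique(base$ftypes), 1L)
      allowed <- setdiff(FEATURE_TYPES, drop_type)
      ftypes <- sample(allowed, k, replace = TRUE)
      xyz0 <- .random_geometry(k)
    } else {
      # uniform expansion: all inter-feature distances grow ~2.5x, far
      # beyond what a 2 A RMSD can absorb
      ftypes <- base$ftypes
      xyz0 <- base$coords * 2.5
    }
    ki <- 10^stats::runif(1, log10(1500), 5)  # inactive range, > 1000 nM
    geom <- compound_geometry(ftypes, xyz0, id)
    emit(id, function(j) jitter_conf(geom), "inactive", NA_character_, ki)
  }

  list(templates = templates,
       features = validate_feature_table(do.call(rbind, rows)),
       compounds = do.call(rbind, compounds),
       memberships = memberships)
}

# Full verification: the hit matrix of all compounds against the planted
# templates must be exactly block-structured (actives hit their own
# template only; inactives hit nothing).
.verify_world <- function(world, tolerance) {
  by_comp <- split(world$features, world$features$compound_id)
  for (i in seq_len(nrow(world$compounds))) {
    id <- world$compounds$compound_id[i]
    own <- world$compounds$template[i]
    for (t in names(world$templates)) {
      hit <- match_hypothesis(world$templates[[t]], by_comp[[id]],
                              tolerance = tolerance)$match
      want <- !is.na(own) && own == t
      if (hit != want) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("<planted world: %d templates, %d actives, %d inactives (seed %s)>\n",
              length(x$templates), sum(x$compounds$label == "active"),
              sum(x$compounds$label == "inactive"), format(x$seed)))
  invisible(x)
}

#' Serialize a planted world to pipeline input files
#'
#' Writes the exact file formats the pipeline consumes: an activity CSV
#' (`activities.csv` with pseudo-Ki records the curation module can
#' process), the feature table (`features.csv`), and the ground-truth
#' clustering (`clustering.json`).
#'
#' @param world a `planted_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
world_to_inputs <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acts <- data.frame(
    compound_id = world$compounds$compound_id,
    smiles = "",
    measure = "Ki",
    value = world$compounds$ki_nM,
    units = "nM",
    species = "human",
    preparation = "cloned",
    stringsAsFactors = FALSE)
  utils::write.csv(acts, file.path(dir, "activities.csv"), row.names = FALSE)
  utils::write.csv(world$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  actives <- world$compounds[world$compounds$label == "active", , drop = FALSE]
  clusters <- split(actives$compound_id, actives$template)
  jsonlite::write_json(
    list(method = "planted", clusters = clusters,
         special_class = character(0L),
         templates = lapply(world$templates, hypothesis_to_list)),
    file.path(dir, "clustering.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read back serialized planted-world inputs
#'
#' Inverse of [world_to_inputs()] for the parts the pipeline consumes.
#'
#' @param dir directory written by [world_to_inputs()].
#' @return list with `activities` (data frame), `features`
#'   (`feature_table`), `clustering` (`pharm_clustering`) and `templates`
#'   (list of `pharm_hypothesis`).
#' @export
read_world_inputs <- function(dir) {
  activities <- utils::read.csv(file.path(dir, "activities.csv"),
                                stringsAsFactors = FALSE)
  features <- validate_feature_table(
    utils::read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE))
  cj <- jsonlite::read_json(file.path(dir, "clustering.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  clustering <- new_clustering(cj$method,
                               lapply(cj$clusters, as.character),
                               as.character(cj$special_class %||% character(0L)))
  templates <- lapply(cj$templates, hypothesis_from_list)
  names(templates) <- vapply(templates, `[[`, character(1L), "hyp_id")
  list(activities = activities, features = features,
       clustering = clustering, templates = templates)
}
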