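# Binary fingerprints: MOLPRINT-2D atom environments (M2D) and 3D
# pharmacophore feature triplets (P3D), compared by Soergel distance.

new_fingerprint <- function(kind, keys) {
  structure(list(kind = kind, keys = sort(unique(as.integer(keys)))),
            class = "pharm_fingerprint")
}

#' @export
print.pharm_fingerprint <- function(x, ...) {
  cat(sprintf("<%s fingerprint: %d keys>\n", x$kind, length(x$keys)))
  invisible(x)
}

#' MOLPRINT-2D atom-environment fingerprint
#'
#' Encodes, for every heavy atom, the multiset of (topological distance,
#' atom type) pairs within bond radius 2 as one hashed environment key; the
#' fingerprint is the set of those keys. Atom types are
#' `element.aromaticity.degree` triples (e.g. `C.ar.2`), a documented,
#' typer-free stand-in for substructure-key typing.
#'
#' @param mol a ChemmineR `SDF`/`SDFset` (first record used) or a
#'   pre-computed graph from the internal extractor.
#' @param id optional compound id used in error messages.
#' @return a `pharm_fingerprint` of kind `M2D`.
#' @examples
#' \dontrun{
#' fp <- molprint2d(read_structures(smiles = c(benzene = "c1ccccc1")))
#' length(fp$keys) # 1: all six aromatic CH environments are identical
#' }
#' @export
molprint2d <- function(mol, id = NULL) {
  g <- tryCatch(if (is.list(mol) && !is.null(mol$adj)) mol else mol_graph(mol),
                error = function(e) {
                  stopf("cannot parse structure%s: %s",
                        if (!is.null(id)) paste0(" ", id) else "",
                        conditionMessage(e))
                })
  n <- length(g$element)
  if (n == 0L) stopf("structure%s has no heavy atoms",
                     if (!is.null(id)) paste0(" ", id) else "")
  atype <- paste(g$element, ifelse(g$aromatic, "ar", "al"), g$degree,
                 sep = ".")
  # shells at topological distance 0, 1 and 2
  a1 <- g$adj
  a2 <- (a1 %*% a1) > 0
  keys <- character(n)
  for (i in seq_len(n)) {
    d1 <- which(a1[i, ])
    d2 <- setdiff(which(a2[i, ]), c(i, d1))
    env <- c(paste0("0:", atype[i]),
             if (length(d1)) paste0("1:", sort(atype[d1])),
             if (length(d2)) paste0("2:", sort(atype[d2])))
    keys[i] <- paste(env, collapse = "|")
  }
  new_fingerprint("M2D", str_hash(keys))
}

#' 3D pharmacophore triplet fingerprint
#'
#' Enumerates all triplets of typed feature points; each triplet is keyed by
#' its sorted type triple together with its sorted inter-feature distance
#' bins (1 Angstrom bins on \[0, 15\]; longer distances clamp into the top
#' bin). The fingerprint is the set of hashed triplet keys.
#'
#' For multi-conformer input (a `conformer` column with several values)
#' triplets are enumerated within each conformer and the fingerprint is
#' the union of the per-conformer key sets, so the conformational ensemble
#' smooths out the hard bin edges.
#'
#' @param points data frame of feature points with columns `ftype` (one of
#'   A, D, H, P, R) and `x`, `y`, `z` in Angstroms; an optional `conformer`
#'   column groups points into conformers.
#' @param bin_width bin width in Angstroms (default 1).
#' @param max_dist clamp distance (default 15).
#' @return a `pharm_fingerprint` of kind `P3D` (empty, with a warning, for
#'   fewer than 3 feature points).
#' @export
pharm3d_fp <- function(points, bin_width = 1, max_dist = 15) {
  if (!is.null(points$conformer) && length(unique(points$conformer)) > 1L) {
    keys <- unlist(lapply(split(points, points$conformer), function(p)
      suppressWarnings(pharm3d_fp(p, bin_width, max_dist))$keys))
    return(new_fingerprint("P3D", keys))
  }
  n <- nrow(points)
  if (is.null(n) || n < 3L) {
    warnf("fewer than 3 feature points; returning an empty P3D fingerprint")
    return(new_fingerprint("P3D", integer(0L)))
  }
  xyz <- as.matrix(points[, c("x", "y", "z")])
  types <- as.character(points$ftype)
  d <- as.matrix(stats::dist(xyz))
  top <- as.integer(max_dist / bin_width)
  trip <- utils::combn(n, 3L)
  keys <- apply(trip, 2L, function(idx) {
    dd <- c(d[idx[1L], idx[2L]], d[idx[1L], idx[3L]], d[idx[2L], idx[3L]])
    bins <- pmin(floor(dd / bin_width), top)
    paste(paste(sort(types[idx]), collapse = ""),
          paste(sort(bins), collapse = ","), sep = "|")
  })
  new_fingerprint("P3D", str_hash(keys))
}

#' Soergel distance between binary fingerprints
#'
#' The Soergel distance is one minus the Tanimoto similarity of the key
#' sets: `1 - |a intersect b| / |a union b|`, and 0 when both sets are
#' empty.
#'
#' @param a,b `pharm_fingerprint` objects of the same kind.
#' @return distance in \[0, 1\].
#' @export
soergel <- function(a, b) {
  if (!inherits(a, "pharm_fingerprint") || !inherits(b, "pharm_fingerprint")) {
    stopf("soergel() expects two fingerprints")
  }
  if (a$kind != b$kind) stopf("fingerprint kinds differ: %s vs %s",
                              a$kind, b$kind)
  u <- length(union(a$keys, b$keys))
  if (u == 0L) return(0)
  1 - length(intersect(a$keys, b$keys)) / u
}

#' Pairwise Soergel distance matrix
#'
#' @param fps named list of fingerprints of one kind.
#' @return symmetric matrix with the fingerprint names as dimnames.
#' @export
soergel_matrix <- function(fps) {
  n <- length(fps)
  ids <- names(fps) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- soergel(fps[[i]], fps[[j]])
    }
  }
  d
}
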