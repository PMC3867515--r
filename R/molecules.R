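# Light molecular-graph view over ChemmineR SDF objects. ChemmineR does the
# parsing and ring/aromaticity perception; here we only assemble the atom
# table the fingerprint and feature-perception code consumes.

.need_chemminer <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stopf("structure handling requires the ChemmineR package")
  }
}

#' Read compound structures
#'
#' SMILES are converted through Open Babel with explicit hydrogens added
#' (hydrogen-free records trip up SDF parsing and hydrogens are needed for
#' donor perception anyway) and 2D or 3D coordinates generated.
#'
#' @param smiles named character vector of SMILES (names are compound ids),
#'   or `NULL`.
#' @param sdf_file path to a (multi-record, uncompressed) SD file, or `NULL`.
#'   Exactly one of the two must be given.
#' @param coords coordinate generation for SMILES input: `"2D"` (default)
#'   or `"3D"`.
#' @return a `ChemmineR::SDFset` with compound ids as CMP ids.
#' @export
read_structures <- function(smiles = NULL, sdf_file = NULL,
                            coords = c("2D", "3D")) {
  .need_chemminer()
  coords <- match.arg(coords)
  if (is.null(smiles) == is.null(sdf_file)) {
    stopf("supply exactly one of `smiles` or `sdf_file`")
  }
  if (!is.null(smiles)) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      stopf("SMILES input requires the ChemmineOB package")
    }
    ids <- names(smiles) %||% paste0("CMP", seq_along(smiles))
    txt <- ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, " ", ids, "\n", collapse = ""),
      options = data.frame(names = c("h", paste0("gen", coords)),
                           args = c("", "")))
    sdf <- ChemmineR::read.SDFset(unlist(strsplit(txt, "\n", fixed = TRUE)))
    ChemmineR::cid(sdf) <- ids
  } else {
    sdf <- ChemmineR::read.SDFset(sdf_file)
    ChemmineR::cid(sdf) <- ChemmineR::makeUnique(ChemmineR::sdfid(sdf))
  }
  sdf
}

# V2000 old-style charge codes -> formal charges.
.charge_code <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                  `5` = -1, `6` = -2, `7` = -3)

# Atom/bond tables for a single SDF record: element, coordinates, formal
# charge, aromaticity (ring perception via ChemmineR), heavy-atom degree and
# an implicit-hydrogen estimate from standard valences.
mol_graph <- function(sdf) {
  .need_chemminer()
  if (inherits(sdf, "SDFset")) sdf <- sdf[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n_all <- nrow(ab)
  element_all <- gsub("_.*$", "", rownames(ab))
  if (ncol(ab) < 3L) stopf("malformed atom block")
  xyz_all <- unname(ab[, 1:3, drop = FALSE])
  # old-style V2000 charge field (as written by Open Babel)
  charge_all <- rep(0, n_all)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    ok <- code %in% names(.charge_code)
    charge_all[ok] <- .charge_code[code[ok]]
  }
  adj_all <- matrix(FALSE, n_all, n_all)
  order_all <- matrix(0, n_all, n_all)
  if (!is.null(bb) && nrow(bb) > 0L) {
    for (r in seq_len(nrow(bb))) {
      i <- bb[r, 1L]; j <- bb[r, 2L]; o <- bb[r, 3L]
      adj_all[i, j] <- adj_all[j, i] <- TRUE
      order_all[i, j] <- order_all[j, i] <- o
    }
  }
  aromatic_all <- rep(FALSE, n_all)
  ring_ids_all <- list()
  rn <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(rn) && length(rn$RINGS)) {
    for (k in seq_along(rn$RINGS)) {
      idx <- as.integer(gsub("^.*_", "", rn$RINGS[[k]]))
      if (isTRUE(rn$AROMATIC[[k]])) {
        aromatic_all[idx] <- TRUE
        ring_ids_all[[length(ring_ids_all) + 1L]] <- idx
      }
    }
  }
  # drop explicit hydrogens; remember how many sat on each heavy atom
  heavy <- which(element_all != "H")
  explicit_h <- vapply(heavy, function(i) {
    sum(element_all[adj_all[i, ]] == "H")
  }, numeric(1L))
  remap <- match(seq_len(n_all), heavy)
  n <- length(heavy)
  element <- element_all[heavy]
  xyz <- xyz_all[heavy, , drop = FALSE]
  charge <- charge_all[heavy]
  adj <- adj_all[heavy, heavy, drop = FALSE]
  order <- order_all[heavy, heavy, drop = FALSE]
  aromatic <- aromatic_all[heavy]
  ring_ids <- lapply(ring_ids_all, function(idx) remap[idx][!is.na(remap[idx])])
  degree <- rowSums(adj)
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1)
  std <- valence[element]
  std[is.na(std)] <- (rowSums(order) + explicit_h)[is.na(std)]
  # protonated N gains a bond slot; deprotonated O loses one
  eff <- std + ifelse(element %in% c("N", "O"), charge, 0)
  implicit_h <- pmax(explicit_h, eff - rowSums(order))
  list(element = element, xyz = xyz, charge = charge, adj = adj,
       order = order, aromatic = aromatic, aromatic_rings = ring_ids,
       degree = degree, implicit_h = implicit_h)
}
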