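# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: the enumerators below
# compute scores from first principles so they can certify the optimized
# implementations.

# Brute-force search for the best k-subset of hit-matrix columns. Own
# confusion counting and own metric formulas; returns score and winning
# id set (ties: lexicographically smallest sorted tuple).
naive_best_combination <- function(hm, actives, decoys, assumed, metric,
                                   mode, k) {
  score_set <- function(ids, inactives) {
    rows <- hm[c(actives, inactives), ids, drop = FALSE]
    nhits <- apply(rows, 1L, sum)
    pred_active <- if (mode == "hit_once") nhits >= 1 else nhits >= 2
    truth <- c(rep(TRUE, length(actives)), rep(FALSE, length(inactives)))
    tp <- sum(pred_active & truth); fp <- sum(pred_active & !truth)
    fn <- sum(!pred_active & truth); tn <- sum(!pred_active & !truth)
    if (metric == "recall") return(tp / (tp + fn))
    if (metric == "accuracy") return((tp + tn) / (tp + fp + tn + fn))
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  }
  best_score <- -Inf
  best_ids <- NULL
  for (combo in utils::combn(sort(colnames(hm)), k, simplify = FALSE)) {
    s <- (score_set(combo, decoys) + score_set(combo, assumed)) / 2
    key <- paste(sort(combo), collapse = "\r")
    if (s > best_score + 1e-12 ||
        (abs(s - best_score) <= 1e-12 &&
         key < paste(sort(best_ids), collapse = "\r"))) {
      best_score <- s
      best_ids <- sort(combo)
    }
  }
  list(score = best_score, ids = best_ids)
}

# Brute-force Kelley penalty: recompute spreads and the normalized
# penalty for every cut level directly from cutree memberships.
naive_kelley <- function(hc, d) {
  n <- nrow(d)
  ks <- seq_len(n - 1L)
  spread <- sapply(ks, function(k) {
    memb <- stats::cutree(hc, k)
    vals <- c()
    for (cl in unique(memb)) {
      idx <- which(memb == cl)
      if (length(idx) < 2L) next
      pairs <- utils::combn(idx, 2L)
      vals <- c(vals, mean(d[cbind(pairs[1L, ], pairs[2L, ])]))
    }
    mean(vals)
  })
  if (max(spread) - min(spread) < 1e-12) return(1L)
  norm <- 1 + (n - 2) * (spread - min(spread)) / (max(spread) - min(spread))
  ks[which.min(norm + ks)]
}

# Planted blob distance matrix: K well-separated clusters with noisy
# small within distances and large between distances.
blob_distances <- function(K, size = 6L, intra = 0.1, inter = 0.8,
                           noise = 0.03, seed = 1L) {
  n <- K * size
  memb <- rep(seq_len(K), each = size)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      base <- if (memb[i] == memb[j]) intra else inter
      d[i, j] <- d[j, i] <- base
    }
  }
  set.seed(seed)
  eps <- matrix(stats::runif(n * n, 0, noise), n, n)
  eps <- (eps + t(eps)) / 2
  diag(eps) <- 0
  d <- d + eps
  dimnames(d) <- list(sprintf("c%d_i%02d", memb, seq_len(n)),
                      sprintf("c%d_i%02d", memb, seq_len(n)))
  attr(d, "membership") <- memb
  d
}

# Random hit matrix with ids; densities drawn per column.
random_hit_matrix <- function(n_compounds, n_hyps, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_compounds * n_hyps) <
                rep(stats::runif(n_hyps, 0.2, 0.7), each = n_compounds),
              n_compounds, n_hyps,
              dimnames = list(sprintf("cmp%02d", seq_len(n_compounds)),
                              sprintf("hyp%02d", seq_len(n_hyps))))
  m
}

# Equal-role test pair over the rows of a hit matrix (first third actives,
# then decoys, then assumed inactives).
pair_from_rows <- function(hm) {
  ids <- rownames(hm)
  n <- length(ids) %/% 3L
  test_set_pair(ids[1:n], ids[(n + 1):(2 * n)], ids[(2 * n + 1):(3 * n)])
}

# Exhaustive assignment matcher used as the oracle for match_hypothesis:
# tries every type-consistent injective assignment and superposes with an
# independently written quaternion-free rotation fit (Horn's closed form
# via eigen decomposition).
oracle_min_rmsd <- function(ftypes, ref_xyz, pts_types, pts_xyz) {
  k <- length(ftypes)
  cand <- lapply(ftypes, function(tt) which(pts_types == tt))
  if (any(lengths(cand) == 0L)) return(Inf)
  best <- Inf
  assigns <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(assigns))) {
    a <- as.integer(assigns[r, ])
    if (anyDuplicated(a)) next
    best <- min(best, horn_rmsd(ref_xyz, pts_xyz[a, , drop = FALSE]))
  }
  best
}

# Horn (1987) absolute-orientation RMSD via the 4x4 quaternion matrix.
horn_rmsd <- function(P, Q) {
  P <- sweep(P, 2L, colMeans(P))
  Q <- sweep(Q, 2L, colMeans(Q))
  M <- crossprod(Q, P)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4L, 4L, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e <- sum(P^2) + sum(Q^2) - 2 * lambda
  sqrt(max(0, e) / nrow(P))
}

# Random rigid motion applied to a feature table's coordinates.
rigid_transform <- function(ft, seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3L, 3L, byrow = TRUE)
  xyz <- as.matrix(ft[, c("x", "y", "z")]) %*% rot
  xyz <- sweep(xyz, 2L, stats::runif(3, -5, 5), `+`)
  ft$x <- xyz[, 1L]; ft$y <- xyz[, 2L]; ft$z <- xyz[, 3L]
  ft
}

# Feature table from a type vector and coordinate matrix.
ft_from_points <- function(id, ftypes, xyz, conformer = 1L) {
  feature_table(id, conformer, ftypes, xyz[, 1L], xyz[, 2L], xyz[, 3L])
}
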