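# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. A NULL seed leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic polynomial string hash onto [0, 2^31 - 2]; used to turn
# canonical environment/triplet strings into integer fingerprint keys.
# All intermediates stay below 2^53 so the arithmetic is exact in doubles.
str_hash <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) {
      h <- (h * 131 + b) %% m
    }
    as.integer(h)
  }, integer(1L), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Validate a square symmetric distance-like matrix with a zero diagonal.
check_distance_matrix <- function(d, what = "distance matrix") {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stopf("%s must be a square matrix", what)
  }
  if (any(d < 0)) stopf("%s has negative entries", what)
  if (any(abs(diag(d)) > 1e-12)) stopf("%s has a non-zero diagonal", what)
  if (any(abs(d - t(d)) > 1e-8)) stopf("%s is not symmetric", what)
  invisible(d)
}
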