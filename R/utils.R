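# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library calls never disturb user randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stage seed from a root seed; keeps results below 2^31 and makes
# stage-level reruns reproducible independently of other stages.
deriveSeed <- function(root, stage) {
  (as.double(root) * 48271 + 99991 * as.double(stage)) %% 2147483629
}

# Squared Euclidean distances between the rows of A (n x 3) and B (m x 3).
pairwiseDist2 <- function(A, B) {
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) +
    matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE) -
    2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

rowNorms <- function(m) sqrt(rowSums(m^2))

# Normalise rows to unit length; zero rows are left untouched.
normalizeRows <- function(m, eps = 1e-300) {
  len <- rowNorms(m)
  len[len < eps] <- 1
  m / len
}

crossProduct <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# Polynomial rolling hash of a character vector, hex string. Used for run
# manifests and content-addressed stage caching (not cryptographic).
contentHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h1 <- 17
  h2 <- 5381
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
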