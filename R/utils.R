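# Internal helpers shared across modules: seeded evaluation, permutation
# enumeration, and distance-matrix plumbing.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` means "use the current
# stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable per-stage seed derived from a master seed and a stage name, so adding
# a stage to a pipeline never perturbs the streams of the others. Plain
# polynomial hash of the name folded into [0, 2^31 - 2].
stage_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((as.numeric(master) + h) %% 2147483647)
}

# All n! permutations of 1:n as an (n! x n) matrix. Only used for exhaustive
# permutation tests, which are capped at n! <= 5040 (n <= 7).
all_permutations <- function(n) {
  stopifnot(n >= 1L, factorial(n) <= 5040)
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

# Coerce a dist or labelled square symmetric matrix to a square matrix with
# dimnames, validating symmetry and a zero diagonal.
as_square_dissimilarity <- function(d, arg = "d") {
  if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else if (is.matrix(d)) {
    m <- d
  } else {
    stop(sprintf("`%s` must be a dist object or a square matrix", arg),
         call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("`%s` is not square", arg), call. = FALSE)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  if (max(abs(m - t(m))) > 1e-12) {
    stop(sprintf("`%s` is not symmetric (tolerance 1e-12)", arg),
         call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-12)) {
    stop(sprintf("`%s` has a non-zero diagonal", arg), call. = FALSE)
  }
  diag(m) <- 0
  m
}

# Lower-triangle vector of a square dissimilarity matrix, pair order fixed
# by column-major lower triangle.
lower_triangle <- function(m) {
  m[lower.tri(m)]
}

# Row/column index pairs matching lower_triangle() order.
lower_triangle_index <- function(n) {
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
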