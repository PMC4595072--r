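# Cross-method comparison of beta-diversity structure: Mantel tests, the
# method correlation matrix, second-stage MDS, distance-decay regression,
# and within/between-plot turnover.

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements of two labelled distance
#' matrices over the same objects, with a one-tailed (greater) permutation
#' test obtained by jointly permuting rows and columns of the second matrix.
#' `p = (1 + #\{r* >= r\}) / (n_perm + 1)`, so p never drops below
#' `1/(n_perm + 1)`. When the number of objects is small enough that
#' `n! <= 5040` (n <= 7) the test is exact by default: all relabelings are
#' enumerated and `p` is the exact tail probability (the identity
#' permutation included).
#'
#' @param d1,d2 `dist` objects or labelled square symmetric matrices over
#'   the same labels (`d2` is re-ordered to `d1`'s labels if needed).
#' @param n_perm number of random permutations when not exhaustive.
#' @param seed RNG seed for the permutations.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) enumeration;
#'   `NULL` enables it automatically when `n! <= 5040`.
#' @return object of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `exhaustive`, `tail` (always `"greater"`), `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 4999, seed = NULL,
                        exhaustive = NULL) {
  m1 <- as_square_dissimilarity(d1, "d1")
  m2 <- as_square_dissimilarity(d2, "d2")
  n <- nrow(m1)
  if (n < 4L) {
    stop("Mantel test needs at least 4 objects", call. = FALSE)
  }
  if (!setequal(rownames(m1), rownames(m2))) {
    stop("`d1` and `d2` have different labels", call. = FALSE)
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  x <- lower_triangle(m1)
  y <- lower_triangle(m2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance off-diagonal vector", call. = FALSE)
  }
  r <- stats::cor(x, y)

  idx <- lower_triangle_index(n)
  xc <- x - mean(x)
  denom <- sqrt(sum(xc^2) * sum((y - mean(y))^2))
  perm_r <- function(p) {
    yp <- m2[cbind(p[idx$i], p[idx$j])]
    sum(xc * yp) / denom
  }

  if (is.null(exhaustive)) {
    exhaustive <- factorial(n) <= 5040
  }
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, perm_r)
    p <- mean(rs >= r - 1e-12)
    n_used <- nrow(perms)
  } else {
    rs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) perm_r(sample.int(n)), numeric(1))
    })
    p <- (1 + sum(rs >= r - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(r = r, p = p, n_perm = n_used, exhaustive = exhaustive,
         tail = "greater", n = n),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%s, %d %s, one-tailed greater)\n",
              x$r, x$p, if (x$exhaustive) "exact" else "Monte Carlo",
              x$n_perm, if (x$exhaustive) "relabelings" else "permutations"))
  invisible(x)
}

#' Method correlation matrix (pairwise Mantel tests)
#'
#' Computes the Mantel correlation of pairwise beta-diversity structure
#' between every pair of methods (eDNA markers and traditional surveys),
#' after restricting all distance matrices to their common plots. The
#' resulting correlation matrix is the input to [second_stage_mds()].
#'
#' @param dmats named list of `dist` objects (or labelled square matrices),
#'   one per method, typically plot-level turnover matrices.
#' @param n_perm,seed permutation settings passed to [mantel_test()]; each
#'   pair receives a distinct seed derived from `seed` so results do not
#'   depend on evaluation order.
#' @return object of class `method_correlation`: matrices `r` and `p`, the
#'   common `labels`, and a long-format data frame `pairs`
#'   (method1, method2, r, p).
#' @export
method_correlation_matrix <- function(dmats, n_perm = 4999, seed = NULL) {
  if (length(dmats) < 2L) {
    stop("need at least 2 methods", call. = FALSE)
  }
  if (is.null(names(dmats)) || anyDuplicated(names(dmats))) {
    stop("`dmats` must have unique names", call. = FALSE)
  }
  mats <- lapply(names(dmats), function(nm)
    as_square_dissimilarity(dmats[[nm]], nm))
  names(mats) <- names(dmats)
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) < 4L) {
    stop("fewer than 4 plots common to all methods", call. = FALSE)
  }
  mats <- lapply(mats, function(m) m[common, common])
  k <- length(mats)
  r <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(names(mats), names(mats))
  rows <- list()
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      pair_seed <- if (is.null(seed)) NULL else
        stage_seed(seed, paste(names(mats)[c(a, b)], collapse = "|"))
      mt <- mantel_test(mats[[a]], mats[[b]], n_perm = n_perm,
                        seed = pair_seed)
      r[a, b] <- r[b, a] <- mt$r
      p[a, b] <- p[b, a] <- mt$p
      rows[[length(rows) + 1L]] <- data.frame(
        method1 = names(mats)[a], method2 = names(mats)[b],
        r = mt$r, p = mt$p)
    }
  }
  structure(
    list(r = r, p = p, labels = common, pairs = do.call(rbind, rows),
         n_perm = n_perm),
    class = "method_correlation"
  )
}

#' @export
print.method_correlation <- function(x, ...) {
  cat(sprintf("Method correlation matrix (%d methods, %d common plots)\n",
              nrow(x$r), length(x$labels)))
  print(round(x$r, 3))
  invisible(x)
}

#' Second-stage MDS of method correlations
#'
#' Ordains the methods themselves: the Mantel correlation matrix is turned
#' into dissimilarities `1 - r` and passed to non-metric MDS, so methods
#' whose pairwise beta diversities co-vary across plots plot close together.
#'
#' @param corr a [method_correlation_matrix()] result, or a symmetric
#'   correlation matrix with unit diagonal.
#' @param dims number of ordination dimensions.
#' @param n_starts,seed passed to [nmds()].
#' @return an `ordination` object (see [nmds()]) over the methods.
#' @export
second_stage_mds <- function(corr, dims = 2, n_starts = 20, seed = NULL) {
  r <- if (inherits(corr, "method_correlation")) corr$r else corr
  if (!is.matrix(r) || nrow(r) != ncol(r) ||
      max(abs(r - t(r))) > 1e-12) {
    stop("`corr` must be a symmetric correlation matrix", call. = FALSE)
  }
  delta <- pmax(1 - r, 0)
  diag(delta) <- 0
  nmds(stats::as.dist(delta), dims = dims, n_starts = n_starts, seed = seed)
}

#' Distance-decay regression of beta diversity on elevation difference
#'
#' Ordinary least squares of pairwise beta-diversity dissimilarity on the
#' absolute elevation difference of the plot pair, over all unordered pairs.
#' A positive slope is the classic distance-decay signature: compositional
#' similarity declines with increasing elevational separation.
#'
#' @param beta a `dist` or labelled square matrix of pairwise dissimilarity
#'   (typically turnover of order 1).
#' @param elevations named numeric vector of plot elevations (meters)
#'   covering all labels of `beta`.
#' @return object of class `decay_regression`: `slope`, `intercept`, `r`
#'   (signed Pearson correlation), `r_squared`, `p` (F-test), `n_pairs`, and
#'   the fitted `model`.
#' @export
distance_decay_regression <- function(beta, elevations) {
  m <- as_square_dissimilarity(beta, "beta")
  labels <- rownames(m)
  if (!all(labels %in% names(elevations))) {
    stop(sprintf("missing elevation for plot(s): %s",
                 paste(setdiff(labels, names(elevations)), collapse = ", ")),
         call. = FALSE)
  }
  e <- as.numeric(elevations[labels])
  if (stats::sd(e) == 0) {
    stop("all elevations are equal (constant predictor)", call. = FALSE)
  }
  dd <- abs(outer(e, e, "-"))
  x <- lower_triangle(dd)
  y <- lower_triangle(m)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r = stats::cor(x, y), r_squared = sm$r.squared, p = p,
         n_pairs = length(x), model = fit),
    class = "decay_regression"
  )
}

#' @export
print.decay_regression <- function(x, ...) {
  cat(sprintf(
    "Distance decay: slope %.3g per m, r = %.3f, R^2 = %.3f, p = %.3g (%d pairs)\n",
    x$slope, x$r, x$r_squared, x$p, x$n_pairs))
  invisible(x)
}

#' Within- versus between-plot turnover
#'
#' Splits all pairwise subplot turnover values by whether the two subplots
#' belong to the same plot. With real plot structure, average within-plot
#' turnover is lower than between plots.
#'
#' @param cm a subplot-level [community_matrix()] with at least two subplots
#'   in at least two plots.
#' @param q diversity order for the turnover.
#' @return object of class `turnover_split`: numeric vectors `within` and
#'   `between`, their means, and the marker label.
#' @export
within_between_turnover <- function(cm, q = 1) {
  stopifnot(inherits(cm, "community_matrix"))
  turn <- as.matrix(pairwise_turnover_matrix(cm, q))
  plots <- cm$plots[rownames(turn)]
  idx <- lower_triangle_index(nrow(turn))
  vals <- turn[cbind(idx$i, idx$j)]
  same <- plots[idx$i] == plots[idx$j]
  if (!any(same)) {
    stop("no within-plot subplot pairs", call. = FALSE)
  }
  structure(
    list(within = vals[same], between = vals[!same],
         mean_within = mean(vals[same]), mean_between = mean(vals[!same]),
         q = q, marker = cm$marker),
    class = "turnover_split"
  )
}

#' @export
print.turnover_split <- function(x, ...) {
  cat(sprintf(
    "Turnover [%s], q = %g: within-plot mean %.3f (%d pairs), between-plot mean %.3f (%d pairs)\n",
    x$marker, x$q, x$mean_within, length(x$within), x$mean_between,
    length(x$between)))
  invisible(x)
}
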