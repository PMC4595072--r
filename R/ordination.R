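# Community distance measures, unconstrained ordination (NMDS, PCoA), and
# Procrustes/PROTEST comparison of ordinations.

#' Community dissimilarity matrix
#'
#' Computes a pairwise dissimilarity matrix over the samples of a community
#' matrix.
#'
#' * `"jaccard"`: `1 - |A intersect B| / |A union B|` on presence/absence
#'   (the classic index; set `quantitative = TRUE` for the abundance-based
#'   Ruzicka generalisation).
#' * `"horn-morisita"`: `1 - 2 * sum(x*y) / ((sum(x^2)/X^2 + sum(y^2)/Y^2) * X * Y)`
#'   with `X`, `Y` the row totals; abundance-based and insensitive to
#'   sampling depth.
#' * `"turnover"`: normalised pairwise effective beta diversity of order
#'   `q` (see [pairwise_turnover_matrix()]).
#'
#' Jaccard and Horn-Morisita are delegated to [vegan::vegdist()].
#'
#' @param cm a [community_matrix()] or counts matrix (samples in rows).
#' @param metric one of `"jaccard"`, `"horn-morisita"`, `"turnover"`.
#' @param q diversity order for `metric = "turnover"`.
#' @param quantitative use abundances rather than presence/absence for
#'   Jaccard.
#' @return a `dist` object with attribute `metric`.
#' @export
community_distance <- function(cm, metric = c("jaccard", "horn-morisita",
                                              "turnover"),
                               q = 1, quantitative = FALSE) {
  metric <- match.arg(metric)
  counts <- if (inherits(cm, "community_matrix")) cm$counts else cm
  if (nrow(counts) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  if (any(rowSums(counts) == 0)) {
    stop("empty sample(s)", call. = FALSE)
  }
  d <- switch(metric,
    "jaccard" = vegan::vegdist(counts, method = "jaccard",
                               binary = !quantitative),
    "horn-morisita" = vegan::vegdist(counts, method = "horn"),
    "turnover" = pairwise_turnover_matrix(cm, q = q)
  )
  attr(d, "metric") <- if (metric == "turnover")
    sprintf("turnover-q%g", q) else metric
  d
}

make_ordination <- function(points, labels, method, stress = NULL,
                            eigenvalues = NULL, negative_inertia = 0,
                            converged = NA, seed = NULL) {
  points <- as.matrix(points)
  points <- sweep(points, 2L, colMeans(points))  # centered coordinates
  rownames(points) <- labels
  colnames(points) <- paste0("axis", seq_len(ncol(points)))
  structure(
    list(points = points, stress = stress, eigenvalues = eigenvalues,
         negative_inertia = negative_inertia, converged = converged,
         method = method, seed = seed),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d points, %d dims", toupper(x$method),
              nrow(x$points), ncol(x$points)))
  if (!is.null(x$stress)) {
    cat(sprintf(", stress %.4f (converged: %s)", x$stress, x$converged))
  }
  if (!is.null(x$eigenvalues)) {
    cat(sprintf(", positive inertia %.4g (negative %.4g)",
                sum(x$eigenvalues), x$negative_inertia))
  }
  cat("\n")
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Wraps [vegan::metaMDS()] (global monotone-regression NMDS minimising
#' stress-1) with multiple random starts, no community transformations, and
#' a fixed seed, returning centered coordinates rotated to principal axes.
#' Stress is on the 0-1 scale; values below 0.2 are conventionally usable,
#' below 0.1 good.
#'
#' @param d a `dist` object or labelled square dissimilarity matrix.
#' @param dims number of dimensions (must be `< n`).
#' @param n_starts random starts; the best (lowest-stress) solution is kept.
#' @param max_iter iteration cap per start.
#' @param seed RNG seed; the same seed and input give identical coordinates.
#' @return an `ordination` object with `stress` and a `converged` flag
#'   (non-convergence is flagged, not fatal).
#' @export
nmds <- function(d, dims = 2, n_starts = 20, max_iter = 500, seed = NULL) {
  m <- as_square_dissimilarity(d, "d")
  n <- nrow(m)
  if (n < dims + 1L) {
    stop("need at least dims + 1 points", call. = FALSE)
  }
  dd <- stats::as.dist(m)
  fit <- with_seed(seed, suppressWarnings(
    vegan::metaMDS(dd, k = dims, try = n_starts, trymax = n_starts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE, expand = FALSE)
  ))
  make_ordination(fit$points, labels = rownames(m), method = "nmds",
                  stress = fit$stress,
                  converged = isTRUE(fit$converged > 0) ||
                    fit$stress < 1e-6,
                  seed = seed)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared dissimilarity matrix is
#' double-centered (Gower transformation) and eigendecomposed; axes are
#' scaled by the square root of their eigenvalues. Axes with negative
#' eigenvalues (which arise for non-Euclidean dissimilarities such as
#' Jaccard) are dropped and their total magnitude reported as
#' `negative_inertia`; no Lingoes/Cailliez correction is applied.
#'
#' @param d a `dist` object or labelled square dissimilarity matrix.
#' @return an `ordination` object with `eigenvalues` (positive, descending)
#'   and `negative_inertia`.
#' @export
pcoa <- function(d) {
  m <- as_square_dissimilarity(d, "d")
  n <- nrow(m)
  if (n < 2L) {
    stop("need at least 2 points", call. = FALSE)
  }
  if (all(m == 0)) {
    stop("all-zero distance matrix", call. = FALSE)
  }
  # Gower double-centering: G = (I - 11'/n) (-d^2/2) (I - 11'/n). Sweeping
  # row means first and then the column means of the swept matrix applies
  # the "+ grand mean" term implicitly.
  G <- -0.5 * m^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values))
  pos <- eig$values > tol
  neg <- eig$values < -tol
  points <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  make_ordination(points, labels = rownames(m), method = "pcoa",
                  eigenvalues = eig$values[pos],
                  negative_inertia = sum(abs(eig$values[neg])))
}

# Center a configuration and scale to unit sum of squares.
normalise_configuration <- function(x) {
  x <- sweep(as.matrix(x), 2L, colMeans(x))
  ss <- sum(x^2)
  if (ss == 0) {
    stop("degenerate (all-coincident) configuration", call. = FALSE)
  }
  x / sqrt(ss)
}

#' Procrustes comparison of two ordinations (PROTEST)
#'
#' Superimposes two ordinations of the same objects by translation, uniform
#' scaling and rigid rotation/reflection, and measures the residual
#' disagreement by the symmetric Procrustes statistic
#' `m12^2 = 1 - (sum of singular values of X'Y)^2` with both configurations
#' centered and scaled to unit sum of squares. Significance of the
#' concordance statistic `r = sqrt(1 - m12^2)` is assessed by permuting the
#' row labels of the second configuration (exact enumeration when
#' `n! <= 5040`, Monte Carlo otherwise, with the usual `1/(n_perm + 1)`
#' floor).
#'
#' @param x,y `ordination` objects or coordinate matrices with matching row
#'   labels and equal dimension.
#' @param n_perm number of permutations (Monte Carlo mode).
#' @param seed RNG seed.
#' @param exhaustive force/forbid enumeration; `NULL` = automatic.
#' @return object of class `protest_result`: `m12_squared`, `r`, `p`,
#'   `n_perm`, `exhaustive`, `n`.
#' @export
procrustes_test <- function(x, y, n_perm = 4999, seed = NULL,
                            exhaustive = NULL) {
  X <- if (inherits(x, "ordination")) x$points else as.matrix(x)
  Y <- if (inherits(y, "ordination")) y$points else as.matrix(y)
  if (is.null(rownames(X)) || is.null(rownames(Y))) {
    stop("configurations must have row labels", call. = FALSE)
  }
  if (!setequal(rownames(X), rownames(Y))) {
    stop("`x` and `y` have different labels", call. = FALSE)
  }
  Y <- Y[rownames(X), , drop = FALSE]
  if (ncol(X) != ncol(Y)) {
    stop("`x` and `y` have different dimensions", call. = FALSE)
  }
  X <- normalise_configuration(X)
  Y <- normalise_configuration(Y)
  stat <- function(Yp) {
    sum(svd(crossprod(X, Yp))$d)  # = sqrt(1 - m12^2)
  }
  r <- stat(Y)
  n <- nrow(X)
  if (is.null(exhaustive)) {
    exhaustive <- factorial(n) <= 5040
  }
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, function(p) stat(Y[p, , drop = FALSE]))
    p <- mean(rs >= r - 1e-12)
    n_used <- nrow(perms)
  } else {
    rs <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(k) stat(Y[sample.int(n), , drop = FALSE]),
             numeric(1))
    })
    p <- (1 + sum(rs >= r - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  m12sq <- max(0, min(1, 1 - r^2))
  structure(
    list(m12_squared = m12sq, r = min(r, 1), p = p, n_perm = n_used,
         exhaustive = exhaustive, n = n),
    class = "protest_result"
  )
}

#' @export
print.protest_result <- function(x, ...) {
  cat(sprintf("Procrustes: m12^2 = %.4f, r = %.4f, p = %.4g (%s, %d)\n",
              x$m12_squared, x$r, x$p,
              if (x$exhaustive) "exact" else "Monte Carlo", x$n_perm))
  invisible(x)
}
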