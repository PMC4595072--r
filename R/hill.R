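# Jost/Hill diversity partitioning: alpha, beta, gamma as effective numbers
# of species, pairwise turnover, and read-subsampling rarefaction.

# Core partition on a matrix P of relative abundances (rows sum to 1) with
# sample weights w (sum to 1). Returns c(alpha, beta, gamma).
#
# q != 1:
#   gamma = (sum_i pbar_i^q)^(1/(1-q)),  pbar_i = sum_j w_j P[j,i]
#   alpha = [ sum_ij (w_j P[j,i])^q / sum_j w_j^q ]^(1/(1-q))
# q == 1 (limits):
#   gamma = exp(-sum_i pbar_i log pbar_i)
#   alpha = exp(-sum_j w_j sum_i P[j,i] log P[j,i])
# Terms with p = 0 contribute 0; natural logarithms throughout.
hill_partition_core <- function(P, q, w) {
  wp <- P * w  # recycles w down columns: wp[j, i] = w_j * P[j, i]
  pbar <- colSums(wp)
  if (q == 1) {
    pos <- pbar > 0
    gamma <- exp(-sum(pbar[pos] * log(pbar[pos])))
    lP <- P
    lP[P > 0] <- P[P > 0] * log(P[P > 0])
    lP[P == 0] <- 0
    alpha <- exp(-sum(w * rowSums(lP)))
  } else {
    pos <- pbar > 0
    gamma <- sum(pbar[pos]^q)^(1 / (1 - q))
    num <- sum(wp[wp > 0]^q)
    alpha <- (num / sum(w^q))^(1 / (1 - q))
  }
  c(alpha = alpha, beta = gamma / alpha, gamma = gamma)
}

# Relative-abundance matrix from a community matrix (rows normalised).
relative_abundance <- function(cm) {
  counts <- if (inherits(cm, "community_matrix")) cm$counts else cm
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("empty sample(s) in community matrix", call. = FALSE)
  }
  counts / rs
}

#' Jost's multiplicative diversity partition
#'
#' Partitions the pooled (gamma) diversity of a community matrix into mean
#' within-sample (alpha) and among-sample (beta) components, all expressed as
#' Hill numbers (effective numbers of species) of order `q`, with
#' `gamma = alpha * beta`. `q = 0` weights all species equally (richness),
#' `q = 1` weights by abundance (exponential Shannon entropy), `q = 2`
#' emphasises dominants (inverse Simpson).
#'
#' With equal sample weights (the default, and the convention used by every
#' pipeline function in this package) beta is independent of alpha at all
#' orders and ranges from 1 (identical compositions) to the number of
#' samples (all disjoint).
#'
#' @param cm a [community_matrix()] or a plain counts matrix (samples in
#'   rows).
#' @param q diversity order, a single non-negative number.
#' @param weights per-sample weights summing to 1 (tolerance 1e-9);
#'   default equal weights `1/N`.
#' @return an object of class `diversity_partition` with elements `q`,
#'   `weights`, `alpha`, `beta`, `gamma`, `n_samples`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), paste0("otu", 1:4)))
#' partition_diversity(m, q = 1)  # alpha 2, beta 2, gamma 4
partition_diversity <- function(cm, q = 1, weights = NULL) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop("`q` must be a single non-negative number", call. = FALSE)
  }
  P <- relative_abundance(cm)
  n <- nrow(P)
  if (is.null(weights)) {
    weights <- rep(1 / n, n)
  }
  if (length(weights) != n || any(weights <= 0)) {
    stop("`weights` must be positive with one entry per sample",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  part <- hill_partition_core(P, q, weights)
  structure(
    list(q = q, weights = weights, alpha = unname(part["alpha"]),
         beta = unname(part["beta"]), gamma = unname(part["gamma"]),
         n_samples = n),
    class = "diversity_partition"
  )
}

#' @export
print.diversity_partition <- function(x, ...) {
  cat(sprintf(
    "Diversity partition (q = %g, %d samples):\n  alpha %.4f  beta %.4f  gamma %.4f\n",
    x$q, x$n_samples, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Pairwise turnover matrix
#'
#' Turnover between two samples is the normalised pairwise effective beta
#' diversity `(D_beta - 1) / (N - 1)` with `N = 2`, i.e. `D_beta - 1`,
#' computed on the two-sample submatrix with equal weights. It is 0 when the
#' two samples have identical relative composition and 1 when they share no
#' OTUs.
#'
#' @param cm a [community_matrix()] or counts matrix with at least 2 samples.
#' @param q diversity order (default 1, the "effective beta" used for
#'   marker comparisons).
#' @return a [stats::dist] object over the samples with attribute `metric`
#'   set to `"turnover-q<q>"`.
#' @export
pairwise_turnover_matrix <- function(cm, q = 1) {
  P <- relative_abundance(cm)
  n <- nrow(P)
  if (n < 2L) {
    stop("need at least 2 samples for pairwise turnover", call. = FALSE)
  }
  w <- c(0.5, 0.5)
  out <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      beta <- hill_partition_core(P[c(j, k), , drop = FALSE], q, w)["beta"]
      out[j, k] <- out[k, j] <- min(max(beta - 1, 0), 1)
    }
  }
  d <- stats::as.dist(out)
  attr(d, "metric") <- sprintf("turnover-q%g", q)
  d
}

#' Rarefaction of diversity components by read subsampling
#'
#' Assesses the sensitivity of alpha, beta and gamma diversity to sequencing
#' depth. For each requested depth and replicate, that many reads are drawn
#' without replacement from the pooled read multiset (every read tagged with
#' its sample and OTU), the community matrix is rebuilt from the draw, and
#' the Jost partition of order `q` recomputed. Samples that receive no reads
#' in a draw are left out of that replicate's partition. Alpha and gamma
#' typically keep climbing with depth while beta stabilises after a few
#' thousand reads.
#'
#' @param cm a [community_matrix()] with integer counts (reads).
#' @param depths strictly increasing vector of read counts, each at most the
#'   grand total.
#' @param replicates number of independent subsamples per depth.
#' @param q diversity order.
#' @param seed RNG seed; each replicate gets an independent substream
#'   derived from it, so replicate `r` is reproducible in isolation.
#' @param scope `"pooled"` (default) draws from the pooled read multiset so
#'   the x-axis is total sequence reads; `"per-sample"` rarefies every
#'   sample to `depth` reads independently (requires depth at most the
#'   smallest sample total).
#' @return object of class `rarefaction_curve`: a `summary` data frame
#'   (depth, component, mean, sd) and a tidy `values` data frame
#'   (depth, replicate, component, value).
#' @export
rarefy_diversity <- function(cm, depths, replicates = 50, q = 1, seed = NULL,
                             scope = c("pooled", "per-sample")) {
  stopifnot(inherits(cm, "community_matrix"))
  scope <- match.arg(scope)
  counts <- cm$counts
  if (any(counts != round(counts))) {
    stop("rarefaction requires integer read counts", call. = FALSE)
  }
  depths <- as.numeric(depths)
  if (any(diff(depths) <= 0)) {
    stop("`depths` must be strictly increasing", call. = FALSE)
  }
  total <- if (scope == "pooled") sum(counts) else min(rowSums(counts))
  if (any(depths > total) || any(depths < 1)) {
    stop(sprintf("depths must lie in [1, %d]", as.integer(total)),
         call. = FALSE)
  }
  n_cell <- length(counts)
  pool <- rep.int(seq_len(n_cell), as.integer(counts))
  rep_seeds <- with_seed(seed, sample.int(2147483646L, replicates))

  one_draw <- function(depth) {
    if (scope == "pooled") {
      drawn <- tabulate(pool[sample.int(length(pool), depth)], nbins = n_cell)
      sub <- matrix(drawn, nrow = nrow(counts), dimnames = dimnames(counts))
    } else {
      sub <- t(apply(counts, 1L, function(row) {
        cells <- rep.int(seq_along(row), as.integer(row))
        tabulate(cells[sample.int(length(cells), depth)],
                 nbins = length(row))
      }))
      dimnames(sub) <- dimnames(counts)
    }
    keep <- rowSums(sub) > 0
    part <- hill_partition_core(relative_abundance(sub[keep, , drop = FALSE]),
                                q, rep(1 / sum(keep), sum(keep)))
    part
  }

  rows <- vector("list", length(depths) * replicates)
  k <- 1L
  for (d in seq_along(depths)) {
    for (r in seq_len(replicates)) {
      part <- with_seed(rep_seeds[r] + d - 1L, one_draw(depths[d]))
      rows[[k]] <- data.frame(depth = depths[d], replicate = r,
                              component = c("alpha", "beta", "gamma"),
                              value = unname(part))
      k <- k + 1L
    }
  }
  values <- do.call(rbind, rows)
  summary <- stats::aggregate(value ~ depth + component, data = values,
                              FUN = mean)
  names(summary)[names(summary) == "value"] <- "mean"
  summary$sd <- stats::aggregate(value ~ depth + component, data = values,
                                 FUN = stats::sd)$value
  structure(
    list(summary = summary, values = values, q = q, seed = seed,
         replicates = replicates, scope = scope, marker = cm$marker),
    class = "rarefaction_curve"
  )
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("Rarefaction curve [%s], q = %g, %d replicates (%s reads)\n",
              x$marker, x$q, x$replicates, x$scope))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
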