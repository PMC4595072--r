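# Conservation-priority ranking of plots by retained beta diversity, and
# rank agreement between methods.

#' Greedy plot ranking by retained beta diversity
#'
#' Ranks plots by conservation priority: at each step the plot whose removal
#' leaves the remaining set with the *maximal* beta diversity (order `q`,
#' equal weights) is removed. Plots removed early are therefore the most
#' redundant (lowest priority); plots surviving longest contribute the most
#' complementary composition. Ties are broken lexicographically by plot id.
#' Removal proceeds until two plots remain; beta diversity of a single plot
#' is degenerate, so the final two plots are ordered by one last application
#' of the tie rule (lexicographic) and no retained-beta value is recorded
#' for them.
#'
#' @param cm a plot-level [community_matrix()] with at least 3 plots.
#' @param q diversity order (default 1, effective beta).
#' @return object of class `priority_ranking`: `removal_order` (first
#'   removed = lowest priority), `retained_beta` (length `n - 2`),
#'   `priority` (plot ids from highest to lowest priority), `q`, `marker`.
#' @export
greedy_beta_ranking <- function(cm, q = 1) {
  stopifnot(inherits(cm, "community_matrix"))
  counts <- cm$counts
  n <- nrow(counts)
  if (n < 3L) {
    stop("need at least 3 plots", call. = FALSE)
  }
  P <- relative_abundance(counts)
  beta_of <- function(rows) {
    k <- length(rows)
    hill_partition_core(P[rows, , drop = FALSE], q, rep(1 / k, k))[["beta"]]
  }
  remaining <- rownames(counts)
  removal_order <- character(0)
  retained_beta <- numeric(0)
  while (length(remaining) > 2L) {
    cand <- sort(remaining)  # lexicographic scan => first max wins ties
    best <- NULL
    best_beta <- -Inf
    for (pl in cand) {
      b <- beta_of(setdiff(remaining, pl))
      if (b > best_beta + 1e-12) {
        best <- pl
        best_beta <- b
      }
    }
    removal_order <- c(removal_order, best)
    retained_beta <- c(retained_beta, best_beta)
    remaining <- setdiff(remaining, best)
  }
  removal_order <- c(removal_order, sort(remaining))
  structure(
    list(removal_order = removal_order, retained_beta = retained_beta,
         priority = rev(removal_order), q = q, marker = cm$marker),
    class = "priority_ranking"
  )
}

#' @export
print.priority_ranking <- function(x, ...) {
  cat(sprintf(
    "Greedy beta-retention ranking [%s], q = %g (first removed = lowest priority)\n",
    x$marker, x$q))
  n <- length(x$removal_order)
  beta <- c(sprintf("%.3f", x$retained_beta), rep("-", 2L))
  for (k in seq_len(n)) {
    cat(sprintf("  %2d. remove %-12s retained beta %s\n", k,
                x$removal_order[k], beta[k]))
  }
  invisible(x)
}

#' Spearman rank correlation between two priority rankings
#'
#' Tie-corrected Spearman rho between the removal ranks of two
#' [greedy_beta_ranking()] results (or any two rankings of the same plot
#' set). The p-value is exact by enumeration of all permutations for
#' `n <= 8` plots, and uses the t approximation otherwise.
#'
#' @param rank1,rank2 `priority_ranking` objects, or named rank vectors
#'   over the same plots.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return object of class `rank_correlation` with `rho`, `p`, `n`,
#'   `method` (`"exact"` or `"t-approximation"`).
#' @export
spearman_rank_correlation <- function(rank1, rank2,
                                      alternative = c("two.sided", "greater",
                                                      "less")) {
  alternative <- match.arg(alternative)
  as_ranks <- function(r) {
    if (inherits(r, "priority_ranking")) {
      stats::setNames(seq_along(r$removal_order), r$removal_order)
    } else if (!is.null(names(r))) {
      r
    } else {
      stop("rankings must be priority_ranking objects or named vectors",
           call. = FALSE)
    }
  }
  r1 <- as_ranks(rank1)
  r2 <- as_ranks(rank2)
  if (!setequal(names(r1), names(r2))) {
    stop("rankings cover different plot sets", call. = FALSE)
  }
  r2 <- r2[names(r1)]
  x <- rank(r1)
  y <- rank(r2)
  n <- length(x)
  rho <- stats::cor(x, y)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(x, y[p]))
    p <- switch(alternative,
      two.sided = mean(abs(rhos) >= abs(rho) - 1e-12),
      greater = mean(rhos >= rho - 1e-12),
      less = mean(rhos <= rho + 1e-12))
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- switch(alternative,
      two.sided = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
      greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
      less = stats::pt(tstat, n - 2))
    p <- min(p, 1)
    method <- "t-approximation"
  }
  structure(
    list(rho = rho, p = p, n = n, method = method,
         alternative = alternative),
    class = "rank_correlation"
  )
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (%s, %s, n = %d)\n",
              x$rho, x$p, x$method, x$alternative, x$n))
  invisible(x)
}
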