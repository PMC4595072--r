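# Independent oracles and fixture builders used across the test suite.
# These deliberately use naive, explicit-loop implementations so they share
# no code path with the package internals they check.

# Direct-formula Jost partition with explicit sums.
oracle_hill_partition <- function(counts, q,
                                  w = rep(1 / nrow(counts), nrow(counts))) {
  N <- nrow(counts)
  S <- ncol(counts)
  P <- matrix(0, N, S)
  for (j in seq_len(N)) {
    P[j, ] <- counts[j, ] / sum(counts[j, ])
  }
  pbar <- numeric(S)
  for (i in seq_len(S)) {
    for (j in seq_len(N)) {
      pbar[i] <- pbar[i] + w[j] * P[j, i]
    }
  }
  if (q == 1) {
    h <- 0
    for (i in seq_len(S)) {
      if (pbar[i] > 0) h <- h - pbar[i] * log(pbar[i])
    }
    gamma <- exp(h)
    ha <- 0
    for (j in seq_len(N)) {
      hj <- 0
      for (i in seq_len(S)) {
        if (P[j, i] > 0) hj <- hj - P[j, i] * log(P[j, i])
      }
      ha <- ha + w[j] * hj
    }
    alpha <- exp(ha)
  } else {
    sg <- 0
    for (i in seq_len(S)) {
      if (pbar[i] > 0) sg <- sg + pbar[i]^q
    }
    gamma <- sg^(1 / (1 - q))
    num <- 0
    for (j in seq_len(N)) {
      for (i in seq_len(S)) {
        if (P[j, i] > 0) num <- num + (w[j] * P[j, i])^q
      }
    }
    den <- 0
    for (j in seq_len(N)) den <- den + w[j]^q
    alpha <- (num / den)^(1 / (1 - q))
  }
  c(alpha = alpha, beta = gamma / alpha, gamma = gamma)
}

# Random small community matrix with no empty rows or columns.
random_counts <- function(n_samples, n_otus, max_count = 20) {
  repeat {
    m <- matrix(rpois(n_samples * n_otus, 1.2) *
                  rbinom(n_samples * n_otus, 1, 0.6),
                n_samples, n_otus)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("o", seq_len(n_otus)))
  m
}

random_cm <- function(n_samples, n_otus, marker = "test", ...) {
  community_matrix(random_counts(n_samples, n_otus, ...), marker = marker)
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dissimilarity <- function(n, labels = paste0("p", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

# Exhaustive-enumeration Mantel p-value, built directly on cor() and full
# matrix relabelings (independent of the package's index tricks).
oracle_mantel_exhaustive <- function(m1, m2) {
  n <- nrow(m1)
  x <- m1[lower.tri(m1)]
  r_obs <- cor(x, m2[lower.tri(m2)])
  perms <- ednacomp:::all_permutations(n)
  rs <- apply(perms, 1, function(p) {
    mp <- m2[p, p]
    cor(x, mp[lower.tri(mp)])
  })
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Greedy ranking recomputed with the oracle partition.
oracle_greedy_ranking <- function(counts, q = 1) {
  remaining <- rownames(counts)
  order_out <- character(0)
  while (length(remaining) > 2) {
    best <- NULL
    best_beta <- -Inf
    for (pl in sort(remaining)) {
      rows <- setdiff(remaining, pl)
      b <- oracle_hill_partition(counts[rows, , drop = FALSE], q)["beta"]
      if (b > best_beta + 1e-12) {
        best <- pl
        best_beta <- b
      }
    }
    order_out <- c(order_out, best)
    remaining <- setdiff(remaining, best)
  }
  c(order_out, sort(remaining))
}

# VIF of each column via explicit per-variable regressions.
oracle_vifs <- function(dat) {
  sapply(names(dat), function(v) {
    others <- setdiff(names(dat), v)
    fit <- lm(as.formula(paste0("`", v, "` ~ ",
                                paste0("`", others, "`", collapse = "+"))),
              data = dat)
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  })
}
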