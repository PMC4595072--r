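# Mantel tests, the method correlation matrix, second-stage MDS,
# distance-decay regression, and within/between-plot turnover.

test_that("Mantel r is 1 for self-comparison and matches vegan", {
  set.seed(1)
  m1 <- random_dissimilarity(8)
  m2 <- random_dissimilarity(8)
  self <- mantel_test(m1, m1, n_perm = 99, seed = 1, exhaustive = FALSE)
  expect_equal(self$r, 1)

  mine <- mantel_test(m1, m2, n_perm = 999, seed = 1, exhaustive = FALSE)
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  # both use (1 + #{r* >= r}) / (n_perm + 1); p-values agree statistically
  expect_lt(abs(mine$p - ref$signif), 0.06)
})

test_that("exhaustive Mantel p equals the enumeration oracle at n = 4 and 5", {
  set.seed(2)
  for (n in c(4, 5)) {
    m1 <- random_dissimilarity(n)
    m2 <- random_dissimilarity(n)
    mt <- mantel_test(m1, m2)
    expect_true(mt$exhaustive)
    expect_equal(mt$n_perm, factorial(n))
    oracle <- oracle_mantel_exhaustive(m1, m2)
    expect_equal(mt$r, oracle$r, tolerance = 1e-12)
    expect_equal(mt$p, oracle$p)
    # symmetry of the statistic and of the exhaustive p in the arguments
    rev <- mantel_test(m2, m1)
    expect_equal(rev$r, mt$r, tolerance = 1e-12)
    expect_equal(rev$p, mt$p)
  }
})

test_that("Mantel p is invariant under joint relabeling of both matrices", {
  set.seed(3)
  m1 <- random_dissimilarity(5)
  m2 <- random_dissimilarity(5)
  p <- sample(5)
  perm1 <- m1[p, p]
  perm2 <- m2[p, p]
  expect_equal(mantel_test(m1, m2)$p, mantel_test(perm1, perm2)$p)
  expect_equal(mantel_test(m1, m2)$r, mantel_test(perm1, perm2)$r,
               tolerance = 1e-12)
})

test_that("Mantel contract errors: label mismatch, degenerate input", {
  m1 <- random_dissimilarity(5)
  m2 <- random_dissimilarity(5, labels = paste0("q", 1:5))
  expect_error(mantel_test(m1, m2), "different labels")
  flat <- matrix(1, 5, 5, dimnames = dimnames(m1))
  diag(flat) <- 0
  expect_error(mantel_test(m1, flat), "zero-variance")
  expect_error(mantel_test(m1[1:3, 1:3], m1[1:3, 1:3]), "at least 4")
})

test_that("method correlation matrix equals pairwise Mantel on common plots", {
  set.seed(4)
  labels <- paste0("Plot", 1:6)
  a <- random_dissimilarity(6, labels)
  b <- random_dissimilarity(6, labels)
  c6 <- random_dissimilarity(6, labels)
  # give one method an extra plot; restriction must drop it everywhere
  b_ext <- random_dissimilarity(7, c(labels, "Plot7"))
  b_ext[labels, labels] <- b
  mc <- method_correlation_matrix(list(A = a, B = b_ext, C = c6),
                                  n_perm = 99, seed = 5)
  expect_equal(unname(diag(mc$r)), rep(1, 3))
  expect_equal(mc$r, t(mc$r))
  direct <- mantel_test(a, b)
  expect_equal(mc$r["A", "B"], direct$r, tolerance = 1e-12)
  # duplicated method correlates perfectly with itself
  mc2 <- method_correlation_matrix(list(A = a, A2 = a, B = b),
                                   n_perm = 99, seed = 5)
  expect_equal(mc2$r["A", "A2"], 1)
  expect_error(method_correlation_matrix(list(A = a[1:3, 1:3],
                                              B = b[1:3, 1:3])),
               "fewer than 4")
})

test_that("methods sharing a gradient all correlate positively", {
  set.seed(6)
  gradient <- seq(0, 1, length.out = 8)
  mats <- lapply(1:6, function(k) {
    g <- gradient + rnorm(8, 0, 0.12)
    as.matrix(dist(g)) -> m
    dimnames(m) <- list(paste0("P", 1:8), paste0("P", 1:8))
    m
  })
  names(mats) <- paste0("m", 1:6)
  mc <- method_correlation_matrix(mats, n_perm = 99, seed = 6)
  expect_true(all(mc$r[upper.tri(mc$r)] > 0))
})

test_that("second-stage MDS places identical methods together, equal r equilateral", {
  set.seed(8)
  labels <- paste0("Plot", 1:6)
  a <- random_dissimilarity(6, labels)
  b <- random_dissimilarity(6, labels)
  c6 <- random_dissimilarity(6, labels)
  mc <- method_correlation_matrix(list(A = a, A2 = a, B = b, C = c6),
                                  n_perm = 99, seed = 1)
  ord <- second_stage_mds(mc, seed = 2)
  d <- as.matrix(dist(ord$points))
  expect_lt(d["A", "A2"], 1e-6)

  # equal off-diagonal correlations give an equilateral configuration
  req <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(req) <- 1
  orde <- second_stage_mds(req, seed = 3)
  de <- dist(orde$points)
  expect_lt(max(de) - min(de), 1e-6)
})

test_that("distance-decay regression recovers exact linear structure", {
  fix <- table1_fixture()
  elev <- setNames(fix$elevation, fix$plot_id)
  dd <- abs(outer(elev, elev, "-"))
  beta <- 0.1 + 0.001 * dd
  diag(beta) <- 0
  dimnames(beta) <- list(fix$plot_id, fix$plot_id)
  # a perfect fit triggers summary.lm's reliability warning; intended here
  reg <- suppressWarnings(distance_decay_regression(beta, elev))
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_equal(reg$slope, 0.001, tolerance = 1e-12)
  expect_equal(reg$r^2, reg$r_squared, tolerance = 1e-12)
  # the Plot 1 / Plot 10 pair sits at |640 - 50| = 590 m separation
  expect_equal(dd["Plot1", "Plot10"], 590)
  expect_equal(reg$n_pairs, 45)

  expect_error(distance_decay_regression(beta,
                                         setNames(rep(100, 10), fix$plot_id)),
               "constant")
})

test_that("within/between turnover split follows plot structure", {
  # duplicate subplots within plots, disjoint across plots
  ids <- c("P1-A", "P1-B", "P2-A", "P2-B")
  counts <- rbind(c(5, 5, 0, 0), c(5, 5, 0, 0),
                  c(0, 0, 5, 5), c(0, 0, 5, 5))
  dimnames(counts) <- list(ids, paste0("o", 1:4))
  cm <- community_matrix(counts,
                         plots = setNames(rep(c("P1", "P2"), each = 2), ids),
                         subplots = setNames(rep(c("A", "B"), 2), ids))
  ts <- within_between_turnover(cm, 1)
  expect_equal(ts$mean_within, 0)
  expect_equal(ts$mean_between, 1)

  # all subplots identical: both means 0
  same <- counts
  same[] <- rep(c(1, 2, 3, 4), each = 4)
  cm2 <- community_matrix(same, plots = cm$plots, subplots = cm$subplots)
  ts2 <- within_between_turnover(cm2, 1)
  expect_equal(ts2$mean_within, 0)
  expect_equal(ts2$mean_between, 0)

  # plot-level input has no within pairs
  expect_error(within_between_turnover(random_cm(4, 6)), "no within-plot")
})
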