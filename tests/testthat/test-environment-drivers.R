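# Environmental preparation, VIF screening, and db-RDA.

toy_env <- function(n = 10, seed = 61) {
  set.seed(seed)
  data.frame(
    plot_id = paste0("Plot", 1:n),
    elevation = seq(50, 640, length.out = n),
    slope = runif(n, 2, 45),
    aspect = runif(n, 0, 360),
    pH = rnorm(n, 5.6, 0.4),
    Olsen.P = rlnorm(n, log(8), 0.5),
    NO3.N = rlnorm(n, log(4), 0.5)
  )
}

test_that("aspect decomposes into east/north components", {
  env <- toy_env()
  env$aspect <- c(90, 0, 225, 180, 270, 45, 135, 315, 10, 350)
  prep <- prepare_environment(env, log_vars = character(0),
                              standardize = FALSE)
  expect_equal(unname(unlist(prep["Plot1", c("sin.aspect", "cos.aspect")])),
               c(1, 0), tolerance = 1e-12)
  expect_equal(unname(unlist(prep["Plot2", c("sin.aspect", "cos.aspect")])),
               c(0, 1), tolerance = 1e-12)
  expect_equal(unname(unlist(prep["Plot3", c("sin.aspect", "cos.aspect")])),
               c(-sqrt(2) / 2, -sqrt(2) / 2), tolerance = 1e-12)
  expect_equal(prep$sin.aspect^2 + prep$cos.aspect^2, rep(1, 10),
               tolerance = 1e-12)
  env$aspect[1] <- 380
  expect_error(prepare_environment(env), "aspect")
})

test_that("log transform validates positivity and standardization zero-centers", {
  env <- toy_env()
  prep <- prepare_environment(env)
  num <- vapply(prep, is.numeric, logical(1))
  expect_true(all(abs(colMeans(prep[, num])) < 1e-12))
  sds <- vapply(prep[, num], sd, numeric(1))
  expect_true(all(abs(sds - 1) < 1e-12))

  env$Olsen.P[3] <- 0
  expect_error(prepare_environment(env), "Olsen.P.*Plot3")
})

test_that("VIF loop: orthogonal survives, duplicates are infinite and pruned", {
  set.seed(62)
  n <- 12
  # columns orthonormal and orthogonal to the intercept => VIF exactly 1
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  dat <- as.data.frame(base)
  names(dat) <- paste0("v", 1:4)
  rep1 <- stepwise_vif_exclusion(dat, threshold = 10)
  expect_length(rep1$excluded, 0)
  expect_true(all(abs(rep1$rounds[[1]] - 1) < 1e-8))

  dat$dup <- dat$v1
  rep2 <- stepwise_vif_exclusion(dat, threshold = 10)
  expect_true(is.infinite(max(rep2$rounds[[1]])))
  expect_equal(rep2$excluded[1], "dup")  # lexicographic tie-break of the pair
  expect_false("dup" %in% rep2$surviving && "v1" %in% rep2$excluded)
})

test_that("VIF exclusion matches the per-round regression oracle", {
  set.seed(63)
  n <- 30
  # 15 variables with planted collinear blocks
  f1 <- rnorm(n); f2 <- rnorm(n)
  dat <- data.frame(
    e1 = f1, e2 = f1 + rnorm(n, 0, 0.1), e3 = f1 + rnorm(n, 0, 0.15),
    b1 = f2, b2 = f2 + rnorm(n, 0, 0.1), b3 = f2 + rnorm(n, 0, 0.12),
    b4 = f2 + rnorm(n, 0, 0.2))
  for (k in 1:8) dat[[paste0("x", k)]] <- rnorm(n)
  report <- stepwise_vif_exclusion(dat, threshold = 10)

  # oracle replay: recompute VIF with explicit regressions each round
  cur <- dat
  oracle_excluded <- character(0)
  repeat {
    vifs <- oracle_vifs(cur)
    expect_equal(unname(vifs[names(vifs)]),
                 unname(report$rounds[[length(oracle_excluded) + 1]][names(vifs)]),
                 tolerance = 1e-8)
    if (max(vifs) < 10) break
    worst <- sort(names(vifs)[vifs >= max(vifs) - 1e-9])[1]
    oracle_excluded <- c(oracle_excluded, worst)
    cur <- cur[, setdiff(names(cur), worst), drop = FALSE]
  }
  expect_equal(report$excluded, oracle_excluded)
  expect_lt(max(report$rounds[[length(report$rounds)]]), 10)
  expect_lte(length(report$rounds), ncol(dat))
})

test_that("db-RDA on an eigen-axis constraint explains exactly its eigenvalue", {
  set.seed(64)
  counts <- random_counts(8, 20)
  rownames(counts) <- paste0("Plot", 1:8)
  d <- community_distance(counts, "jaccard")
  ord <- pcoa(d)
  env <- data.frame(axis1 = ord$points[, 1], row.names = rownames(ord$points))
  fit <- dbrda(d, env, n_perm = 0)
  expect_equal(fit$proportion, ord$eigenvalues[1] / sum(ord$eigenvalues),
               tolerance = 1e-9)
  # inertia decomposition conserves the total
  expect_equal(fit$constrained_inertia + (fit$total_inertia -
                                            fit$constrained_inertia),
               sum(ord$eigenvalues), tolerance = 1e-9)
})

test_that("db-RDA matches vegan::capscale on a Euclidean toy problem", {
  set.seed(65)
  X <- matrix(rnorm(10 * 4), 10, dimnames = list(paste0("Plot", 1:10),
                                                 paste0("sp", 1:4)))
  d <- dist(X)
  env <- data.frame(v1 = rnorm(10), v2 = rnorm(10),
                    row.names = paste0("Plot", 1:10))
  mine <- dbrda(as.matrix(`attr<-`(d, "Labels", paste0("Plot", 1:10))) ->
                  dm, env, n_perm = 0)
  ref <- vegan::capscale(d ~ v1 + v2, data = env)
  expect_equal(mine$proportion,
               unname(ref$CCA$tot.chi / ref$tot.chi), tolerance = 1e-8)
})

test_that("db-RDA permutation p behaves under null and signal", {
  set.seed(66)
  # orthogonal constraint: proportion ~ 0 and p large (median over seeds)
  ps <- replicate(20, {
    counts <- random_counts(10, 25)
    rownames(counts) <- paste0("Plot", 1:10)
    env <- data.frame(noise = rnorm(10), row.names = rownames(counts))
    dbrda(counts, env, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(median(ps), 0.2)

  # elevation-driven composition: elevation beats a random covariate
  fix <- table1_fixture()
  elev <- setNames(fix$elevation, fix$plot_id)
  wins <- 0
  for (k in 1:20) {
    cfg <- synthetic_config(
      profiles = list(M = marker_profile("M", S = 150, depth = 2000,
                                         sigma = 120, g = 1)),
      seed = 6600 + k)
    sim <- simulate_gradient_metacommunity(cfg)
    cm <- pool_to_plots(sim$communities$M)
    env <- data.frame(elevation = scale(elev)[, 1],
                      noise = rnorm(10), row.names = names(elev))
    fit <- dbrda(cm, env, marginal = TRUE, n_perm = 0)
    marg <- fit$marginal
    if (marg$proportion[marg$variable == "elevation"] >
        marg$proportion[marg$variable == "noise"]) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("stepwise selection finds a planted driver and stays empty under null", {
  fix <- table1_fixture()
  elev <- setNames(fix$elevation, fix$plot_id)
  hits <- 0
  for (k in 1:15) {
    cfg <- synthetic_config(
      profiles = list(M = marker_profile("M", S = 150, depth = 2000,
                                         sigma = 100, g = 1)),
      seed = 6700 + k)
    sim <- simulate_gradient_metacommunity(cfg)
    cm <- pool_to_plots(sim$communities$M)
    set.seed(k)
    env <- data.frame(elevation = scale(elev)[, 1], n1 = rnorm(10),
                      n2 = rnorm(10), row.names = names(elev))
    sel <- stepwise_model_selection(cm, env, mode = "forward",
                                    n_perm = 199, seed = k)
    if (identical(sel$selected, "elevation")) hits <- hits + 1
  }
  expect_gte(hits, 12)

  nulls <- 0
  for (k in 1:15) {
    cm <- simulate_structureless_community(n_plots = 10, S = 100,
                                           depth = 1000, seed = 6800 + k)
    set.seed(k)
    env <- data.frame(v1 = rnorm(10), v2 = rnorm(10), v3 = rnorm(10),
                      row.names = rownames(cm$counts))
    sel <- stepwise_model_selection(cm, env, mode = "forward",
                                    n_perm = 199, seed = k)
    if (length(sel$selected) == 0) nulls <- nulls + 1
  }
  expect_gte(nulls, 12)
})

test_that("backward selection result is nested in the candidate span", {
  fix <- table1_fixture()
  elev <- setNames(fix$elevation, fix$plot_id)
  cfg <- synthetic_config(
    profiles = list(M = marker_profile("M", S = 150, depth = 2000,
                                       sigma = 100, g = 1)),
    seed = 70)
  sim <- simulate_gradient_metacommunity(cfg)
  cm <- pool_to_plots(sim$communities$M)
  set.seed(70)
  # every candidate is the planted driver duplicated with noise
  env <- data.frame(elevation = scale(elev)[, 1],
                    elev2 = scale(elev)[, 1] + rnorm(10, 0, 0.2),
                    elev3 = scale(elev)[, 1] + rnorm(10, 0, 0.25),
                    row.names = names(elev))
  fwd <- stepwise_model_selection(cm, env, mode = "forward", n_perm = 199,
                                  seed = 71)
  bwd <- stepwise_model_selection(cm, env, mode = "backward", n_perm = 199,
                                  seed = 71)
  expect_gte(length(fwd$selected), 1)
  expect_true(all(bwd$selected %in% names(env)))
  # both models explain a comparable share of inertia (same latent driver)
  if (length(bwd$selected)) {
    expect_lt(abs(bwd$proportion - fwd$proportion), 0.35)
  }
})

test_that("saturated and collinear designs are rejected", {
  counts <- random_counts(5, 10)
  rownames(counts) <- paste0("Plot", 1:5)
  env <- as.data.frame(matrix(rnorm(5 * 5), 5),
                       row.names = paste0("Plot", 1:5))
  expect_error(dbrda(counts, env, n_perm = 0), "saturated")
  env2 <- data.frame(a = rnorm(5), row.names = paste0("Plot", 1:5))
  env2$b <- 2 * env2$a
  expect_error(dbrda(counts, env2, n_perm = 0), "collinear")
})
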