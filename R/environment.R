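# Environmental covariate preparation (transforms, aspect decomposition,
# VIF pruning) and distance-based redundancy analysis with permutation
# tests and stepwise model selection.

#' Prepare an environment table for modelling
#'
#' Decomposes circular aspect into `sin.aspect` (how east-facing, 1 = east,
#' -1 = west) and `cos.aspect` (how north-facing, 1 = north, -1 = south),
#' natural-log transforms the listed skewed variables (strictly positive
#' values required), and standardizes every numeric modelling variable to
#' zero mean and unit variance so downstream inertia proportions are
#' scale-free.
#'
#' @param env data frame of plot-level variables; plot ids are taken from a
#'   `plot_id` column if present, otherwise from rownames.
#' @param log_vars variables to log-transform. The default covers the soil
#'   chemistry measurements that are typically right-skewed
#'   (Olsen phosphorus, electrical conductivity, nitrate, ammonium); pass
#'   your own list to change it.
#' @param aspect_var name of the aspect column (degrees in `[0, 360)`), or
#'   `NULL` if absent.
#' @param standardize standardize variables after transforming
#'   (default `TRUE`).
#' @return data frame of class `env_table` with rownames = plot ids, all
#'   numeric columns, and attributes `log_vars` and `standardized`.
#' @export
prepare_environment <- function(env,
                                log_vars = c("Olsen.P", "EC", "NO3.N",
                                             "NH4.N"),
                                aspect_var = "aspect", standardize = TRUE) {
  env <- as.data.frame(env)
  if ("plot_id" %in% names(env)) {
    rownames(env) <- as.character(env$plot_id)
    env$plot_id <- NULL
  }
  if (!is.null(aspect_var) && aspect_var %in% names(env)) {
    a <- env[[aspect_var]]
    if (any(a < 0 | a >= 360)) {
      stop("aspect must lie in [0, 360)", call. = FALSE)
    }
    rad <- a * pi / 180
    env$sin.aspect <- sin(rad)
    env$cos.aspect <- cos(rad)
  }
  log_vars <- intersect(log_vars, names(env))
  for (v in log_vars) {
    bad <- which(env[[v]] <= 0)
    if (length(bad)) {
      stop(sprintf("log transform of non-positive value: variable '%s', plot '%s'",
                   v, rownames(env)[bad[1L]]),
           call. = FALSE)
    }
    env[[v]] <- log(env[[v]])
  }
  num <- vapply(env, is.numeric, logical(1))
  if (standardize) {
    for (v in names(env)[num]) {
      s <- stats::sd(env[[v]])
      env[[v]] <- if (s > 0) (env[[v]] - mean(env[[v]])) / s else
        env[[v]] - mean(env[[v]])
    }
  }
  structure(env, log_vars = log_vars, standardized = standardize,
            class = c("env_table", "data.frame"))
}

# VIF of every column of a numeric data frame: 1 / (1 - R^2) of each
# variable regressed on all others; exact singularities give Inf.
compute_vifs <- function(dat) {
  vars <- names(dat)
  vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = dat)
    # exact collinearity gives a perfect fit; that is the Inf-VIF case, so
    # summary()'s perfect-fit warning is expected noise here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise exclusion of collinear variables by VIF
#'
#' Computes the variance inflation factor (VIF) of every candidate variable,
#' removes the variable with the highest VIF if that VIF is at or above the
#' threshold, recomputes, and repeats until every remaining variable has
#' VIF below the threshold. Exact singularities (e.g. duplicated variables,
#' or the sin/cos decomposition together with raw aspect) count as infinite
#' VIF.
#'
#' @param env an [prepare_environment()] table or numeric data frame.
#' @param threshold exclusion threshold (default 10, the conventional
#'   cut-off).
#' @param vars candidate variables (default: all numeric columns).
#' @return object of class `vif_report`: `rounds` (list of named VIF
#'   vectors, one per iteration), `excluded` (in exclusion order),
#'   `surviving`, `threshold`.
#' @export
stepwise_vif_exclusion <- function(env, threshold = 10, vars = NULL) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  vars <- vars %||% names(env)[num]
  if (length(vars) < 2L) {
    stop("need at least 2 candidate variables", call. = FALSE)
  }
  if (nrow(env) < 3L) {
    stop("need at least 3 plots", call. = FALSE)
  }
  dat <- env[, vars, drop = FALSE]
  rounds <- list()
  excluded <- character(0)
  repeat {
    vifs <- compute_vifs(dat)
    rounds[[length(rounds) + 1L]] <- vifs
    worst <- max(vifs)
    if (worst < threshold || ncol(dat) == 2L) {
      break
    }
    # drop the current maximum; ties resolved lexicographically
    cand <- sort(names(vifs)[vifs >= worst - 1e-9])
    drop_var <- cand[1L]
    excluded <- c(excluded, drop_var)
    dat <- dat[, setdiff(names(dat), drop_var), drop = FALSE]
  }
  structure(
    list(rounds = rounds, excluded = excluded, surviving = names(dat),
         threshold = threshold),
    class = "vif_report"
  )
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("Stepwise VIF exclusion (threshold %g): %d excluded, %d surviving\n",
              x$threshold, length(x$excluded), length(x$surviving)))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  cat("  surviving VIF:\n")
  print(round(x$rounds[[length(x$rounds)]], 2))
  invisible(x)
}

# Shared db-RDA machinery: site scores U from PCoA of the community
# distance, predictors Z (centered/scaled columns of the env table), and
# the permutation distribution of the pseudo-F for a variable set.
dbrda_setup <- function(cm, env, metric, q, quantitative) {
  is_dissimilarity <- inherits(cm, "dist") ||
    (is.matrix(cm) && nrow(cm) == ncol(cm) &&
       max(abs(cm - t(cm))) < 1e-12 && all(abs(diag(cm)) < 1e-12))
  d <- if (is_dissimilarity) {
    stats::as.dist(as_square_dissimilarity(cm, "cm"))
  } else {
    community_distance(cm, metric = metric, q = q,
                       quantitative = quantitative)
  }
  pc <- pcoa(d)
  U <- pc$points
  env <- as.data.frame(env)
  labels <- rownames(U)
  if (!all(labels %in% rownames(env))) {
    stop(sprintf("environment table missing plot(s): %s",
                 paste(setdiff(labels, rownames(env)), collapse = ", ")),
         call. = FALSE)
  }
  env <- env[labels, , drop = FALSE]
  list(U = U, env = env, total = sum(U^2),
       negative_inertia = pc$negative_inertia, labels = labels)
}

# Constrained inertia of site scores U under predictors in `dat` (columns
# centered; projection through QR without intercept).
constrained_inertia <- function(U, dat) {
  Z <- as.matrix(dat)
  Z <- sweep(Z, 2L, colMeans(Z))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("collinear (singular) variable set in db-RDA", call. = FALSE)
  }
  list(value = sum(qr.fitted(qz, U)^2), rank = qz$rank, qr = qz)
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a (possibly non-Euclidean) community
#' dissimilarity: the distance matrix is embedded by principal coordinates
#' (positive axes only, square-root eigenvalue scaling), and the site
#' scores are projected onto the space spanned by the environmental
#' predictors. Constrained inertia is the sum of squared fitted values;
#' the reported proportion is relative to the total positive inertia.
#' Significance of the pseudo-F statistic
#' `F = (constrained/m) / (residual/(n - m - 1))` is assessed by free
#' permutation of the site-score rows.
#'
#' @param cm a plot-level [community_matrix()], or a precomputed `dist` /
#'   labelled distance matrix.
#' @param env an [prepare_environment()] table (rows = plots).
#' @param variables variables to constrain on (default: all columns).
#' @param metric,q,quantitative distance options (see
#'   [community_distance()]); Jaccard is the conventional choice.
#' @param n_perm number of permutations; `0` skips the test.
#' @param seed RNG seed.
#' @param marginal if `TRUE`, additionally fit every variable alone and
#'   report its marginal explained proportion and p-value.
#' @return object of class `dbrda_result`: `total_inertia`,
#'   `constrained_inertia`, `proportion`, `pseudo_F`, `p`, `variables`,
#'   `n`, `negative_inertia`, and (if `marginal`) a `marginal` data frame.
#' @export
dbrda <- function(cm, env, variables = NULL, metric = "jaccard", q = 1,
                  quantitative = FALSE, n_perm = 999, seed = NULL,
                  marginal = FALSE) {
  setup <- dbrda_setup(cm, env, metric, q, quantitative)
  variables <- variables %||% names(setup$env)
  if (!all(variables %in% names(setup$env))) {
    stop("unknown variable(s): ",
         paste(setdiff(variables, names(setup$env)), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(setup$U)
  if (n < 3L) {
    stop("need at least 3 plots", call. = FALSE)
  }
  if (length(variables) >= n - 1L) {
    stop("saturated model: need fewer variables than plots - 1",
         call. = FALSE)
  }
  fit_one <- function(vars, seed_k) {
    ci <- constrained_inertia(setup$U, setup$env[, vars, drop = FALSE])
    m <- ci$rank
    resid <- setup$total - ci$value
    f <- (ci$value / m) / (resid / (n - m - 1))
    p <- NA_real_
    if (n_perm > 0) {
      fs <- with_seed(seed_k, vapply(seq_len(n_perm), function(k) {
        Up <- setup$U[sample.int(n), , drop = FALSE]
        cv <- sum(qr.fitted(ci$qr, Up)^2)
        (cv / m) / ((setup$total - cv) / (n - m - 1))
      }, numeric(1)))
      p <- (1 + sum(fs >= f - 1e-12)) / (n_perm + 1)
    }
    list(value = ci$value, proportion = ci$value / setup$total,
         pseudo_F = f, p = p, m = m)
  }
  full <- fit_one(variables, seed)
  marg <- NULL
  if (marginal) {
    marg <- do.call(rbind, lapply(variables, function(v) {
      fv <- fit_one(v, if (is.null(seed)) NULL else stage_seed(seed, v))
      data.frame(variable = v, proportion = fv$proportion,
                 pseudo_F = fv$pseudo_F, p = fv$p)
    }))
  }
  structure(
    list(total_inertia = setup$total, constrained_inertia = full$value,
         proportion = full$proportion, pseudo_F = full$pseudo_F, p = full$p,
         variables = variables, n = n, n_perm = n_perm,
         negative_inertia = setup$negative_inertia, marginal = marg),
    class = "dbrda_result"
  )
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "db-RDA (%d plots): %d variable(s) explain %.1f%% of inertia, pseudo-F %.3f, p = %.4g\n",
    x$n, length(x$variables), 100 * x$proportion, x$pseudo_F, x$p))
  if (!is.null(x$marginal)) {
    cat("Marginal (single-variable) models:\n")
    m <- x$marginal
    m$proportion <- sprintf("%.1f%%", 100 * m$proportion)
    print(m, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Stepwise db-RDA model selection by permutation tests
#'
#' Forward mode starts from an empty model and repeatedly adds the
#' candidate whose partial pseudo-F (conditional on the current model) has
#' the smallest permutation p-value, as long as that p-value is below
#' `alpha`. Backward mode starts from the full candidate set and repeatedly
#' drops the variable with the largest partial p-value at or above `alpha`.
#' Candidates should normally be the VIF-surviving variables.
#'
#' @param cm,env,metric,q,quantitative as in [dbrda()].
#' @param mode `"forward"` or `"backward"`.
#' @param alpha significance level for entry/removal.
#' @param candidates candidate variables (default: all env columns).
#' @param n_perm,seed permutation settings.
#' @return a `dbrda_result` for the selected model with extra fields
#'   `selected` (variable set, possibly empty), `mode`, `steps` (data frame
#'   trace of the selection path).
#' @export
stepwise_model_selection <- function(cm, env, mode = c("forward", "backward"),
                                     alpha = 0.05, candidates = NULL,
                                     metric = "jaccard", q = 1,
                                     quantitative = FALSE, n_perm = 999,
                                     seed = NULL) {
  mode <- match.arg(mode)
  setup <- dbrda_setup(cm, env, metric, q, quantitative)
  candidates <- candidates %||% names(setup$env)
  n <- nrow(setup$U)
  if (length(candidates) >= n - 1L) {
    stop("more candidates than plots - 2; prune with VIF first",
         call. = FALSE)
  }

  # partial permutation p for `var` given `base` (free row permutation)
  partial_test <- function(var, base, seed_k) {
    with_vars <- c(base, var)
    ci_with <- constrained_inertia(setup$U, setup$env[, with_vars,
                                                      drop = FALSE])
    ci_base_val <- if (length(base)) {
      constrained_inertia(setup$U, setup$env[, base, drop = FALSE])$value
    } else 0
    m <- ci_with$rank
    gain <- ci_with$value - ci_base_val
    f <- gain / ((setup$total - ci_with$value) / (n - m - 1))
    qz_with <- ci_with$qr
    qz_base <- if (length(base))
      qr(sweep(as.matrix(setup$env[, base, drop = FALSE]), 2L,
               colMeans(as.matrix(setup$env[, base, drop = FALSE]))))
    fs <- with_seed(seed_k, vapply(seq_len(n_perm), function(k) {
      Up <- setup$U[sample.int(n), , drop = FALSE]
      cw <- sum(qr.fitted(qz_with, Up)^2)
      cb <- if (length(base)) sum(qr.fitted(qz_base, Up)^2) else 0
      (cw - cb) / ((setup$total - cw) / (n - m - 1))
    }, numeric(1)))
    p <- (1 + sum(fs >= f - 1e-12)) / (n_perm + 1)
    list(p = p, f = f)
  }

  steps <- list()
  step_i <- 0L
  seed_for <- function(tag) {
    if (is.null(seed)) NULL else stage_seed(seed, tag)
  }
  if (mode == "forward") {
    selected <- character(0)
    pool <- candidates
    repeat {
      if (!length(pool)) break
      step_i <- step_i + 1L
      tests <- lapply(pool, function(v)
        partial_test(v, selected, seed_for(paste0("f", step_i, v))))
      ps <- vapply(tests, `[[`, numeric(1), "p")
      fs <- vapply(tests, `[[`, numeric(1), "f")
      best <- order(ps, -fs)[1L]
      steps[[step_i]] <- data.frame(step = step_i, action = "add",
                                    variable = pool[best], p = ps[best])
      if (ps[best] >= alpha) break
      selected <- c(selected, pool[best])
      pool <- setdiff(pool, pool[best])
      if (length(selected) >= n - 2L) break
    }
  } else {
    selected <- candidates
    repeat {
      if (length(selected) <= 1L) {
        if (length(selected) == 1L) {
          step_i <- step_i + 1L
          t1 <- partial_test(selected, character(0),
                             seed_for(paste0("b", step_i, selected)))
          steps[[step_i]] <- data.frame(step = step_i, action = "drop?",
                                        variable = selected, p = t1$p)
          if (t1$p >= alpha) selected <- character(0)
        }
        break
      }
      step_i <- step_i + 1L
      tests <- lapply(selected, function(v)
        partial_test(v, setdiff(selected, v),
                     seed_for(paste0("b", step_i, v))))
      ps <- vapply(tests, `[[`, numeric(1), "p")
      worst <- order(-ps)[1L]
      steps[[step_i]] <- data.frame(step = step_i, action = "drop?",
                                    variable = selected[worst], p = ps[worst])
      if (ps[worst] < alpha) break
      selected <- setdiff(selected, selected[worst])
    }
  }

  out <- if (length(selected)) {
    dbrda(cm, env, variables = selected, metric = metric, q = q,
          quantitative = quantitative, n_perm = n_perm,
          seed = seed_for("final"))
  } else {
    structure(
      list(total_inertia = setup$total, constrained_inertia = 0,
           proportion = 0, pseudo_F = NA_real_, p = NA_real_,
           variables = character(0), n = n, n_perm = n_perm,
           negative_inertia = setup$negative_inertia, marginal = NULL),
      class = "dbrda_result"
    )
  }
  out$selected <- selected
  out$mode <- mode
  out$steps <- if (length(steps)) do.call(rbind, steps) else NULL
  out
}
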