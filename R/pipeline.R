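# Orchestration: run every comparison stage on a set of community matrices
# plus an environment table, with per-stage seeds derived from one master
# seed and optional CSV/JSON output.

write_stage_csv <- function(out_dir, name, df) {
  if (!is.null(out_dir)) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
}

#' Run the full multi-method biodiversity comparison
#'
#' Executes the whole analysis battery over a set of community matrices
#' (eDNA markers and/or traditional surveys of the same plots):
#'
#' a. per-method diversity summary (sample/OTU counts, alpha/beta/gamma at
#'    each requested order);
#' b. rarefaction curves of the diversity components (integer-count
#'    methods only);
#' c. within- versus between-plot turnover (subplot-level methods only);
#' d. distance-decay: Mantel test and OLS regression of plot-level
#'    turnover against elevation difference;
#' e. method correlation matrix (pairwise Mantel) and its second-stage
#'    MDS;
#' f. NMDS ordination per method;
#' g. Procrustes (PROTEST) comparison of every pair of plot-level
#'    ordinations;
#' h. greedy beta-retention plot rankings and their Spearman rank
#'    correlations;
#' i. environmental preparation, stepwise VIF exclusion, and db-RDA per
#'    method (marginal models, the full VIF-surviving model, and
#'    forward/backward stepwise selection).
#'
#' Every stochastic stage draws its seed deterministically from the master
#' seed and the stage name, so reruns with the same inputs are
#' byte-identical and adding a stage never perturbs the others. When
#' `out_dir` is given, each stage's tables are written as they are
#' computed, so partial output survives a failing stage; a stage failure
#' aborts with an error naming the stage.
#'
#' @param communities named list of [community_matrix()] objects or CSV
#'   paths (read with [read_community_matrix()]).
#' @param env environment data frame or CSV path; must contain an
#'   `elevation` column and cover all plots.
#' @param q_orders diversity orders for the summary (default `c(0, 1)`).
#' @param q order used for turnover-based comparison stages (default 1).
#' @param n_perm permutations for Mantel/PROTEST/db-RDA stages.
#' @param seed master seed.
#' @param remove_singletons drop single-read OTUs first (read-count
#'   methods only).
#' @param rarefaction_fracs grand-total fractions at which to rarefy.
#' @param rarefaction_replicates replicates per depth.
#' @param out_dir optional output directory (created if needed).
#' @return a list of class `comparison_report` with one element per stage
#'   (`diversity`, `rarefaction`, `turnover_split`, `distance_decay`,
#'   `method_correlation`, `second_stage_mds`, `nmds`, `procrustes`,
#'   `rankings`, `drivers`) plus `log`.
#' @export
run_full_comparison <- function(communities, env, q_orders = c(0, 1), q = 1,
                                n_perm = 999, seed = 1,
                                remove_singletons = FALSE,
                                rarefaction_fracs = c(0.05, 0.2, 0.5, 1),
                                rarefaction_replicates = 10,
                                out_dir = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    invisible(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # -- inputs -----------------------------------------------------------
  cms <- stage("input", {
    if (is.null(names(communities))) {
      stop("`communities` must be a named list")
    }
    lapply(names(communities), function(nm) {
      x <- communities[[nm]]
      if (is.character(x)) x <- read_community_matrix(x, marker = nm)
      stopifnot(inherits(x, "community_matrix"))
      x
    })
  })
  names(cms) <- names(communities)
  env <- stage("input", {
    if (is.character(env)) env <- utils::read.csv(env)
    env <- as.data.frame(env)
    if ("plot_id" %in% names(env)) {
      rownames(env) <- as.character(env$plot_id)
    }
    if (!"elevation" %in% names(env)) {
      stop("environment table needs an `elevation` column")
    }
    env
  })
  if (remove_singletons) {
    cms <- stage("singleton-removal", lapply(cms, function(cm) {
      if (all(cm$counts == round(cm$counts))) remove_singleton_otus(cm)
      else cm
    }))
  }
  plot_cms <- lapply(cms, pool_to_plots)
  elev <- stats::setNames(env$elevation, rownames(env))
  note("inputs: %d methods, master seed %d, n_perm %d", length(cms),
       as.integer(seed), n_perm)

  # -- (a) diversity summary -------------------------------------------
  diversity <- stage("diversity", {
    rows <- lapply(names(plot_cms), function(nm) {
      cm <- plot_cms[[nm]]
      out <- data.frame(method = nm, n_plots = nrow(cm$counts),
                        n_otus = ncol(cm$counts), total = sum(cm$counts))
      for (qq in q_orders) {
        part <- partition_diversity(cm, q = qq)
        out[[sprintf("alpha_q%g", qq)]] <- part$alpha
        out[[sprintf("beta_q%g", qq)]] <- part$beta
        out[[sprintf("gamma_q%g", qq)]] <- part$gamma
      }
      out
    })
    do.call(rbind, rows)
  })
  write_stage_csv(out_dir, "diversity_summary", diversity)

  # -- (b) rarefaction --------------------------------------------------
  rarefaction <- stage("rarefaction", {
    out <- list()
    for (nm in names(cms)) {
      cm <- cms[[nm]]
      if (any(cm$counts != round(cm$counts))) {
        note("rarefaction: skipped %s (non-integer counts)", nm)
        next
      }
      total <- sum(cm$counts)
      depths <- sort(unique(pmax(1, round(rarefaction_fracs * total))))
      out[[nm]] <- rarefy_diversity(cm, depths = depths,
                                    replicates = rarefaction_replicates,
                                    q = q,
                                    seed = stage_seed(seed,
                                                      paste0("rarefy:", nm)))
    }
    out
  })
  if (length(rarefaction)) {
    write_stage_csv(out_dir, "rarefaction",
                    do.call(rbind, lapply(names(rarefaction), function(nm)
                      cbind(method = nm, rarefaction[[nm]]$values))))
  }

  # -- (c) within/between turnover -------------------------------------
  turnover_split <- stage("turnover-split", {
    out <- list()
    for (nm in names(cms)) {
      cm <- cms[[nm]]
      if (is.null(cm$subplots) || length(unique(cm$plots)) == nrow(cm$counts)) {
        note("turnover-split: skipped %s (no subplot structure)", nm)
        next
      }
      out[[nm]] <- within_between_turnover(cm, q = q)
    }
    out
  })
  if (length(turnover_split)) {
    write_stage_csv(out_dir, "turnover_split",
                    do.call(rbind, lapply(names(turnover_split), function(nm) {
                      ts <- turnover_split[[nm]]
                      data.frame(method = nm,
                                 scope = rep(c("within", "between"),
                                             c(length(ts$within),
                                               length(ts$between))),
                                 turnover = c(ts$within, ts$between))
                    })))
  }

  # -- plot-level turnover distances (shared by d, e, h) ----------------
  turn <- stage("turnover", lapply(plot_cms, pairwise_turnover_matrix, q = q))

  # -- (d) distance decay ----------------------------------------------
  distance_decay <- stage("distance-decay", {
    delev <- stats::dist(elev[rownames(plot_cms[[1L]]$counts)])
    rows <- lapply(names(turn), function(nm) {
      labs <- attr(turn[[nm]], "Labels")
      de <- stats::dist(elev[labs])
      mt <- mantel_test(turn[[nm]], de, n_perm = n_perm,
                        seed = stage_seed(seed, paste0("decay:", nm)),
                        exhaustive = FALSE)
      reg <- distance_decay_regression(turn[[nm]], elev)
      data.frame(method = nm, mantel_r = mt$r, mantel_p = mt$p,
                 slope = reg$slope, r_squared = reg$r_squared,
                 p_value = reg$p)
    })
    do.call(rbind, rows)
  })
  write_stage_csv(out_dir, "distance_decay", distance_decay)

  # -- (e) method correlations + second-stage MDS -----------------------
  method_correlation <- stage("method-correlation",
    method_correlation_matrix(turn, n_perm = n_perm,
                              seed = stage_seed(seed, "method-correlation")))
  write_stage_csv(out_dir, "method_correlation", method_correlation$pairs)
  ssmds <- NULL
  if (nrow(method_correlation$r) >= 3L) {
    ssmds <- stage("second-stage-mds",
      second_stage_mds(method_correlation,
                       seed = stage_seed(seed, "second-stage-mds")))
    write_stage_csv(out_dir, "second_stage_mds",
                    data.frame(method = rownames(ssmds$points),
                               ssmds$points, stress = ssmds$stress))
  } else {
    note("second-stage-mds: skipped (needs at least 3 methods)")
  }

  # -- (f) NMDS per method ---------------------------------------------
  nmds_fits <- stage("nmds", {
    out <- lapply(names(cms), function(nm)
      nmds(pairwise_turnover_matrix(cms[[nm]], q = q),
           seed = stage_seed(seed, paste0("nmds:", nm))))
    names(out) <- names(cms)
    out
  })
  if (!is.null(out_dir)) {
    for (nm in names(nmds_fits)) {
      write_stage_csv(out_dir, paste0("nmds_", gsub("[^A-Za-z0-9]", "_", nm)),
                      data.frame(sample = rownames(nmds_fits[[nm]]$points),
                                 nmds_fits[[nm]]$points,
                                 stress = nmds_fits[[nm]]$stress))
    }
  }

  # -- (g) Procrustes between plot-level ordinations --------------------
  procrustes <- stage("procrustes", {
    ords <- lapply(names(turn), function(nm)
      nmds(turn[[nm]], seed = stage_seed(seed, paste0("ord:", nm))))
    names(ords) <- names(turn)
    nms <- names(ords)
    rows <- list()
    for (a in seq_along(nms)[-length(nms)]) {
      for (b in (a + 1L):length(nms)) {
        pr <- procrustes_test(ords[[a]], ords[[b]], n_perm = n_perm,
                              seed = stage_seed(seed,
                                                paste0("pro:", nms[a], "|",
                                                       nms[b])))
        rows[[length(rows) + 1L]] <- data.frame(
          method1 = nms[a], method2 = nms[b], m12_squared = pr$m12_squared,
          r = pr$r, p = pr$p)
      }
    }
    do.call(rbind, rows)
  })
  write_stage_csv(out_dir, "procrustes", procrustes)

  # -- (h) greedy rankings + Spearman ----------------------------------
  rankings <- stage("rankings", {
    ranks <- lapply(plot_cms, greedy_beta_ranking, q = q)
    nms <- names(ranks)
    rho <- diag(1, length(nms))
    pmat <- matrix(NA_real_, length(nms), length(nms))
    dimnames(rho) <- dimnames(pmat) <- list(nms, nms)
    if (length(nms) > 1L) {
      for (a in seq_along(nms)[-length(nms)]) {
        for (b in (a + 1L):length(nms)) {
          sc <- spearman_rank_correlation(ranks[[a]], ranks[[b]])
          rho[a, b] <- rho[b, a] <- sc$rho
          pmat[a, b] <- pmat[b, a] <- sc$p
        }
      }
    }
    list(rankings = ranks, rho = rho, p = pmat)
  })
  write_stage_csv(out_dir, "rankings",
                  do.call(rbind, lapply(names(rankings$rankings), function(nm) {
                    rk <- rankings$rankings[[nm]]
                    data.frame(method = nm,
                               rank = seq_along(rk$removal_order),
                               plot_id = rk$removal_order,
                               retained_beta = c(rk$retained_beta, NA, NA))
                  })))

  # -- (i) environmental drivers ---------------------------------------
  drivers <- stage("drivers", {
    prep <- prepare_environment(env[, setdiff(names(env), "plot_id"),
                                    drop = FALSE])
    vif <- stepwise_vif_exclusion(prep)
    per_method <- lapply(names(plot_cms), function(nm) {
      sd_seed <- stage_seed(seed, paste0("dbrda:", nm))
      cand <- vif$surviving
      # keep the model unsaturated on small designs
      n <- nrow(plot_cms[[nm]]$counts)
      if (length(cand) >= n - 1L) {
        cand <- cand[seq_len(n - 2L)]
      }
      list(
        marginal = dbrda(plot_cms[[nm]], prep, variables = cand,
                         n_perm = n_perm, seed = sd_seed, marginal = TRUE),
        forward = stepwise_model_selection(plot_cms[[nm]], prep,
                                           mode = "forward",
                                           candidates = cand,
                                           n_perm = n_perm, seed = sd_seed),
        backward = stepwise_model_selection(plot_cms[[nm]], prep,
                                            mode = "backward",
                                            candidates = cand,
                                            n_perm = n_perm, seed = sd_seed)
      )
    })
    names(per_method) <- names(plot_cms)
    list(env = prep, vif = vif, models = per_method)
  })
  if (!is.null(out_dir)) {
    marg <- do.call(rbind, lapply(names(drivers$models), function(nm)
      cbind(method = nm, drivers$models[[nm]]$marginal$marginal)))
    write_stage_csv(out_dir, "dbrda_marginal", marg)
    jsonlite::write_json(
      list(vif_surviving = drivers$vif$surviving,
           vif_excluded = drivers$vif$excluded,
           models = lapply(drivers$models, function(m) list(
             full_proportion = m$marginal$proportion,
             forward_selected = m$forward$selected,
             forward_proportion = m$forward$proportion,
             backward_selected = m$backward$selected,
             backward_proportion = m$backward$proportion))),
      file.path(out_dir, "dbrda_models.json"), auto_unbox = TRUE,
      digits = NA)
  }

  structure(
    list(diversity = diversity, rarefaction = rarefaction,
         turnover_split = turnover_split, distance_decay = distance_decay,
         method_correlation = method_correlation,
         second_stage_mds = ssmds, nmds = nmds_fits,
         procrustes = procrustes, rankings = rankings, drivers = drivers,
         seed = seed, n_perm = n_perm, log = log),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report: %d methods, seed %d, %d permutations\n",
              nrow(x$diversity), as.integer(x$seed), x$n_perm))
  cat("\nDiversity summary:\n")
  print(x$diversity, row.names = FALSE, digits = 4)
  cat("\nDistance decay (turnover vs elevation):\n")
  print(x$distance_decay, row.names = FALSE, digits = 3)
  cat("\nMethod correlations (Mantel r):\n")
  print(round(x$method_correlation$r, 3))
  invisible(x)
}
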