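# Synthetic gradient-metacommunity generator: multi-marker community
# matrices with elevational niche structure, a plot/subplot hierarchy, and
# an environment table with planted collinearity, so that every analysis in
# the package can be exercised and calibrated without sequence data.

#' Study-plot elevation and temperature fixture
#'
#' The ten 20 x 20 m forest plots used throughout the package's examples and
#' synthetic defaults: one plot per 60 m elevational band from 50 m to
#' 640 m, each with its mean annual surface soil temperature (degrees C,
#' two-year logger average). Temperature declines with elevation (about
#' -0.5 degrees C per 100 m) with one local anomaly at Plot 8, which makes
#' the pair a realistic planted collinearity for covariate screening.
#'
#' @return data frame with columns `plot_id`, `elevation` (m),
#'   `temperature` (degrees C), rownames = plot ids.
#' @export
#' @examples
#' table1_fixture()
table1_fixture <- function() {
  # Reviewed constant block; do not edit piecemeal.
  df <- data.frame(
    plot_id = paste0("Plot", 1:10),
    elevation = c(50, 90, 160, 260, 240, 320, 420, 460, 595, 640),
    temperature = c(15.270, 15.225, 14.665, 14.115, 13.935, 13.555,
                    12.935, 13.645, 12.245, 12.215)
  )
  rownames(df) <- df$plot_id
  df
}

#' Per-marker simulation profile
#'
#' Bundles the parameters controlling one simulated marker (or traditional
#' method): species pool size, sequencing depth per subplot sample, niche
#' width, gradient strength, and the spread of the lognormal
#' species-abundance distribution.
#'
#' @param marker method label.
#' @param S species pool size.
#' @param depth reads drawn per subplot sample (multinomial total).
#' @param sigma niche width in meters of elevation (Gaussian response).
#' @param g gradient strength in `[0, 1]`: 1 = pure niche model, 0 = no
#'   elevational structure.
#' @param abund_sigma sdlog of the lognormal species abundance
#'   distribution.
#' @return a named list of class `marker_profile`.
#' @export
marker_profile <- function(marker, S, depth, sigma = 150, g = 0.8,
                           abund_sigma = 1) {
  stopifnot(S >= 1, depth >= 1, sigma > 0, g >= 0, g <= 1, abund_sigma >= 0)
  structure(list(marker = marker, S = as.integer(S),
                 depth = as.integer(depth), sigma = sigma, g = g,
                 abund_sigma = abund_sigma),
            class = "marker_profile")
}

#' Default multi-marker simulation profiles
#'
#' Six profiles emulating the characteristic contrasts between soil eDNA
#' markers: order-of-magnitude differences in OTU richness and read depth
#' (a ribosomal marker with a huge pool and deep sequencing down to an
#' organism-enriched COI fraction with few OTUs and shallow depth), and
#' differing strengths of elevational niche structure (strongest for the
#' 18S/COI-like markers, weak for the 16S/trnL-like ones). Pool sizes and
#' depths are scaled to desk-size computations while preserving the
#' relative magnitudes.
#'
#' @return named list of [marker_profile()] objects.
#' @export
default_marker_profiles <- function() {
  profs <- list(
    marker_profile("16S",      S = 3000, depth = 15000, g = 0.40),
    marker_profile("18S",      S = 1300, depth = 11000, g = 0.90),
    marker_profile("trnL",     S = 6000, depth = 4000,  g = 0.45),
    marker_profile("ITS",      S = 1400, depth = 3000,  g = 0.60),
    marker_profile("COI",      S = 2800, depth = 2000,  g = 0.90),
    marker_profile("COI-spun", S = 600,  depth = 1500,  g = 0.70)
  )
  stats::setNames(profs, vapply(profs, `[[`, character(1), "marker"))
}

#' Synthetic metacommunity configuration
#'
#' @param n_plots number of plots; ignored when `elevations` is given.
#' @param subplots_per_plot subplots sampled per plot (soil cores).
#' @param elevations named numeric vector of plot elevations (m); default
#'   the ten [table1_fixture()] plots.
#' @param profiles named list of [marker_profile()]s; default
#'   [default_marker_profiles()].
#' @param temp_intercept,temp_slope,temp_sd environment collinearity spec:
#'   temperature is generated as
#'   `temp_intercept + temp_slope * elevation + N(0, temp_sd)`. The default
#'   slope/intercept track the fixture's observed lapse rate.
#' @param seed RNG seed; the same config and seed give identical output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plots = 10, subplots_per_plot = 2,
                             elevations = NULL,
                             profiles = default_marker_profiles(),
                             temp_intercept = 15.53, temp_slope = -0.00518,
                             temp_sd = 0.15, seed = 1) {
  if (is.null(elevations)) {
    fix <- table1_fixture()
    elevations <- stats::setNames(fix$elevation, fix$plot_id)[
      seq_len(min(n_plots, 10L))]
  }
  if (is.null(names(elevations))) {
    names(elevations) <- paste0("Plot", seq_along(elevations))
  }
  stopifnot(subplots_per_plot >= 1, length(elevations) >= 2)
  if (!length(profiles) || is.null(names(profiles))) {
    stop("`profiles` must be a named list of marker_profile objects",
         call. = FALSE)
  }
  structure(
    list(elevations = elevations, n_plots = length(elevations),
         subplots_per_plot = as.integer(subplots_per_plot),
         profiles = profiles, temp_intercept = temp_intercept,
         temp_slope = temp_slope, temp_sd = temp_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Expected relative composition of one marker across plots: species i has a
# Gaussian niche on elevation with optimum mu_i and width sigma, mixed with
# a flat (structureless) component by the gradient strength g, and an
# overall lognormal abundance A_i:
#   E[abundance of i in plot s] ~ A_i * (g * exp(-(e_s - mu_i)^2 / (2 sigma^2)) + (1 - g))
marker_expected_composition <- function(elevations, profile) {
  S <- profile$S
  mu <- stats::runif(S, min(elevations), max(elevations))
  A <- stats::rlnorm(S, 0, profile$abund_sigma)
  lambda <- sapply(seq_along(elevations), function(s) {
    resp <- profile$g * exp(-(elevations[s] - mu)^2 /
                              (2 * profile$sigma^2)) + (1 - profile$g)
    A * resp
  })
  lambda <- t(lambda)  # plots x species
  rownames(lambda) <- names(elevations)
  list(mu = mu, A = A, lambda = lambda)
}

#' Simulate a multi-marker gradient metacommunity
#'
#' Generates, for each marker profile, a subplot-level community matrix
#' along an elevational gradient, plus a plot-level environment table with
#' planted collinearity, and the generating truth for parameter-recovery
#' tests. Species niches are Gaussian in elevation; subplot read vectors
#' are multinomial draws at the profile's depth from the plot's expected
#' composition. Two randomly chosen subplot codes (letters A-P) are sampled
#' per plot, mirroring a two-soil-cores-per-plot design.
#'
#' The environment table contains the latent driver (elevation), a
#' temperature collinear with it, a correlated soil-fertility block
#' (electrical conductivity, organic carbon, total nitrogen, ammonium,
#' water content sharing one latent factor), independent nuisance variables
#' (slope, aspect, pH, Olsen phosphorus, nitrate, C/N ratio), and the
#' sin/cos aspect decomposition inputs.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_metacommunity`:
#'   `communities` (named list of [community_matrix()]),
#'   `env` (raw data frame, one row per plot),
#'   `truth` (per-marker `mu`, `A`, expected plot compositions, and the
#'   config).
#' @export
simulate_gradient_metacommunity <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    e <- config$elevations
    nsub <- config$subplots_per_plot
    communities <- list()
    truth <- list()
    for (nm in names(config$profiles)) {
      prof <- config$profiles[[nm]]
      comp <- marker_expected_composition(e, prof)
      rows <- list()
      ids <- character(0)
      plots <- character(0)
      subplots <- character(0)
      for (s in seq_along(e)) {
        codes <- sort(sample(LETTERS[1:16], nsub))
        for (code in codes) {
          rows[[length(rows) + 1L]] <-
            as.numeric(stats::rmultinom(1, prof$depth, comp$lambda[s, ]))
          sid <- paste0(names(e)[s], "-", code)
          ids <- c(ids, sid)
          plots <- c(plots, names(e)[s])
          subplots <- c(subplots, code)
        }
      }
      counts <- do.call(rbind, rows)
      dimnames(counts) <- list(ids, paste0(nm, "_otu", seq_len(prof$S)))
      keep <- colSums(counts) > 0  # unobserved species carry no information
      communities[[nm]] <- community_matrix(
        counts[, keep, drop = FALSE], marker = nm,
        plots = stats::setNames(plots, ids),
        subplots = stats::setNames(subplots, ids))
      truth[[nm]] <- list(mu = comp$mu, A = comp$A, lambda = comp$lambda)
    }
    n <- length(e)
    fert <- stats::rnorm(n)  # latent soil-fertility factor
    env <- data.frame(
      plot_id = names(e),
      elevation = as.numeric(e),
      temperature = config$temp_intercept + config$temp_slope * e +
        stats::rnorm(n, 0, config$temp_sd),
      slope = stats::runif(n, 2, 45),
      aspect = stats::runif(n, 0, 360),
      pH = stats::rnorm(n, 5.6, 0.4),
      Olsen.P = stats::rlnorm(n, log(8), 0.5),
      EC = exp(0.8 * fert + stats::rnorm(n, log(12), 0.2)),
      Organic.C = exp(0.8 * fert + stats::rnorm(n, log(9), 0.2)),
      Total.N = exp(0.8 * fert + stats::rnorm(n, log(0.6), 0.2)),
      NO3.N = stats::rlnorm(n, log(4), 0.5),
      NH4.N = exp(0.8 * fert + stats::rnorm(n, log(6), 0.3)),
      Water.Content = stats::plogis(0.8 * fert + stats::rnorm(n, 0, 0.3)),
      row.names = names(e)
    )
    env$C.N.ratio <- env$Organic.C / env$Total.N
    structure(
      list(communities = communities, env = env,
           truth = c(truth, list(config = config))),
      class = "synthetic_metacommunity"
    )
  })
}

#' @export
print.synthetic_metacommunity <- function(x, ...) {
  cat(sprintf("Synthetic metacommunity: %d markers, %d plots x %d subplots\n",
              length(x$communities), x$truth$config$n_plots,
              x$truth$config$subplots_per_plot))
  for (nm in names(x$communities)) {
    cm <- x$communities[[nm]]
    cat(sprintf("  %-10s %d OTUs, grand total %s reads\n", nm,
                ncol(cm$counts), format(sum(cm$counts), big.mark = ",")))
  }
  invisible(x)
}

#' Simulate a structureless community
#'
#' The null counterpart of [simulate_gradient_metacommunity()]: every
#' sample draws from the same lognormal species-abundance distribution, so
#' composition carries no plot or elevation signal (a "birds-like"
#' dataset). Useful for type-I-error calibration of the permutation tests.
#'
#' @param n_plots,subplots_per_plot sampling design.
#' @param S species pool size.
#' @param depth reads per sample.
#' @param abund_sigma sdlog of the shared abundance distribution.
#' @param marker method label.
#' @param seed RNG seed.
#' @return a subplot-level [community_matrix()] (plot-level when
#'   `subplots_per_plot = 1`, with plain plot ids).
#' @export
simulate_structureless_community <- function(n_plots = 10,
                                             subplots_per_plot = 1,
                                             S = 200, depth = 5000,
                                             abund_sigma = 1,
                                             marker = "null", seed = NULL) {
  stopifnot(n_plots >= 2, subplots_per_plot >= 1, S >= 1, depth >= 1)
  with_seed(seed, {
    A <- stats::rlnorm(S, 0, abund_sigma)
    plot_ids <- paste0("Plot", seq_len(n_plots))
    if (subplots_per_plot == 1L) {
      ids <- plot_ids
      plots <- stats::setNames(plot_ids, ids)
      subplots <- NULL
    } else {
      ids <- as.vector(t(outer(plot_ids, LETTERS[seq_len(subplots_per_plot)],
                               paste, sep = "-")))
      plots <- stats::setNames(rep(plot_ids, each = subplots_per_plot), ids)
      subplots <- stats::setNames(rep(LETTERS[seq_len(subplots_per_plot)],
                                      n_plots), ids)
    }
    counts <- t(vapply(ids, function(id)
      as.numeric(stats::rmultinom(1, depth, A)), numeric(S)))
    colnames(counts) <- paste0("otu", seq_len(S))
    keep <- colSums(counts) > 0
    community_matrix(counts[, keep, drop = FALSE], marker = marker,
                     plots = plots, subplots = subplots)
  })
}
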