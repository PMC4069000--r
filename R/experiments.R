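#' Scenario specification for the power and estimation studies
#'
#' Bundles everything a study cell needs: the pseudo-observed data
#' configuration (sample size, loci, locus length, diversity, recombination
#' and the true bottleneck), the ABC settings and the simulation sizes.
#' Defaults follow the study design: 750-bp loci, pseudo-observed
#' `rho_bp = 0.01`, bottleneck ending 0.2 coalescent units in the past,
#' Bayes-factor cutoff 3, tolerance 0.001, 1000 replicates and 10^6 prior
#' draws per model.  The full scenario serializes into the run manifest.
#'
#' @param n Sample size (haploid sequences).
#' @param loci Number of loci.
#' @param L Locus length (bp).
#' @param theta_bp Per-bp theta of the pseudo-observed data.
#' @param rho_bp Per-bp rho of the pseudo-observed data.
#' @param bot_end,bot_ne,bot_dur True bottleneck parameters of the
#'   pseudo-observed BNM data.
#' @param timescale Time-scale convention (see [demography()]).
#' @param stat_sets Statistic sets to evaluate (see [stat_set()]).
#' @param tolerance Acceptance proportion.
#' @param cutoff Bayes-factor threshold.
#' @param replicates Pseudo-observed replicates per model.
#' @param draws_per_model Reference-table draws per model.
#' @param prior A [prior_spec()].
#' @param scaling Distance standardization (see [euclidean_distance()]).
#' @param seed Root seed.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(n = 20, loci = 30, L = 750, theta_bp = 0.005,
                     rho_bp = 0.01, bot_end = 0.2, bot_ne = 0.1,
                     bot_dur = 0.1, timescale = "4N",
                     stat_sets = c("TPH", "SFS3", "T+SFS3", "SFS5", "TPH+DH"),
                     tolerance = 0.001, cutoff = 3, replicates = 1000,
                     draws_per_model = 1e6, prior = prior_spec(),
                     scaling = "sd", seed = 1) {
  stopifnot(n >= 2, loci >= 1, L >= 1, replicates >= 1, draws_per_model >= 1)
  if (!(bot_ne > 0 && bot_ne <= 1)) stop("bot_ne must be in (0, 1]")
  for (s in stat_sets) stat_set(s)  # validate names
  structure(as.list(environment()), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: n = %d, loci = %d, L = %d bp, theta = %g/bp, botNe = %g\n",
    x$n, x$loci, x$L, x$theta_bp, x$bot_ne))
  cat(sprintf("  stat sets: %s; tolerance %g; BF cutoff %g; %d replicates\n",
              paste(x$stat_sets, collapse = ", "), x$tolerance, x$cutoff,
              x$replicates))
  invisible(x)
}

#' Wilson 95% score interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return `c(lower, upper)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  lo <- if (k == 0) 0 else max(0, mid - half)
  hi <- if (k == n) 1 else min(1, mid + half)
  c(lo, hi)
}

# Simulate the pseudo-observed replicate summary vectors of one scenario.
# Returns list(bnm = matrix, snm = matrix), replicates x 36.
.pseudo_obs <- function(sc, snm_too = TRUE) {
  reg <- summary_registry()
  tsf <- if (sc$timescale == "2N") 0.5 else 1
  sim_block <- function(bnm, tag) {
    m <- matrix(NA_real_, sc$replicates, length(reg),
                dimnames = list(NULL, reg))
    for (r in seq_len(sc$replicates)) {
      set.seed(spawn_seed(sc$seed, if (bnm) 1L else 2L, r))
      m[r, ] <- .sim_summary(as.integer(sc$n), as.integer(sc$L),
                             as.integer(sc$loci), sc$theta_bp, sc$rho_bp,
                             bnm, sc$bot_end * tsf, sc$bot_ne,
                             sc$bot_dur * tsf)
    }
    m
  }
  list(bnm = sim_block(TRUE), snm = if (snm_too) sim_block(FALSE) else NULL)
}

# Bayes factors for each pseudo-observed row against the pooled table.
.replicate_bfs <- function(table, obs_mat, set, tolerances, scaling) {
  cols <- stat_set(set)
  sims <- as.matrix(table[, cols, drop = FALSE])
  obs_mat <- obs_mat[, cols, drop = FALSE]
  if (scaling == "sd") {  # standardize once, not per replicate
    s <- apply(sims, 2, sd)
    s[!is.finite(s) | s == 0] <- 1
    sims <- sweep(sims, 2, s, "/")
    obs_mat <- sweep(obs_mat, 2, s, "/")
  }
  is_bnm <- table$model == "BNM"
  ks <- round(tolerances * nrow(sims))
  if (any(ks < 1)) stop("tolerance yields zero acceptances for this table size")
  bf <- matrix(NA_real_, nrow(obs_mat), length(tolerances))
  for (r in seq_len(nrow(obs_mat))) {
    d <- euclidean_distance(obs_mat[r, ], sims, scaling = "none")
    o <- order(d)
    for (j in seq_along(ks)) {
      acc <- o[seq_len(ks[j])]
      kb <- sum(is_bnm[acc])
      bf[r, j] <- if (kb == ks[j]) Inf else kb / (ks[j] - kb)
    }
  }
  bf
}

#' Power and false-positive rate of ABC model choice for one scenario
#'
#' For each of the scenario's `replicates` pseudo-observed datasets
#' simulated under the true BNM (and, for the false-positive rate, under the
#' SNM), performs the rejection step against the pooled two-model reference
#' table, computes the Bayes factor BNM:SNM and applies the cutoff.  Power
#' is the proportion of BNM-true replicates with BF >= cutoff; the FPR is
#' the same proportion among SNM-true replicates.
#'
#' @param sc A [scenario()].
#' @param table A [reference_table] matching the scenario's `n` and `loci`;
#'   built from the scenario (at `draws_per_model`) if omitted.
#' @param verbose Print progress.
#' @return A `"power_result"` data frame with one row per statistic set:
#'   power and FPR with Wilson 95% intervals.  Replicate-level Bayes factors
#'   are retained in attribute `bf`.
#' @export
run_power_scenario <- function(sc, table = NULL, verbose = FALSE) {
  if (is.null(table)) {
    if (verbose) message("building reference table ...")
    table <- build_reference_table(sc$n, sc$loci, sc$L,
                                   draws_per_model = sc$draws_per_model,
                                   prior = sc$prior, bot_dur = sc$bot_dur,
                                   timescale = sc$timescale,
                                   seed = spawn_seed(sc$seed, 0L),
                                   verbose = verbose)
  }
  obs <- .pseudo_obs(sc)
  res <- .power_table(sc, table, obs, sc$tolerance)
  res$tolerance <- NULL
  res
}

# shared by run_power_scenario and tolerance_sweep
.power_table <- function(sc, table, obs, tolerances) {
  rows <- list()
  bfs <- list()
  for (set in sc$stat_sets) {
    bf_b <- .replicate_bfs(table, obs$bnm, set, tolerances, sc$scaling)
    bf_s <- .replicate_bfs(table, obs$snm, set, tolerances, sc$scaling)
    for (j in seq_along(tolerances)) {
      kp <- sum(bf_b[, j] >= sc$cutoff)
      kf <- sum(bf_s[, j] >= sc$cutoff)
      R <- sc$replicates
      wp <- wilson_interval(kp, R)
      wf <- wilson_interval(kf, R)
      rows[[length(rows) + 1]] <- data.frame(
        stat_set = set, tolerance = tolerances[j],
        power = kp / R, power_lo = wp[1], power_hi = wp[2],
        fpr = kf / R, fpr_lo = wf[1], fpr_hi = wf[2],
        replicates = R)
    }
    bfs[[set]] <- list(bnm = bf_b, snm = bf_s)
  }
  out <- do.call(rbind, rows)
  attr(out, "bf") <- bfs
  attr(out, "scenario") <- sc
  class(out) <- c("power_result", "data.frame")
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat("ABC model-choice power study\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Power as a function of the rejection tolerance
#'
#' Re-evaluates model choice for several tolerance levels, reusing a single
#' reference table and a single batch of pseudo-observed replicates (the
#' replicate seeds are shared across tolerances).
#'
#' @param sc A [scenario()].
#' @param tolerances Tolerance levels in (0, 1].
#' @param table Optional pre-built [reference_table].
#' @return A `"power_result"` with one row per (statistic set, tolerance).
#' @export
tolerance_sweep <- function(sc, tolerances = c(0.1, 0.01, 0.005, 0.001),
                            table = NULL) {
  stopifnot(all(tolerances > 0 & tolerances <= 1))
  if (is.null(table))
    table <- build_reference_table(sc$n, sc$loci, sc$L,
                                   draws_per_model = sc$draws_per_model,
                                   prior = sc$prior, bot_dur = sc$bot_dur,
                                   timescale = sc$timescale,
                                   seed = spawn_seed(sc$seed, 0L))
  obs <- .pseudo_obs(sc)
  .power_table(sc, table, obs, tolerances)
}

#' Power over a grid of sample sizes and locus counts
#'
#' Runs [run_power_scenario()] for every (n, loci) cell of a grid, building
#' one reference table per cell, and reports power against the n x loci
#' product (a proxy for sequencing cost).
#'
#' @param n_values Sample sizes.
#' @param loci_values Locus counts.
#' @param sc Scenario template (its `n` and `loci` are overridden).
#' @param verbose Print progress.
#' @return A data frame with one row per (cell, statistic set).
#' @export
dataset_size_grid <- function(n_values, loci_values, sc, verbose = FALSE) {
  stopifnot(length(n_values) >= 1, length(loci_values) >= 1)
  rows <- list()
  for (n in n_values) for (loci in loci_values) {
    cell <- sc
    cell$n <- n
    cell$loci <- loci
    cell$seed <- spawn_seed(sc$seed, 3L, n, loci)
    if (verbose) message(sprintf("grid cell n = %d, loci = %d", n, loci))
    pr <- run_power_scenario(cell)
    pr$n <- n
    pr$loci <- loci
    pr$n_x_loci <- n * loci
    rows[[length(rows) + 1]] <- as.data.frame(pr)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Parameter-estimation accuracy study under the bottleneck model
#'
#' For each replicate, simulates a pseudo-observed dataset at the scenario's
#' true BNM parameters, fits the ABC posterior ([abc_fit()]) on the BNM rows
#' of the reference table for each statistic set, and records the posterior
#' mean of each parameter.  Reports the mean posterior mean, relative bias,
#' relative RMSE and coverage of the central 10%/50%/90% credible intervals.
#'
#' @param sc A [scenario()]; its `theta_bp`, `bot_end`, `bot_ne` are the
#'   true values (must lie strictly inside the prior).
#' @param table Optional pre-built [reference_table].
#' @param method `"loclinear"` or `"rejection"`.
#' @param params Parameters to assess.
#' @param verbose Print progress.
#' @return An `"estimation_result"` data frame, one row per (statistic set,
#'   parameter); per-replicate posterior means are kept in attribute
#'   `estimates`.
#' @export
run_estimation_study <- function(sc, table = NULL,
                                 method = c("loclinear", "rejection"),
                                 params = c("theta", "bot_end", "bot_ne"),
                                 verbose = FALSE) {
  method <- match.arg(method)
  truth <- c(theta = sc$theta_bp, rho = sc$rho_bp, bot_end = sc$bot_end,
             bot_ne = sc$bot_ne)[params]
  pr <- sc$prior
  for (p in params) {
    b <- pr[[if (p == "theta") "theta" else p]]
    if (truth[p] <= b[1] || truth[p] >= b[2])
      stop("true value of ", p, " must lie strictly inside its prior")
  }
  if (is.null(table))
    table <- build_reference_table(sc$n, sc$loci, sc$L,
                                   draws_per_model = sc$draws_per_model,
                                   prior = sc$prior, bot_dur = sc$bot_dur,
                                   timescale = sc$timescale,
                                   seed = spawn_seed(sc$seed, 0L))
  bnm <- table[table$model == "BNM", , drop = FALSE]
  obs <- .pseudo_obs(sc, snm_too = FALSE)$bnm
  sets <- sc$stat_sets
  est <- array(NA_real_, c(sc$replicates, length(params), length(sets)),
               dimnames = list(NULL, params, sets))
  cover <- array(0, c(3, length(params), length(sets)),
                 dimnames = list(c("10", "50", "90"), params, sets))
  fallbacks <- setNames(integer(length(sets)), sets)
  for (r in seq_len(sc$replicates)) {
    for (set in sets) {
      fit <- abc_fit(obs[r, stat_set(set)], bnm, tolerance = sc$tolerance,
                     method = method, model = "BNM", scaling = sc$scaling,
                     param_cols = params)
      est[r, , set] <- coef(fit)[params]
      if (fit$fallback) fallbacks[set] <- fallbacks[set] + 1L
      for (lv in c(0.1, 0.5, 0.9)) {
        for (p in params) {
          ci <- credible_interval(fit, p, level = lv)
          if (truth[p] >= ci[1] && truth[p] <= ci[2])
            cover[sprintf("%d", lv * 100), p, set] <-
              cover[sprintf("%d", lv * 100), p, set] + 1
        }
      }
    }
    if (verbose && r %% 50 == 0)
      message(sprintf("  estimation replicate %d / %d", r, sc$replicates))
  }
  rows <- list()
  for (set in sets) for (p in params) {
    e <- est[, p, set]
    am <- accuracy_metrics(e, truth[p])
    rows[[length(rows) + 1]] <- data.frame(
      stat_set = set, parameter = p, true = unname(truth[p]),
      mean_estimate = mean(e), rbias = unname(am["rbias"]),
      rrmse = unname(am["rrmse"]),
      cover10 = cover["10", p, set] / sc$replicates,
      cover50 = cover["50", p, set] / sc$replicates,
      cover90 = cover["90", p, set] / sc$replicates)
  }
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- est
  attr(out, "fallbacks") <- fallbacks
  attr(out, "scenario") <- sc
  class(out) <- c("estimation_result", "data.frame")
  out
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("ABC parameter-estimation study (bottleneck model)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
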