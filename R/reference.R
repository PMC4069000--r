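#' @name reference_table
#' @title Reference tables
#' @description A reference table is a data frame with one row per prior
#'   simulation: a `model` label column, the parameter columns `theta`,
#'   `rho`, `bot_end`, `bot_ne` (the latter two `NA` for SNM rows) and the
#'   36 summary-statistic columns of [summary_registry()].  Tables from both
#'   models are pooled for model choice; the tolerance is a proportion of
#'   the pooled table unless a single model's rows are subset first.
NULL

# fast internal path: simulate one dataset and return its summary vector
.sim_summary <- function(n, L, loci, theta_bp, rho_bp, bnm, bot_end, bot_ne,
                         bot_dur, pooled_sfs = FALSE) {
  raw <- cpp_simulate_dataset(n, L, loci, theta_bp, rho_bp,
                              bnm, bot_end, bot_dur, bot_ne)
  summary_vector(cpp_dataset_stats(raw, n, L), pooled_sfs = pooled_sfs)
}

#' Build a two-model ABC reference table
#'
#' Draws `draws_per_model` parameter vectors from the priors for each of the
#' SNM and BNM, simulates a multi-locus dataset for each draw, and stores
#' its full summary vector.  Each row uses a child seed derived from `seed`
#' with [spawn_seed()], so any single row can be reproduced in isolation.
#'
#' @param n Sample size (haploid sequences) of the datasets to emulate.
#' @param loci Number of loci per dataset.
#' @param L Locus length (bp).
#' @param draws_per_model Prior draws per model.
#' @param prior A [prior_spec()].
#' @param bot_dur Fixed bottleneck duration (coalescent units).
#' @param timescale `"4N"` or `"2N"` (see [demography()]).
#' @param seed Root seed; `NULL` uses the current RNG state (not
#'   row-reproducible).
#' @param pooled_sfs See [summary_vector()].
#' @param verbose Print progress.
#' @return A `"reference_table"` data frame (see [reference_table]).
#' @export
build_reference_table <- function(n, loci, L = 750, draws_per_model = 1000,
                                  prior = prior_spec(), bot_dur = 0.1,
                                  timescale = c("4N", "2N"), seed = NULL,
                                  pooled_sfs = FALSE, verbose = FALSE) {
  timescale <- match.arg(timescale)
  stopifnot(draws_per_model >= 1, loci >= 1)
  tsf <- if (timescale == "2N") 0.5 else 1
  n <- as.integer(n); L <- as.integer(L); loci <- as.integer(loci)
  total <- 2L * as.integer(draws_per_model)
  reg <- summary_registry()
  stats <- matrix(NA_real_, total, length(reg), dimnames = list(NULL, reg))
  pars <- matrix(NA_real_, total, 4,
                 dimnames = list(NULL, c("theta", "rho", "bot_end", "bot_ne")))
  model <- rep(c("SNM", "BNM"), each = draws_per_model)
  u <- function(b) runif(1, b[1], b[2])
  for (i in seq_len(total)) {
    if (!is.null(seed)) set.seed(spawn_seed(seed, i))
    bnm <- model[i] == "BNM"
    th <- u(prior$theta); rh <- u(prior$rho)
    pars[i, 1:2] <- c(th, rh)
    if (bnm) {
      be <- u(prior$bot_end); bn <- u(prior$bot_ne)
      pars[i, 3:4] <- c(be, bn)
      stats[i, ] <- .sim_summary(n, L, loci, th, rh, TRUE,
                                 be * tsf, bn, bot_dur * tsf,
                                 pooled_sfs = pooled_sfs)
    } else {
      stats[i, ] <- .sim_summary(n, L, loci, th, rh, FALSE, 0, 1, 0,
                                 pooled_sfs = pooled_sfs)
    }
    if (verbose && i %% 5000 == 0)
      message(sprintf("  reference table: %d / %d rows", i, total))
  }
  out <- data.frame(model = model, pars, stats, check.names = FALSE)
  attr(out, "stat_names") <- reg
  attr(out, "n") <- n
  attr(out, "loci") <- loci
  attr(out, "L") <- L
  attr(out, "bot_dur") <- bot_dur
  attr(out, "timescale") <- timescale
  class(out) <- c("reference_table", "data.frame")
  out
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf(
    "ABC reference table: %d rows (%s), n = %s, loci = %s, %d statistics\n",
    nrow(x), paste(sprintf("%s: %d", names(table(x$model)), table(x$model)),
                   collapse = ", "),
    attr(x, "n"), attr(x, "loci"), length(attr(x, "stat_names"))))
  invisible(x)
}
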