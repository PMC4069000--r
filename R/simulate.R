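#' Demographic model specification
#'
#' Defines the demography under which coalescent genealogies are generated.
#' Two models are supported: `"SNM"`, a constant-size standard neutral model,
#' and `"BNM"`, in which the population shrinks instantaneously to a relative
#' size `bot_ne` at time `bot_end` in the past (looking backwards), stays at
#' that size for `bot_dur` time units and then returns to the ancestral size
#' (fixed at 1, the present-day size).
#'
#' Times are in coalescent units.  Under the default `timescale = "4N"` one
#' unit is 4N generations (the ms convention, with theta = 4N mu and
#' rho = 4N r); `timescale = "2N"` reinterprets all input times as units of
#' 2N generations, i.e. halves them internally.
#'
#' @param model `"SNM"` or `"BNM"`.
#' @param bot_end Time of the bottleneck end, backwards from the present
#'   (coalescent units).  Ignored for SNM.
#' @param bot_ne Relative effective population size during the bottleneck,
#'   in (0, 1].  `bot_ne = 1` is degenerate with the SNM.
#' @param bot_dur Duration of the bottleneck (coalescent units).
#' @param timescale `"4N"` (default) or `"2N"`; declares the unit in which
#'   `bot_end` and `bot_dur` are expressed.
#' @return An object of class `"demography"`.
#' @examples
#' demography("BNM", bot_end = 0.2, bot_ne = 0.1)
#' @export
demography <- function(model = c("SNM", "BNM"), bot_end = 0.2, bot_ne = 0.1,
                       bot_dur = 0.1, timescale = c("4N", "2N")) {
  model <- match.arg(model)
  timescale <- match.arg(timescale)
  if (model == "BNM") {
    stopifnot(bot_end >= 0, bot_dur > 0)
    if (!(bot_ne > 0 && bot_ne <= 1))
      stop("bot_ne must be in (0, 1]")
  }
  structure(
    list(model = model,
         bot_end = if (model == "BNM") bot_end else NA_real_,
         bot_ne = if (model == "BNM") bot_ne else NA_real_,
         bot_dur = if (model == "BNM") bot_dur else NA_real_,
         timescale = timescale),
    class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  if (x$model == "SNM") {
    cat("Standard neutral model (constant size)\n")
  } else {
    cat(sprintf(
      "Bottleneck model: size %g during [%g, %g) back in time (%s units)\n",
      x$bot_ne, x$bot_end, x$bot_end + x$bot_dur, x$timescale))
  }
  invisible(x)
}

# internal: times rescaled to the simulator's native 4N units
.times_4N <- function(dem) {
  f <- if (dem$timescale == "2N") 0.5 else 1
  list(bot_end = dem$bot_end * f, bot_dur = dem$bot_dur * f)
}

#' Uniform prior bounds for model parameters
#'
#' Defaults follow the study design: per-bp theta ~ U(0, 0.01) and per-bp
#' rho ~ U(0, 0.02) under both models; for the bottleneck model the end time
#' bot_end ~ U(0, 1.5) and relative size bot_ne ~ U(0, 1).
#'
#' @param theta,rho,bot_end,bot_ne Numeric length-2 `c(lower, upper)` bounds.
#' @return An object of class `"prior_spec"`: a named list of bounds.
#' @export
prior_spec <- function(theta = c(0, 0.01), rho = c(0, 0.02),
                       bot_end = c(0, 1.5), bot_ne = c(0, 1)) {
  pr <- list(theta = theta, rho = rho, bot_end = bot_end, bot_ne = bot_ne)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
      stop("malformed bounds for ", nm, ": need c(lower, upper), lower < upper")
  }
  if (pr$bot_ne[2] > 1) stop("bot_ne upper bound must be <= 1")
  if (pr$theta[1] < 0 || pr$rho[1] < 0) stop("rates must be non-negative")
  structure(pr, class = "prior_spec")
}

#' Draw parameter vectors from the prior
#'
#' Draws `n_draws` independent parameter vectors for the given model.  SNM
#' draws carry only `theta` and `rho`; BNM draws add `bot_end` and `bot_ne`.
#'
#' @param model `"SNM"` or `"BNM"`.
#' @param prior A [prior_spec()].
#' @param n_draws Number of draws.
#' @return A data frame with one row per draw and a `model` column.
#' @export
draw_from_prior <- function(model = c("SNM", "BNM"), prior = prior_spec(),
                            n_draws = 1) {
  model <- match.arg(model)
  if (!inherits(prior, "prior_spec")) stop("prior must be a prior_spec")
  u <- function(b) runif(n_draws, b[1], b[2])
  out <- data.frame(model = rep(model, n_draws),
                    theta = u(prior$theta),
                    rho = u(prior$rho))
  if (model == "BNM") {
    out$bot_end <- u(prior$bot_end)
    out$bot_ne <- u(prior$bot_ne)
  }
  out
}

#' Simulate one locus under the coalescent with recombination
#'
#' Generates the genealogy of `n` haploid sequences at a locus of `L` base
#' pairs by Hudson's coalescent with recombination (an ancestral
#' recombination graph) and drops infinite-sites mutations on it.  Per-locus
#' intensities are `theta_bp * L` for mutation and `rho_bp * (L - 1)` for
#' recombination.  During the bottleneck epoch the coalescence rate is
#' multiplied by `1 / bot_ne`.
#'
#' @param n Number of sampled haploid sequences (2..64).
#' @param L Locus length in base pairs.
#' @param theta_bp Per-bp scaled mutation rate.
#' @param rho_bp Per-bp scaled recombination rate.
#' @param dem A [demography()].
#' @return A `"haplotype_matrix"`: list with `positions` (strictly increasing
#'   in (0,1)) and `states` (an `n` x S 0/1 matrix, 1 = derived), plus `n`
#'   and `L`.
#' @examples
#' set.seed(1)
#' h <- simulate_locus(5, 750, theta_bp = 0.005, rho_bp = 0.01,
#'                     dem = demography("SNM"))
#' @export
simulate_locus <- function(n, L, theta_bp, rho_bp = 0, dem = demography("SNM")) {
  simulate_dataset(n, loci = 1, L = L, theta_bp = theta_bp, rho_bp = rho_bp,
                   dem = dem)[[1]]
}

#' Simulate a multi-locus dataset
#'
#' Simulates `loci` independent loci sharing `n`, `L` and the demographic
#' model.  Reproducible under [set.seed()].
#'
#' @inheritParams simulate_locus
#' @param loci Number of unlinked loci.
#' @return A `"dataset"`: list of haplotype matrices with attributes `n` and
#'   `L`.
#' @export
simulate_dataset <- function(n, loci, L, theta_bp, rho_bp = 0,
                             dem = demography("SNM")) {
  if (!inherits(dem, "demography")) stop("dem must be a demography")
  if (loci < 1) stop("loci must be >= 1")
  bn <- dem$model == "BNM"
  t4 <- .times_4N(dem)
  raw <- cpp_simulate_dataset(as.integer(n), as.integer(L), as.integer(loci),
                              theta_bp, rho_bp, bn,
                              if (bn) t4$bot_end else 0,
                              if (bn) t4$bot_dur else 0,
                              if (bn) dem$bot_ne else 1)
  ds <- lapply(raw, function(x) {
    structure(list(positions = x$positions, states = x$states, n = n, L = L),
              class = "haplotype_matrix")
  })
  structure(ds, n = n, L = L, class = "dataset")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype matrix: n = %d, L = %d bp, %d segregating sites\n",
              x$n, x$L, length(x$positions)))
  invisible(x)
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("dataset: %d loci, n = %d, L = %d bp, mean S = %.2f\n",
              length(x), attr(x, "n"), attr(x, "L"),
              mean(vapply(x, function(h) length(h$positions), 0))))
  invisible(x)
}

#' Deterministic child seeds
#'
#' Derives a reproducible child seed from a root seed and an index path, so
#' that any (scenario, replicate) unit can be re-run in isolation.  Uses a
#' multiplicative integer hash; results are in `[0, 2^31 - 2]`.
#'
#' @param root Integer root seed.
#' @param ... Further integer indices identifying the stream.
#' @return A single integer seed.
#' @export
spawn_seed <- function(root, ...) {
  idx <- c(root, ...)
  h <- 0
  for (v in idx) {
    h <- (h * 69069 + (as.numeric(v) %% 2147483647) + 12345) %% 2147483647
    h <- (h * 1103515245 + 54321) %% 2147483647
  }
  as.integer(h)
}
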