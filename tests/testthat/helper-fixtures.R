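# Shared fixtures built in code.

# Four-haplotype, three-site locus with derived counts 3, 2, 1:
#   h1 = 000, h2 = 100, h3 = 110, h4 = 111
fixture_m4 <- function() {
  structure(list(
    positions = c(0.1, 0.4, 0.7),
    states = matrix(c(0L, 1L, 1L, 1L,
                      0L, 0L, 1L, 1L,
                      0L, 0L, 0L, 1L), nrow = 4),
    n = 4L, L = 750L), class = "haplotype_matrix")
}

fixture_dataset <- function(loci = list(fixture_m4())) {
  structure(loci, n = loci[[1]]$n, L = loci[[1]]$L, class = "dataset")
}

# random 0/1 matrix wrapped as a haplotype matrix (may contain fixed columns)
random_hapmat <- function(n = 6, S = 10, L = 500) {
  structure(list(positions = sort(runif(S)),
                 states = matrix(rbinom(n * S, 1, 0.4), n, S),
                 n = n, L = L), class = "haplotype_matrix")
}

# tiny two-model reference table with synthetic (non-simulated) statistics,
# for exercising the ABC machinery in isolation
synthetic_table <- function(rows_per_model = 100, seed = 1) {
  set.seed(seed)
  n <- 2 * rows_per_model
  model <- rep(c("SNM", "BNM"), each = rows_per_model)
  theta <- runif(n, 0, 0.01)
  tab <- data.frame(model = model, theta = theta, rho = runif(n, 0, 0.02),
                    bot_end = ifelse(model == "BNM", runif(n, 0, 1.5), NA),
                    bot_ne = ifelse(model == "BNM", runif(n, 0, 1), NA))
  tab$thetaW <- theta + rnorm(n, 0, 1e-4)
  tab$thetaPi <- theta + rnorm(n, 0, 1e-4)
  tab$He <- runif(n)
  tab
}

# memoised mid-scale simulated reference tables shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached_reference_table <- function(n, loci, draws_per_model, seed = 20240601) {
  key <- sprintf("tab_%d_%d_%d", n, loci, draws_per_model)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_reference_table(
      n, loci, draws_per_model = draws_per_model, seed = seed)
  }
  .fixture_cache[[key]]
}

# Acceptance-scale shared tables (built once per test session; the power and
# estimation criteria reuse them).  Sizes chosen so the whole suite stays
# desk-scale: 2.5e4 draws/model for the large design, 1.25e4 for the small.
acceptance_table_large <- function() {
  cached_reference_table(20, 30, 25000, seed = 77001)
}

acceptance_table_small <- function() {
  cached_reference_table(10, 15, 12500, seed = 77002)
}
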