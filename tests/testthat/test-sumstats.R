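test_that("per-locus statistics match hand computations on the M4 fixture", {
  m4 <- fixture_m4()
  expect_identical(seg_sites(m4), 3L)
  expect_equal(theta_w(m4), 3 / ((1 + 1/2 + 1/3) * 750))
  expect_equal(theta_pi(m4), (10 / 6) / 750)
  expect_equal(theta_h(m4), (28 / 12) / 750)
  expect_equal(fay_wu_h(m4), 10 / 6 - 28 / 12)
  expect_equal(haplotype_diversity(m4), 1)
  expect_equal(tajima_d(m4), 0.1676558, tolerance = 1e-6)
})

test_that("degenerate matrices behave as specified", {
  empty <- structure(list(positions = numeric(0),
                          states = matrix(0L, 4, 0), n = 4L, L = 750L),
                     class = "haplotype_matrix")
  expect_identical(seg_sites(empty), 0L)
  expect_equal(theta_w(empty), 0)
  expect_true(is.na(tajima_d(empty)))
  expect_true(is.na(fay_wu_h(empty)))
  expect_equal(haplotype_diversity(empty), 0)

  # a fixed column (derived in all samples) is not segregating
  fixed <- fixture_m4()
  fixed$states <- cbind(fixed$states, 1L)
  expect_identical(seg_sites(fixed), 3L)

  # n = 2: a site with S = 7 gives thetaW = 7 / 750 (a_2 = 1)
  two <- structure(list(positions = sort(runif(7)),
                        states = rbind(rep(0L, 7), rep(1L, 7)),
                        n = 2L, L = 750L), class = "haplotype_matrix")
  expect_equal(theta_w(two), 7 / 750)
})

test_that("closed forms hold for singleton-only and 50/50 matrices", {
  n <- 6; S <- 4
  singles <- matrix(0L, n, S)
  singles[1, ] <- 1L
  h <- structure(list(positions = sort(runif(S)), states = singles,
                      n = n, L = 100L), class = "haplotype_matrix")
  expect_equal(theta_h(h), 2 * S / (n * (n - 1) * 100))
  expect_gt(fay_wu_h(h), 0)

  half <- structure(list(positions = 0.5,
                         states = matrix(c(1L, 1L, 0L, 0L), 4, 1),
                         n = 4L, L = 100L), class = "haplotype_matrix")
  expect_equal(haplotype_diversity(half), (4 / 3) * 0.5)
})

test_that("frequency-weighted pi equals brute-force pairwise enumeration", {
  brute_pi <- function(m, L) {
    n <- nrow(m)
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
    tot / choose(n, 2) / L
  }
  set.seed(42)
  for (rep in 1:200) {
    h <- random_hapmat(n = sample(3:8, 1), S = sample(0:12, 1))
    # drop non-segregating columns for the brute-force sum too
    dc <- colSums(h$states)
    keep <- dc >= 1 & dc <= nrow(h$states) - 1
    m <- h$states[, keep, drop = FALSE]
    expect_equal(theta_pi(h), brute_pi(m, h$L))
  }
})

test_that("folded SFS bins are correct, normalized, and fold-invariant", {
  expect_equal(folded_sfs_bins(fixture_dataset(), 3), c(0, 2/3, 1/3))
  # relabeling ancestral/derived leaves folded bins unchanged
  set.seed(7)
  for (rep in 1:50) {
    h <- random_hapmat(n = 7, S = 9)
    flipped <- h
    flipped$states <- 1L - h$states
    for (k in c(3, 5)) {
      b <- folded_sfs_bins(list(h), k)
      expect_equal(b, folded_sfs_bins(list(flipped), k))
      if (is.null(attr(b, "degenerate"))) expect_equal(sum(b), 1)
    }
  }
  # n = 2: every site has minor frequency 0.5, the last bin
  two <- structure(list(positions = c(0.2, 0.6),
                        states = rbind(c(1L, 0L), c(0L, 1L)),
                        n = 2L, L = 100L), class = "haplotype_matrix")
  expect_equal(folded_sfs_bins(list(two), 3), c(0, 0, 1))
  # no segregating site anywhere -> zero vector with flag
  empty <- structure(list(positions = numeric(0),
                          states = matrix(0L, 4, 0), n = 4L, L = 750L),
                     class = "haplotype_matrix")
  b <- folded_sfs_bins(list(empty), 3)
  expect_equal(as.numeric(b), c(0, 0, 0))
  expect_true(attr(b, "degenerate"))
})

test_that("cross-locus aggregation follows the exclusion and quantile rules", {
  a <- aggregate_stats(c(1, 2, 3, 4, 5))
  expect_equal(unname(a["mean"]), 3)
  expect_equal(unname(a["sd"]), 1.58114, tolerance = 1e-5)
  expect_equal(unname(a["q5"]), unname(quantile(1:5, 0.05)))

  one <- aggregate_stats(2.5)
  expect_equal(unname(one), c(2.5, 0, 2.5, 2.5))

  excl <- aggregate_stats(c(NA, 0.5, -0.5))
  expect_equal(unname(excl["mean"]), 0)

  deg <- aggregate_stats(c(NA_real_, NA_real_))
  expect_equal(unname(deg), c(0, 0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(deg, "degenerate"))

  expect_true(a["q5"] <= a["q95"])
})

test_that("statistic sets have the documented membership and order", {
  expect_length(stat_set("TPH+DH"), 5)
  expect_length(stat_set("SFS5"), 5)
  expect_length(stat_set("T+SFS3"), 4)
  expect_length(stat_set("ALL"), 31)
  expect_error(stat_set("bogus"), "unknown")
  expect_length(summary_registry(), 36)

  ds <- fixture_dataset()
  v <- summary_vector(ds)
  expect_identical(names(v), summary_registry())
  expect_equal(sum(v[stat_set("SFS5")]), 1)
  expect_equal(unname(v["thetaW"]), theta_w(fixture_m4()))
  expect_equal(unname(v["D_sd"]), 0)  # single locus
  # restriction preserves registry order
  expect_identical(names(build_stat_vector(ds, "TPH+DH")), stat_set("TPH+DH"))
  # determinism: identical loci give identical vectors
  expect_identical(v, summary_vector(fixture_dataset()))
})

test_that("compiled per-locus statistics agree with the R implementations", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    ds <- simulate_dataset(n, 4, 500, theta_bp = 0.01, rho_bp = 0.005,
                           dem = demography("BNM", 0.1, 0.2))
    m <- dataset_stats(ds)
    eq <- function(a, b) expect_equal(unname(a), unname(b), ignore_attr = TRUE)
    for (l in seq_len(4)) {
      h <- ds[[l]]
      eq(m[l, "S"], seg_sites(h))
      eq(m[l, "thetaW"], theta_w(h))
      eq(m[l, "thetaPi"], theta_pi(h))
      eq(m[l, "thetaH"], theta_h(h))
      eq(m[l, "He"], haplotype_diversity(h))
      if (seg_sites(h) > 0) {
        eq(m[l, "D"], tajima_d(h))
        eq(m[l, "H"], fay_wu_h(h))
        eq(m[l, paste0("sfs3_", 1:3)], folded_sfs_bins(list(h), 3))
      } else {
        expect_true(is.na(m[l, "D"]))
      }
    }
  }
})

test_that("theta estimators are all unbiased for theta under the SNM", {
  set.seed(31)
  ds <- simulate_dataset(8, 3000, 500, theta_bp = 0.004, rho_bp = 0)
  m <- dataset_stats(ds)
  for (est in c("thetaW", "thetaPi", "thetaH")) {
    se <- sd(m[, est]) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, est]) - 0.004), 3 * se)
  }
})
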