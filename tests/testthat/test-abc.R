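test_that("euclidean distance is Pythagorean and registry-checked", {
  obs <- c(a = 1, b = 2)
  sims <- matrix(c(1, 2, 4, 6), 2, 2, byrow = FALSE,
                 dimnames = list(NULL, c("a", "b")))
  sims[2, ] <- c(4, 6)  # differs by (3, 4)
  sims[1, ] <- c(1, 2)
  d <- euclidean_distance(obs, sims)
  expect_equal(d, c(0, 5))
  bad <- sims
  colnames(bad) <- c("b", "a")
  expect_error(euclidean_distance(obs, bad), "registries")
})

test_that("sd-standardized distance is invariant to rescaling a statistic", {
  set.seed(2)
  sims <- cbind(a = rnorm(50), b = rnorm(50, sd = 4))
  obs <- c(a = 0.3, b = -1)
  d1 <- euclidean_distance(obs, sims, scaling = "sd")
  sims2 <- sims
  sims2[, "b"] <- sims2[, "b"] * 10
  obs2 <- obs
  obs2["b"] <- obs2["b"] * 10
  expect_equal(d1, euclidean_distance(obs2, sims2, scaling = "sd"))
})

test_that("rejection accepts round(tolerance x rows), with edge cases", {
  tab <- synthetic_table(500)
  obs <- c(thetaW = 0.005, thetaPi = 0.005, He = 0.5)
  rej <- abc_reject(tab, obs, tolerance = 0.1)
  expect_length(rej$accepted, 100)
  expect_true(all(rej$distances[rej$accepted] <= rej$delta))

  all_in <- abc_reject(tab, obs, tolerance = 1)
  expect_length(all_in$accepted, nrow(tab))
  expect_equal(all_in$delta, max(all_in$distances))

  # a row identical to the observation is always accepted
  tab2 <- tab
  tab2[17, c("thetaW", "thetaPi", "He")] <- obs
  rej2 <- abc_reject(tab2, obs, tolerance = 0.002)
  expect_true(17 %in% rej2$accepted)

  expect_error(abc_reject(tab[0, ], obs, 0.1), "empty")
  expect_error(abc_reject(tab, obs, 1e-9), "zero acceptances")
})

test_that("rejection equals an exhaustive sort-by-distance oracle", {
  set.seed(14)
  for (rep in 1:20) {
    tab <- synthetic_table(sample(50:500, 1), seed = rep)
    obs <- c(thetaW = runif(1, 0, 0.01), thetaPi = runif(1, 0, 0.01),
             He = runif(1))
    tol <- sample(c(0.01, 0.05, 0.2, 1), 1)
    for (scaling in c("none", "sd")) {
      rej <- abc_reject(tab, obs, tol, scaling = scaling)
      # oracle: explicit standardization, full distance vector, stable sort
      sims <- as.matrix(tab[, names(obs)])
      oo <- obs
      if (scaling == "sd") {
        sds <- apply(sims, 2, sd)
        sims <- sweep(sims, 2, sds, "/")
        oo <- obs / sds
      }
      d <- sqrt(rowSums(sweep(sims, 2, oo)^2))
      k <- round(tol * nrow(tab))
      oracle <- sort.int(d, index.return = TRUE,
                         method = "radix")$ix[seq_len(k)]
      expect_identical(sort(rej$accepted), sort(oracle))
      expect_equal(rej$delta, sort(d)[k])
    }
  }
})

test_that("model probabilities, Bayes factors, and decisions are consistent", {
  tab <- synthetic_table(500, seed = 3)
  obs <- c(thetaW = 0.005, thetaPi = 0.005, He = 0.5)
  mc <- abc_model_choice(tab, obs, tolerance = 0.1)
  expect_equal(sum(mc$prob), 1)
  expect_equal(mc$bayes_factor, mc$prob["BNM"] / mc$prob["SNM"],
               ignore_attr = TRUE)
  expect_identical(mc$decision, mc$bayes_factor >= 3)

  # 75 of 100 accepted BNM -> BF 3, decision at cutoff 3
  tab2 <- synthetic_table(500, seed = 4)
  d0 <- sqrt(rowSums(sweep(as.matrix(tab2[, names(obs)]), 2, obs)^2))
  keep <- order(d0)[1:100]
  tab3 <- tab2
  tab3$model <- "SNM"
  tab3$model[keep[1:75]] <- "BNM"
  tab3$model[setdiff(seq_len(nrow(tab3)), keep)] <-
    rep(c("SNM", "BNM"), length.out = nrow(tab3) - 100)
  mc2 <- abc_model_choice(tab3, obs, tolerance = 0.1, scaling = "none")
  expect_equal(unname(mc2$prob["BNM"]), 0.75)
  expect_equal(mc2$bayes_factor, 3)
  expect_true(mc2$decision)

  # tolerance 1 on an equal-count table recovers the prior
  mc3 <- abc_model_choice(tab, obs, tolerance = 1)
  expect_equal(unname(mc3$prob["BNM"]), 0.5)
  expect_equal(mc3$bayes_factor, 1)
  expect_false(mc3$decision)
})

test_that("zero SNM acceptances give an infinite Bayes factor", {
  tab <- synthetic_table(50, seed = 5)
  tab$model <- "BNM"
  obs <- c(thetaW = 0.005, thetaPi = 0.005, He = 0.5)
  mc <- abc_model_choice(tab, obs, tolerance = 0.1)
  expect_identical(mc$bayes_factor, Inf)
  expect_true(mc$decision)
  mcl <- abc_model_choice(tab, obs, tolerance = 0.1, laplace = TRUE)
  expect_true(is.finite(mcl$bayes_factor))
})

test_that("Epanechnikov weights have the right shape", {
  expect_equal(epanechnikov_weights(0, 2), 1)
  expect_equal(epanechnikov_weights(2, 2), 0)
  expect_equal(epanechnikov_weights(2 / sqrt(2), 2), 0.5)
  expect_error(epanechnikov_weights(3, 2), "<= delta")
  w0 <- epanechnikov_weights(c(0, 0), 0)
  expect_equal(as.numeric(w0), c(1, 1))
  expect_true(attr(w0, "uniform_fallback"))
})

test_that("local-linear regression recovers an exact linear map", {
  set.seed(8)
  s1 <- runif(60)
  params <- cbind(theta = 2 * s1 + 1)
  stats <- cbind(s1 = s1)
  obs <- c(s1 = 0.3)
  w <- epanechnikov_weights(abs(s1 - 0.3), max(abs(s1 - 0.3)) + 1e-9)
  adj <- loclinear_adjust(params, stats, obs, w)
  expect_false(adj$fallback)
  expect_lt(max(abs(adj$adjusted - 1.6)) / 1.6, 1e-8)

  # stats identical to obs -> no adjustment
  same <- loclinear_adjust(params, matrix(0.3, 60, 1,
                                          dimnames = list(NULL, "s1")),
                           obs, rep(1, 60))
  expect_equal(same$adjusted, params)
})

test_that("uniform-weight single-statistic adjustment matches the OLS oracle", {
  set.seed(9)
  s1 <- runif(40)
  th <- 3 * s1 + rnorm(40, 0, 0.1)
  obs <- c(s1 = 0.5)
  adj <- loclinear_adjust(cbind(theta = th), cbind(s1 = s1), obs, rep(1, 40))
  fit <- lm(th ~ s1)
  expected <- th - coef(fit)["s1"] * (s1 - 0.5)
  expect_equal(as.numeric(adj$adjusted), as.numeric(expected),
               tolerance = 1e-10)
})

test_that("too few accepted rows fall back to the rejection sample", {
  params <- cbind(theta = c(1, 2))
  stats <- cbind(a = c(0.1, 0.2), b = c(0.3, 0.1), c = c(1, 2))
  adj <- loclinear_adjust(params, stats, c(a = 0, b = 0, c = 0), c(1, 1))
  expect_true(adj$fallback)
  expect_equal(adj$adjusted, params)
})

test_that("abc_fit estimates a known linear rule and clips when asked", {
  set.seed(10)
  n <- 400
  theta <- runif(n, 0, 1)
  tab <- data.frame(model = "BNM", theta = theta,
                    thetaW = theta / 2 + rnorm(n, 0, 1e-6))
  fit <- abc_fit(c(thetaW = 0.25), tab, tolerance = 0.2,
                 param_cols = "theta")
  expect_s3_class(fit, "abcfit")
  expect_equal(unname(coef(fit)["theta"]), 0.5, tolerance = 1e-3)
  ci <- credible_interval(fit, "theta", 0.9)
  expect_true(ci[1] <= coef(fit)["theta"] && coef(fit)["theta"] <= ci[2])
  s <- summary(fit)
  expect_true(all(c("lo90", "hi90") %in% names(s)))

  clipped <- abc_fit(c(thetaW = 0.0), tab, tolerance = 0.2,
                     param_cols = "theta", clip = list(theta = c(0.2, 1)))
  expect_true(all(clipped$adjusted[, "theta"] >= 0.2))
})

test_that("rejection-method fit returns raw accepted draws", {
  tab <- synthetic_table(200, seed = 6)
  obs <- c(thetaW = 0.005, thetaPi = 0.005, He = 0.5)
  fit <- abc_fit(obs, tab, tolerance = 0.1, method = "rejection",
                 model = "BNM")
  expect_equal(fit$raw, fit$adjusted)
  expect_equal(nrow(fit$raw), round(0.1 * sum(tab$model == "BNM")))
})

test_that("accuracy metrics match their definitions", {
  expect_equal(accuracy_metrics(c(1, 1, 1), 1), c(rbias = 0, rrmse = 0))
  expect_equal(accuracy_metrics(c(1.1, 0.9), 1), c(rbias = 0, rrmse = 0.1))
  expect_equal(accuracy_metrics(c(1.2, 1.2), 1), c(rbias = 0.2, rrmse = 0.2))
  expect_error(accuracy_metrics(1, 0), "non-zero")
})

test_that("weighted quantiles are monotone and bracket the median", {
  set.seed(11)
  x <- rnorm(200)
  w <- runif(200)
  q <- abcpower:::weighted_quantile(x, w, c(0.05, 0.5, 0.95))
  expect_true(all(diff(q) > 0))
  expect_lt(abs(q[2] - median(x)), 0.3)
})
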