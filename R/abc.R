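#' Euclidean distance between summary vectors
#'
#' Distance between one observed summary vector and each row of a matrix of
#' simulated summary vectors sharing the same name registry.  With
#' `scaling = "sd"` each statistic is first divided by its standard
#' deviation across the simulated rows (statistics with zero variance are
#' left unscaled); the default applies no standardization.
#'
#' @param obs Named numeric vector.
#' @param sims Numeric matrix with matching column names.
#' @param scaling `"none"` (default) or `"sd"`.
#' @return Numeric vector of distances, one per row of `sims`.
#' @export
euclidean_distance <- function(obs, sims, scaling = c("none", "sd")) {
  scaling <- match.arg(scaling)
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1,
                                         dimnames = list(NULL, names(sims)))
  if (!identical(colnames(sims), names(obs)))
    stop("summary-statistic registries of obs and sims do not match")
  if (scaling == "sd") {
    s <- apply(sims, 2, sd)
    s[!is.finite(s) | s == 0] <- 1
    sims <- sweep(sims, 2, s, "/")
    obs <- obs / s
  }
  sqrt(colSums((t(sims) - obs)^2))
}

#' Rejection step
#'
#' Accepts the `round(tolerance * nrow)` simulations closest to the observed
#' summary vector, by Euclidean distance over the statistics named in `obs`.
#' Ties at the threshold are broken by row order.
#'
#' @param table A [reference_table] (or any data frame holding the columns
#'   named in `obs`).
#' @param obs Named numeric summary vector (typically from
#'   [build_stat_vector()]).
#' @param tolerance Acceptance proportion in (0, 1].
#' @param scaling `"sd"` (default) standardizes every statistic by its
#'   standard deviation across the reference table before the distance, as in
#'   Beaumont-style ABC; `"none"` uses raw scales.
#' @return A list of class `"abc_rejection"`: `accepted` (row indices),
#'   `distances`, `delta` (distance at the tolerance quantile),
#'   `tolerance`.
#' @export
abc_reject <- function(table, obs, tolerance = 0.001,
                       scaling = c("sd", "none")) {
  if (nrow(table) == 0) stop("empty reference table")
  scaling <- match.arg(scaling)
  if (!(tolerance > 0 && tolerance <= 1))
    stop("tolerance must be in (0, 1]")
  k <- round(tolerance * nrow(table))
  if (k < 1) stop("tolerance yields zero acceptances for this table size")
  sims <- as.matrix(table[, names(obs), drop = FALSE])
  d <- euclidean_distance(obs, sims, scaling)
  accepted <- order(d)[seq_len(k)]  # stable: ties broken by row order
  structure(list(accepted = accepted, distances = d,
                 delta = max(d[accepted]), tolerance = tolerance),
            class = "abc_rejection")
}

#' @export
print.abc_rejection <- function(x, ...) {
  cat(sprintf("ABC rejection: %d of %d accepted (tolerance %g, delta %.4g)\n",
              length(x$accepted), length(x$distances), x$tolerance, x$delta))
  invisible(x)
}

#' Model choice by posterior model probabilities
#'
#' Performs the rejection step on a pooled two-model reference table and
#' defines each model's posterior probability as its share of the accepted
#' simulations.  The Bayes factor is the ratio P(BNM)/P(SNM) (`Inf` when no
#' SNM row is accepted; with `laplace = TRUE` a (k + 1/2)/(k + 1/2)
#' correction is applied instead).
#'
#' @inheritParams abc_reject
#' @param cutoff Bayes-factor threshold for rejecting the SNM (default 3).
#' @param laplace Apply the half-count correction to the Bayes factor.
#' @return An object of class `"abc_model_choice"` with elements `prob`
#'   (named probabilities), `bayes_factor`, `decision`, `cutoff` and
#'   `rejection`.
#' @export
abc_model_choice <- function(table, obs, tolerance = 0.001, cutoff = 3,
                             scaling = c("sd", "none"), laplace = FALSE) {
  rej <- abc_reject(table, obs, tolerance, scaling)
  models <- as.character(table$model[rej$accepted])
  k_bnm <- sum(models == "BNM")
  k_snm <- sum(models == "SNM")
  tot <- k_bnm + k_snm
  prob <- c(SNM = k_snm / tot, BNM = k_bnm / tot)
  bf <- if (laplace) (k_bnm + 0.5) / (k_snm + 0.5)
        else if (k_snm == 0) Inf else k_bnm / k_snm
  structure(list(prob = prob, bayes_factor = bf,
                 decision = bf >= cutoff, cutoff = cutoff, rejection = rej),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat(sprintf("P(SNM) = %.3f, P(BNM) = %.3f, BF(BNM:SNM) = %s\n",
              x$prob["SNM"], x$prob["BNM"], format(x$bayes_factor, digits = 4)))
  cat(sprintf("SNM %s at BF >= %g\n",
              if (x$decision) "rejected" else "not rejected", x$cutoff))
  invisible(x)
}

#' Epanechnikov kernel weights
#'
#' Weights `1 - (d / delta)^2` for accepted distances `d`, vanishing at the
#' acceptance threshold `delta`.  If `delta` is zero (all accepted rows sit
#' exactly on the observation) uniform weights are returned with attribute
#' `uniform_fallback = TRUE`.
#'
#' @param distances Accepted distances, all `<= delta`.
#' @param delta Acceptance threshold (> 0 for proper weights).
#' @return Non-negative weights.
#' @export
epanechnikov_weights <- function(distances, delta) {
  if (any(distances > delta + 1e-12)) stop("distances must be <= delta")
  if (delta == 0)
    return(structure(rep(1, length(distances)), uniform_fallback = TRUE))
  pmax(0, 1 - (distances / delta)^2)
}

#' Local-linear regression adjustment
#'
#' Beaumont-style post-rejection correction: each parameter is regressed on
#' the summary statistics by weighted least squares over the accepted rows,
#' and every accepted draw is shifted to the observed statistics,
#' `theta* = theta - (s - s_obs)' beta`.  A singular design is solved with a
#' small ridge term (flagged); with fewer accepted rows than statistics + 2
#' the unadjusted draws are returned (flagged).
#'
#' @param params Matrix (rows = accepted draws) of parameter values.
#' @param stats Matrix of the same rows' summary statistics.
#' @param obs Observed summary vector (same columns as `stats`).
#' @param weights Regression weights (e.g. [epanechnikov_weights()]).
#' @return List with `adjusted` (matrix like `params`), `beta`, and logical
#'   flags `fallback`, `ridged`.
#' @export
loclinear_adjust <- function(params, stats, obs, weights) {
  params <- as.matrix(params)
  stats <- as.matrix(stats)
  if (all(weights == 0)) weights <- rep(1, length(weights))
  p <- ncol(stats)
  if (nrow(params) < p + 2)
    return(list(adjusted = params, beta = NULL, fallback = TRUE,
                ridged = FALSE))
  X <- cbind(1, sweep(stats, 2, obs))
  W <- weights
  XtWX <- crossprod(X * W, X)
  XtWy <- crossprod(X * W, params)
  ridged <- FALSE
  co <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(co) || !all(is.finite(co))) {
    ridged <- TRUE
    co <- solve(XtWX + diag(1e-8 * max(diag(XtWX)), nrow(XtWX)), XtWy)
  }
  beta <- co[-1, , drop = FALSE]
  adjusted <- params - sweep(stats, 2, obs) %*% beta
  dimnames(adjusted) <- dimnames(params)
  list(adjusted = adjusted, beta = beta, fallback = FALSE, ridged = ridged)
}

#' Fit an ABC posterior for one model's parameters
#'
#' The package's central estimator.  Applies the rejection step to the rows
#' of one model in a reference table, then (by default) the local-linear
#' regression adjustment with Epanechnikov weights, and returns a classed
#' posterior-sample object.  Point estimates are weighted means of the
#' (adjusted) accepted draws; credible intervals are central weighted
#' empirical quantiles.  Adjusted draws falling outside the prior bounds are
#' retained unless `clip` supplies bounds to truncate to.
#'
#' @param obs Named numeric summary vector of the observed dataset.
#' @param table A [reference_table]; only rows of `model` are used.
#' @param tolerance Acceptance proportion, applied to those rows.
#' @param method `"loclinear"` (default) or `"rejection"` (no adjustment).
#' @param model Which model's parameters to estimate (default `"BNM"`).
#' @param scaling Passed to [euclidean_distance()].
#' @param clip Optional named list of `c(lower, upper)` bounds used to clamp
#'   adjusted draws (e.g. a [prior_spec()]).
#' @return An object of class `"abcfit"`: accepted raw and adjusted
#'   parameter draws, weights, distances and flags.
#' @seealso [coef.abcfit()], [summary.abcfit()], [credible_interval()]
#' @examples
#' ## toy reference table with a known linear parameter-statistic map
#' tab <- data.frame(model = "BNM", theta = runif(200))
#' tab$thetaW <- tab$theta / 2
#' fit <- abc_fit(c(thetaW = 0.25), tab, tolerance = 0.25,
#'                param_cols = "theta")
#' coef(fit)
#' @param param_cols Parameter columns to estimate; defaults to the model's
#'   parameters present in the table.
#' @export
abc_fit <- function(obs, table, tolerance = 0.001,
                    method = c("loclinear", "rejection"), model = "BNM",
                    scaling = c("sd", "none"), clip = NULL,
                    param_cols = NULL) {
  method <- match.arg(method)
  sub <- table[table$model == model, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for model ", model)
  if (is.null(param_cols)) {
    cand <- c("theta", "rho", "bot_end", "bot_ne")
    param_cols <- cand[cand %in% names(sub) &
                         vapply(cand, function(p) p %in% names(sub) &&
                                  !all(is.na(sub[[p]])), TRUE)]
  }
  rej <- abc_reject(sub, obs, tolerance, scaling)
  acc <- rej$accepted
  params <- as.matrix(sub[acc, param_cols, drop = FALSE])
  stats <- as.matrix(sub[acc, names(obs), drop = FALSE])
  w <- epanechnikov_weights(rej$distances[acc], rej$delta)
  if (all(w == 0)) w <- rep(1, length(w))
  if (method == "loclinear") {
    adj <- loclinear_adjust(params, stats, obs, w)
  } else {
    adj <- list(adjusted = params, beta = NULL, fallback = FALSE,
                ridged = FALSE)
  }
  adjusted <- adj$adjusted
  if (!is.null(clip)) {
    for (p in intersect(colnames(adjusted), names(clip))) {
      adjusted[, p] <- pmin(pmax(adjusted[, p], clip[[p]][1]), clip[[p]][2])
    }
  }
  structure(list(raw = params, adjusted = adjusted, weights = w,
                 distances = rej$distances[acc], delta = rej$delta,
                 tolerance = tolerance, method = method, model = model,
                 obs = obs, fallback = adj$fallback, ridged = adj$ridged),
            class = "abcfit")
}

#' @export
print.abcfit <- function(x, ...) {
  cat(sprintf("ABC %s fit (%s), %d accepted draws (tolerance %g)\n",
              x$method, x$model, nrow(x$adjusted), x$tolerance))
  print(coef(x))
  invisible(x)
}

#' Posterior point estimates
#'
#' Weighted means of the (adjusted) accepted parameter draws.
#' @param object An [abc_fit()] result.
#' @param ... Unused.
#' @export
coef.abcfit <- function(object, ...) {
  apply(object$adjusted, 2, stats::weighted.mean, w = object$weights)
}

#' @export
summary.abcfit <- function(object, levels = c(0.1, 0.5, 0.9), ...) {
  est <- coef(object)
  out <- data.frame(parameter = names(est), estimate = unname(est))
  for (lv in levels) {
    ci <- t(vapply(names(est), function(p)
      credible_interval(object, p, level = lv), numeric(2)))
    out[[sprintf("lo%d", round(lv * 100))]] <- ci[, 1]
    out[[sprintf("hi%d", round(lv * 100))]] <- ci[, 2]
  }
  structure(out, class = c("summary.abcfit", "data.frame"),
            n_accepted = nrow(object$adjusted), method = object$method)
}

#' @export
print.summary.abcfit <- function(x, ...) {
  cat(sprintf("ABC posterior (%s, %d accepted draws)\n",
              attr(x, "method"), attr(x, "n_accepted")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.abcfit <- function(x, parameter = colnames(x$adjusted)[1], ...) {
  graphics::hist(x$adjusted[, parameter], breaks = 30, freq = FALSE,
                 main = sprintf("ABC posterior of %s", parameter),
                 xlab = parameter, ...)
  graphics::abline(v = coef(x)[parameter], lwd = 2)
  invisible(x)
}

# weighted empirical quantile (linear interpolation on the weighted CDF)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' Central weighted credible interval
#'
#' @param fit An [abc_fit()] result.
#' @param parameter Parameter name.
#' @param level Central mass of the interval (e.g. 0.9).
#' @return `c(lower, upper)`.
#' @export
credible_interval <- function(fit, parameter, level = 0.9) {
  a <- (1 - level) / 2
  weighted_quantile(fit$adjusted[, parameter], fit$weights, c(a, 1 - a))
}

#' Relative bias and relative RMSE of an estimator
#'
#' `rbias = (mean(estimates) - true) / true`;
#' `rrmse = sqrt(mean(((estimates - true) / true)^2))`.
#'
#' @param estimates Point estimates across replicates.
#' @param true_value True parameter value (non-zero).
#' @return Named vector `c(rbias, rrmse)`.
#' @export
accuracy_metrics <- function(estimates, true_value) {
  if (true_value == 0) stop("true_value must be non-zero")
  rel <- (estimates - true_value) / true_value
  c(rbias = mean(rel), rrmse = sqrt(mean(rel^2)))
}
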