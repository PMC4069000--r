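#' Parameter-statistic correlation matrix
#'
#' Pearson correlations between each model parameter and each summary
#' statistic over one model's rows of a reference table — the diagnostic
#' used to judge which statistics respond to which parameters (e.g. the
#' bottleneck parameters correlate most strongly with Tajima's D and the
#' low-frequency SFS class).  Constant statistic columns yield `NA` and are
#' flagged.
#'
#' @param table A [reference_table].
#' @param model `"SNM"` or `"BNM"`.
#' @param stats Statistic columns to use (default: the `ALL` battery).
#' @return A parameters x statistics matrix of class
#'   `"correlation_matrix"`; constant columns are listed in attribute
#'   `constant`.
#' @export
param_stat_correlations <- function(table, model = c("BNM", "SNM"),
                                    stats = stat_set("ALL")) {
  model <- match.arg(model)
  sub <- table[table$model == model, , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 rows of model ", model)
  params <- if (model == "BNM") c("theta", "bot_end", "bot_ne", "rho")
            else c("theta", "rho")
  sm <- as.matrix(sub[, stats, drop = FALSE])
  const <- colnames(sm)[apply(sm, 2, function(v) sd(v) == 0 || !all(is.finite(v)))]
  out <- matrix(NA_real_, length(params), length(stats),
                dimnames = list(params, stats))
  ok <- setdiff(stats, const)
  for (p in params)
    out[p, ok] <- suppressWarnings(cor(sub[[p]], sm[, ok]))
  structure(out, constant = const, class = c("correlation_matrix", "matrix"))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("parameter-statistic Pearson correlations\n")
  print(round(unclass(x), 2))
  if (length(attr(x, "constant")))
    cat("constant statistics (NA):",
        paste(attr(x, "constant"), collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis of summary statistics
#'
#' PCA of the summary-statistic columns of a reference table (optionally of
#' one model's rows), by eigen-decomposition of the correlation matrix
#' (`standardize = TRUE`, the default — the statistics span very different
#' scales) or the raw covariance.  Component signs are fixed so that each
#' component's largest-magnitude loading is positive.  Constant columns are
#' dropped and flagged.
#'
#' @param table A [reference_table] (or plain data frame with the columns).
#' @param model Optional model filter.
#' @param standardize Scale statistics to unit variance first.
#' @param stats Statistic columns (default: the `ALL` battery).
#' @return An object of class `"pca_stats"`: `loadings` (statistics x
#'   components), `var_fraction`, `scores`, `dropped`.
#' @export
pca_stats <- function(table, model = NULL, standardize = TRUE,
                      stats = stat_set("ALL")) {
  sub <- if (is.null(model)) table else table[table$model == model, , drop = FALSE]
  sm <- as.matrix(sub[, stats, drop = FALSE])
  if (nrow(sm) <= ncol(sm)) stop("need more rows than statistics")
  keep <- apply(sm, 2, function(v) all(is.finite(v)) && sd(v) > 0)
  dropped <- colnames(sm)[!keep]
  sm <- sm[, keep, drop = FALSE]
  pc <- prcomp(sm, center = TRUE, scale. = standardize)
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(loadings = pc$rotation,
                 var_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 scores = pc$x, dropped = dropped,
                 standardized = standardize),
            class = "pca_stats")
}

#' @export
print.pca_stats <- function(x, n = 4, ...) {
  cat(sprintf("PCA of summary statistics (%s)\n",
              if (x$standardized) "unit-variance standardized" else
                "raw covariance"))
  vf <- x$var_fraction[seq_len(min(n, length(x$var_fraction)))]
  cat("variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf),
            collapse = ", "), "\n")
  if (length(x$dropped))
    cat("dropped constant statistics:", paste(x$dropped, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
plot.pca_stats <- function(x, components = c(1, 2), ...) {
  graphics::plot(x$scores[, components[1]], x$scores[, components[2]],
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$var_fraction[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$var_fraction[components[2]]),
                 pch = 16, cex = 0.4, ...)
  invisible(x)
}
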