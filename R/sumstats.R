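#' @title Per-locus population-genetic statistics
#' @description Classic estimators computed from a 0/1 haplotype matrix with
#'   known ancestral/derived orientation (0 = ancestral, 1 = derived).
#'   `seg_sites()` counts polymorphic columns; `theta_w()`, `theta_pi()` and
#'   `theta_h()` are Watterson's, Tajima's and Fay & Wu's per-bp estimators
#'   of theta; `tajima_d()` and `fay_wu_h()` are the corresponding neutrality
#'   tests (NA when no site segregates); `haplotype_diversity()` is Nei's
#'   unbiased gene diversity over row patterns.
#' @param h A `"haplotype_matrix"` (see [simulate_locus()]) or a plain 0/1
#'   matrix with rows = sequences.
#' @param L Locus length in bp; taken from `h` when available.
#' @name locus_stats
NULL

.hap_mat <- function(h) {
  if (inherits(h, "haplotype_matrix")) h$states
  else if (is.matrix(h)) h
  else stop("h must be a haplotype matrix")
}

.hap_L <- function(h, L) {
  if (!is.null(L)) return(L)
  if (inherits(h, "haplotype_matrix")) return(h$L)
  stop("L must be supplied for a plain matrix")
}

# derived counts of segregating columns only
.derived_counts <- function(m) {
  if (ncol(m) == 0) return(integer(0))
  dc <- colSums(m)
  dc[dc >= 1 & dc <= nrow(m) - 1]
}

.a_n <- function(n) sum(1 / seq_len(n - 1))

#' @rdname locus_stats
#' @export
seg_sites <- function(h) length(.derived_counts(.hap_mat(h)))

#' @rdname locus_stats
#' @export
theta_w <- function(h, L = NULL) {
  m <- .hap_mat(h)
  if (nrow(m) < 2) stop("need n >= 2")
  seg_sites(h) / (.a_n(nrow(m)) * .hap_L(h, L))
}

#' @rdname locus_stats
#' @export
theta_pi <- function(h, L = NULL) {
  m <- .hap_mat(h)
  n <- nrow(m)
  if (n < 2) stop("need n >= 2")
  dc <- .derived_counts(m)
  sum(2 * dc * (n - dc) / (n * (n - 1))) / .hap_L(h, L)
}

#' @rdname locus_stats
#' @export
theta_h <- function(h, L = NULL) {
  m <- .hap_mat(h)
  n <- nrow(m)
  if (n < 2) stop("need n >= 2")
  dc <- .derived_counts(m)
  sum(2 * dc^2 / (n * (n - 1))) / .hap_L(h, L)
}

#' @rdname locus_stats
#' @export
tajima_d <- function(h) {
  m <- .hap_mat(h)
  n <- nrow(m)
  dc <- .derived_counts(m)
  S <- length(dc)
  if (S == 0) return(NA_real_)
  a1 <- .a_n(n)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_loc <- sum(2 * dc * (n - dc) / (n * (n - 1)))
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)  # n = 3: e1 = e2 = 0
  (pi_loc - S / a1) / denom
}

#' @rdname locus_stats
#' @export
fay_wu_h <- function(h) {
  m <- .hap_mat(h)
  n <- nrow(m)
  dc <- .derived_counts(m)
  if (length(dc) == 0) return(NA_real_)
  pi_loc <- sum(2 * dc * (n - dc) / (n * (n - 1)))
  th_loc <- sum(2 * dc^2 / (n * (n - 1)))
  pi_loc - th_loc
}

#' @rdname locus_stats
#' @export
haplotype_diversity <- function(h) {
  m <- .hap_mat(h)
  n <- nrow(m)
  if (n < 2) stop("need n >= 2")
  pat <- apply(m, 1, paste, collapse = "")
  p <- table(pat) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Folded site-frequency-spectrum bins
#'
#' Maps every segregating site to its minor-allele frequency
#' `min(i, n - i) / n` in (0, 0.5] and bins these into `k` equal-width,
#' right-closed classes partitioning (0, 0.5].  Per-locus proportions are
#' averaged over loci with at least one segregating site (`pooled = FALSE`,
#' the default), or all sites across loci can be pooled before normalizing
#' (`pooled = TRUE`).
#'
#' @param dataset A `"dataset"` (see [simulate_dataset()]) or a single
#'   haplotype matrix.
#' @param k Number of frequency classes (3 or 5 in the study design).
#' @param pooled Pool sites across loci instead of averaging per-locus
#'   proportions.
#' @return Numeric vector of `k` proportions summing to 1, or all zeros with
#'   attribute `degenerate = TRUE` when nothing segregates.
#' @export
folded_sfs_bins <- function(dataset, k = 3, pooled = FALSE) {
  if (k < 2) stop("k must be >= 2")
  if (inherits(dataset, "haplotype_matrix") || is.matrix(dataset))
    dataset <- list(dataset)
  per_locus <- lapply(dataset, function(h) {
    m <- .hap_mat(h)
    n <- nrow(m)
    dc <- .derived_counts(m)
    if (length(dc) == 0) return(NULL)
    mf <- pmin(dc, n - dc) / n
    bin <- pmin(pmax(ceiling(mf * 2 * k), 1), k)
    tabulate(bin, nbins = k)
  })
  per_locus <- per_locus[!vapply(per_locus, is.null, TRUE)]
  if (length(per_locus) == 0)
    return(structure(rep(0, k), degenerate = TRUE))
  if (pooled) {
    tot <- Reduce(`+`, per_locus)
    tot / sum(tot)
  } else {
    props <- vapply(per_locus, function(x) x / sum(x), numeric(k))
    rowMeans(matrix(props, nrow = k))
  }
}

#' Cross-locus aggregation of a per-locus statistic
#'
#' Mean, standard deviation (n - 1 denominator) and 5%/95% quantiles (linear
#' interpolation, R type 7) over the loci where the statistic is defined.
#' A single locus gives sd = 0 and degenerate quantiles; if the statistic is
#' undefined at every locus all four values are 0 and the result carries
#' attribute `degenerate = TRUE`.
#'
#' @param values Per-locus statistic values; NA marks "undefined".
#' @return Named numeric vector `c(mean, sd, q5, q95)`.
#' @export
aggregate_stats <- function(values) {
  v <- values[!is.na(values)]
  nv <- length(v)
  if (nv == 0)
    return(structure(c(mean = 0, sd = 0, q5 = 0, q95 = 0), degenerate = TRUE))
  mu <- sum(v) / nv
  s <- if (nv > 1) sqrt(sum((v - mu)^2) / (nv - 1)) else 0
  # type-7 quantiles, inlined (this sits in the reference-table hot loop)
  sv <- sort(v)
  q7 <- function(p) {
    h <- (nv - 1) * p + 1
    fl <- floor(h)
    sv[fl] + (h - fl) * (sv[min(fl + 1, nv)] - sv[fl])
  }
  c(mean = mu, sd = s, q5 = q7(0.05), q95 = q7(0.95))
}

# ---------------------------------------------------------------------------
# summary-vector registry

.base_stats <- c("thetaW", "thetaPi", "thetaH", "He", "S", "D", "H")

#' Summary-statistic name registry
#'
#' The fixed, documented column order shared by summary vectors and
#' reference tables: for each base statistic the cross-locus mean (bare
#' name), `_sd`, `_q5` and `_q95`, followed by the 3-class and 5-class
#' folded-SFS bins.  Distance computations in the ABC step rely on this
#' order.
#'
#' @return Character vector of 36 names.
#' @export
summary_registry <- function() {
  c(as.vector(vapply(.base_stats,
                     function(s) c(s, paste0(s, c("_sd", "_q5", "_q95"))),
                     character(4))),
    paste0("sfs3_", 1:3), paste0("sfs5_", 1:5))
}

#' Named summary-statistic sets
#'
#' The statistic sets compared in the power study.  For power analysis the
#' members are cross-locus means and SFS bins only: `TPH` = (mean Watterson's
#' theta, mean nucleotide diversity, mean haplotype diversity); `SFS3` /
#' `SFS5` = the folded SFS in 3 / 5 bins; `T+SFS3` = mean Watterson's theta
#' plus the 3 bins; `TPH+DH` = TPH plus mean Tajima's D and mean Fay & Wu's
#' H.  `ALL` is the full mean/sd/quantile battery plus the 3-bin SFS, used
#' for the exploratory correlation/PCA analyses.
#'
#' @param name One of `"TPH"`, `"SFS3"`, `"T+SFS3"`, `"SFS5"`, `"TPH+DH"`,
#'   `"ALL"`.
#' @return Character vector of member names (a subset of
#'   [summary_registry()]).
#' @export
stat_set <- function(name) {
  reg <- summary_registry()
  members <- switch(name,
    "TPH" = c("thetaW", "thetaPi", "He"),
    "SFS3" = paste0("sfs3_", 1:3),
    "T+SFS3" = c("thetaW", paste0("sfs3_", 1:3)),
    "SFS5" = paste0("sfs5_", 1:5),
    "TPH+DH" = c("thetaW", "thetaPi", "He", "D", "H"),
    "ALL" = c(reg[1:28], paste0("sfs3_", 1:3)),
    stop("unknown statistic set: ", name))
  reg[reg %in% members]
}

#' Per-locus statistic matrix for a dataset
#'
#' Computes all per-locus statistics (S, per-bp theta estimators, Tajima's D,
#' Fay & Wu's H, haplotype diversity and per-locus folded-SFS proportions)
#' for every locus of a dataset, via compiled code.
#'
#' @param dataset A `"dataset"`.
#' @return Numeric matrix, loci x 15, with NA for statistics undefined at
#'   monomorphic loci.
#' @export
dataset_stats <- function(dataset) {
  n <- attr(dataset, "n")
  L <- attr(dataset, "L")
  if (is.null(n)) {
    n <- nrow(.hap_mat(dataset[[1]]))
    L <- dataset[[1]]$L
  }
  cpp_dataset_stats(unclass(dataset), as.integer(n), as.numeric(L))
}

#' Full summary vector of a multi-locus dataset
#'
#' Aggregates the per-locus statistics into the full 36-value registry
#' vector: mean/sd/q5/q95 across loci for each base statistic (undefined
#' loci excluded) plus the 3- and 5-class folded-SFS proportions.
#'
#' @param dataset A `"dataset"`, or a per-locus matrix from
#'   [dataset_stats()] (used internally to avoid recomputation).
#' @param pooled_sfs Pool SFS counts across loci rather than averaging
#'   per-locus proportions.
#' @return Named numeric vector in [summary_registry()] order.
#' @export
summary_vector <- function(dataset, pooled_sfs = FALSE) {
  m <- if (is.matrix(dataset)) dataset else dataset_stats(dataset)
  out <- numeric(0)
  for (s in .base_stats) out <- c(out, aggregate_stats(m[, s]))
  loci_S <- m[, "S"]
  seg <- which(loci_S > 0)
  sfs <- function(cols, k) {
    if (length(seg) == 0) return(rep(0, k))
    if (pooled_sfs) {
      cnt <- colSums(m[seg, cols, drop = FALSE] * loci_S[seg])
      cnt / sum(cnt)
    } else {
      colMeans(m[seg, cols, drop = FALSE])
    }
  }
  out <- c(out, sfs(paste0("sfs3_", 1:3), 3), sfs(paste0("sfs5_", 1:5), 5))
  setNames(out, summary_registry())
}

#' Summary vector restricted to a statistic set
#'
#' @param dataset A `"dataset"`.
#' @param set A statistic-set name (see [stat_set()]).
#' @param pooled_sfs See [summary_vector()].
#' @return Named numeric vector with the set's members, in registry order.
#' @export
build_stat_vector <- function(dataset, set = "TPH+DH", pooled_sfs = FALSE) {
  summary_vector(dataset, pooled_sfs)[stat_set(set)]
}
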