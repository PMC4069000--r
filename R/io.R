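#' Write a dataset as ms-style locus blocks
#'
#' One block per locus: a `//` separator line, `segsites: S`, a
#' `positions:` line with positions printed to 6 decimals (omitted when
#' `S = 0`), then one 0/1 character row per sampled sequence.  This dialect
#' is the package's canonical exchange format; a written file re-reads and
#' re-writes bit-identically.
#'
#' @param dataset A `"dataset"` (see [simulate_dataset()]).
#' @param path Output file (gzip transparent when the name ends in `.gz`).
#' @export
write_ms <- function(dataset, path) {
  lines <- character(0)
  for (h in dataset) {
    m <- .hap_mat(h)
    S <- ncol(m)
    lines <- c(lines, "//", sprintf("segsites: %d", S))
    if (S > 0) {
      lines <- c(lines,
                 paste("positions:",
                       paste(sprintf("%.6f", h$positions), collapse = " ")),
                 apply(m, 1, paste, collapse = ""))
    } else {
      lines <- c(lines, rep("", 0))
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read ms-style locus blocks
#'
#' Parses the dialect written by [write_ms()]; leading lines before the
#' first `//` (such as an ms command-line header) are skipped.  Loci with
#' `segsites: 0` contain no haplotype rows; their sample size is taken from
#' the other loci (or `n`).
#'
#' @param path Input file.
#' @param L Locus length in bp (not stored in the format).
#' @param n Sample size; required only if every locus is monomorphic.
#' @return A `"dataset"`.
#' @export
read_ms <- function(path, L = 750, n = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "//")
  if (length(starts) == 0) stop("no '//' locus blocks found in ", path)
  bounds <- c(starts, length(lines) + 1)
  loci <- list()
  for (b in seq_along(starts)) {
    li <- b  # locus index for error messages
    block <- lines[(bounds[b] + 1):(bounds[b + 1] - 1)]
    block <- block[block != ""]
    if (length(block) < 1 || !grepl("^segsites:", block[1]))
      stop("locus ", li, ": expected 'segsites:' line")
    S <- as.integer(sub("^segsites:\\s*", "", block[1]))
    if (is.na(S)) stop("locus ", li, ": malformed segsites line")
    if (S == 0) {
      loci[[b]] <- list(positions = numeric(0), S = 0L, rows = NULL)
      next
    }
    if (length(block) < 2 || !grepl("^positions:", block[2]))
      stop("locus ", li, ": expected 'positions:' line")
    pos <- as.numeric(strsplit(sub("^positions:\\s*", "", block[2]),
                               "\\s+")[[1]])
    if (length(pos) != S || anyNA(pos))
      stop("locus ", li, ": positions do not match segsites")
    rows <- block[-(1:2)]
    if (length(rows) == 0) stop("locus ", li, ": truncated block, no haplotypes")
    if (any(nchar(rows) != S))
      stop("locus ", li, ": haplotype row length differs from segsites")
    loci[[b]] <- list(positions = pos, S = S, rows = rows)
  }
  nn <- unique(vapply(loci, function(x) length(x$rows), 0L))
  nn <- nn[nn > 0]
  if (length(nn) > 1) stop("inconsistent sample sizes across loci")
  if (length(nn) == 1) n <- nn
  if (is.null(n)) stop("all loci monomorphic; supply n")
  ds <- lapply(loci, function(x) {
    states <- if (x$S == 0) matrix(0L, n, 0) else {
      do.call(rbind, lapply(strsplit(x$rows, ""), function(r) as.integer(r)))
    }
    structure(list(positions = x$positions, states = states, n = n, L = L),
              class = "haplotype_matrix")
  })
  structure(ds, n = n, L = L, class = "dataset")
}

#' Persist and reload reference tables
#'
#' Headered TSV with the `model` column, the four parameter columns
#' (`NA` markers for the bottleneck parameters of SNM rows) and the
#' summary-statistic columns in registry order.  Reading verifies the
#' column order against [summary_registry()] and restores the
#' `reference_table` class; gzip is transparent in both directions.
#'
#' @param table A [reference_table].
#' @param path File path (`.gz` for compression).
#' @return `read_reference_table()` returns the [reference_table].
#' @export
write_reference_table <- function(table, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  meta <- sprintf("# abcpower reference table: n=%s loci=%s L=%s",
                  attr(table, "n"), attr(table, "loci"), attr(table, "L"))
  writeLines(meta, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  first <- readLines(path, n = 1)
  meta <- if (startsWith(first, "#")) first else NULL
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  par_cols <- c("model", "theta", "rho", "bot_end", "bot_ne")
  if (!identical(names(df)[seq_along(par_cols)], par_cols))
    stop("reference table header mismatch: expected columns ",
         paste(par_cols, collapse = ", "))
  stat_names <- names(df)[-seq_along(par_cols)]
  reg <- summary_registry()
  if (!identical(stat_names, reg[reg %in% stat_names]))
    stop("statistic columns are not in registry order")
  attr(df, "stat_names") <- stat_names
  if (!is.null(meta)) {
    kv <- regmatches(meta, gregexpr("[a-zA-Z]+=[0-9]+", meta))[[1]]
    for (p in kv) {
      nm <- sub("=.*", "", p)
      attr(df, nm) <- as.integer(sub(".*=", "", p))
    }
  }
  class(df) <- c("reference_table", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# configuration and run manifests

.config_schema <- list(
  seed = NULL,
  demography = c("timescale", "bot_dur"),
  priors = c("theta", "rho", "bot_end", "bot_ne"),
  scenario = c("n_samples", "loci", "L", "theta_bp", "rho_bp", "bot_end", "bot_ne",
               "stat_sets", "tolerance", "cutoff", "replicates",
               "draws_per_model", "scaling", "tolerances", "n_values",
               "loci_values"),
  output = c("dir", "prefix"))

#' Read a structured run configuration
#'
#' YAML with the sections `seed`, `demography` (timescale, bot_dur),
#' `priors` (uniform bounds), `scenario` (dataset sizes, true bottleneck,
#' ABC settings, grids) and `output`.  Unknown keys are rejected.  The
#' sample size is spelled `n_samples` (a bare `n` is a YAML 1.1 boolean).
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown keys in '", sec, "': ", paste(bad, collapse = ", "))
  }
  cfg
}

# scenario from a config list (+ optional seed override)
.config_scenario <- function(cfg, seed = NULL) {
  args <- cfg$scenario
  if (!is.null(args$n_samples)) {
    args$n <- args$n_samples
    args$n_samples <- NULL
  }
  args$tolerances <- NULL
  args$n_values <- NULL
  args$loci_values <- NULL
  if (!is.null(cfg$demography$timescale)) args$timescale <- cfg$demography$timescale
  if (!is.null(cfg$demography$bot_dur)) args$bot_dur <- cfg$demography$bot_dur
  if (!is.null(cfg$priors)) args$prior <- do.call(prior_spec, lapply(cfg$priors, unlist))
  args$seed <- if (!is.null(seed)) seed else if (!is.null(cfg$seed)) cfg$seed else 1
  if (!is.null(args$stat_sets)) args$stat_sets <- unlist(args$stat_sets)
  do.call(scenario, args)
}

#' Write a run manifest
#'
#' JSON snapshot sufficient to re-run a stage bit-identically: the
#' configuration, the root seed and derived stage seeds, the package
#' version and a timestamp.
#'
#' @param path Output JSON path.
#' @param config Configuration list (or serialized scenario).
#' @param seed Root seed.
#' @param stage Stage name.
#' @param extra Further named entries.
#' @export
write_manifest <- function(path, config, seed, stage = "run", extra = list()) {
  man <- c(list(stage = stage, seed = seed, config = config,
                package = "abcpower",
                version = as.character(utils::packageVersion("abcpower")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# serialize a scenario for manifests
.scenario_manifest <- function(sc) {
  out <- unclass(sc)
  out$prior <- unclass(out$prior)
  out
}
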