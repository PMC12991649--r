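#' Validate an SOA-aggregated TOJ trial table
#'
#' Checks the schema used throughout the package: columns
#' `participant_id`, `condition`, `soa_ms` (signed ms, negative when the
#' probe leads), `n_trials`, `n_probe_first`; counts must satisfy
#' `0 <= n_probe_first <= n_trials` and (participant, condition, SOA)
#' keys must be unique. Violations raise row-addressed errors.
#'
#' @param x Data frame to validate.
#' @return `x` with class `toj_trial_table`.
#' @export
validate_toj_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("participant_id", "condition", "soa_ms", "n_trials",
            "n_probe_first")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("TOJ table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), need)
  if (length(extra)) {
    stop("TOJ table has unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(x$soa_ms) || any(!is.finite(x$soa_ms))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x$soa_ms))))
    stop("non-numeric SOA at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (col in c("n_trials", "n_probe_first")) {
    v <- x[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) ||
        any(v != round(v))) {
      bad <- which(!is.finite(v) | v < 0 | v != round(v))
      stop(col, " must be non-negative integers; bad row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(x$n_probe_first > x$n_trials)
  if (length(bad)) {
    stop("n_probe_first > n_trials at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$participant_id, x$condition, x$soa_ms)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (participant, condition, soa) key(s) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "),
         "; aggregate trial-long data instead of repeating cells",
         call. = FALSE)
  }
  x$n_trials <- as.integer(x$n_trials)
  x$n_probe_first <- as.integer(x$n_probe_first)
  if (!inherits(x, "toj_trial_table")) {
    class(x) <- c("toj_trial_table", class(x))
  }
  x
}

#' Read a TOJ response table from CSV
#'
#' Accepts either the aggregated schema
#' (`participant_id,condition,soa_ms,n_trials,n_probe_first`) or a
#' trial-long dialect with one row per trial and a 0/1 `probe_first`
#' column (`participant_id,condition,soa_ms,probe_first`), which is
#' aggregated to cells by summation. SOA sign convention: negative means
#' the probe leads. Count violations, unknown columns and non-numeric
#' SOAs raise row-addressed errors.
#'
#' @param path CSV file path.
#' @return A validated `toj_trial_table`.
#' @export
read_toj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  long_cols <- c("participant_id", "condition", "soa_ms", "probe_first")
  if (setequal(names(x), long_cols)) {
    if (!is.numeric(x$probe_first) || !all(x$probe_first %in% c(0, 1))) {
      bad <- which(!(x$probe_first %in% c(0, 1)))
      stop("trial-long `probe_first` must be 0 or 1; bad row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    agg <- stats::aggregate(
      cbind(n_trials = rep(1L, nrow(x)), n_probe_first = x$probe_first),
      by = list(participant_id = x$participant_id,
                condition = x$condition, soa_ms = x$soa_ms),
      FUN = sum)
    agg <- agg[order(agg$participant_id, agg$condition, agg$soa_ms), ]
    rownames(agg) <- NULL
    x <- agg
  }
  validate_toj_table(x)
}

#' Write a TOJ trial table to CSV
#'
#' @param x A `toj_trial_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_toj <- function(x, path) {
  x <- validate_toj_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Validate a matching-task table
#'
#' Schema: `participant_id`, `identity` (self/other), `pairing`
#' (match/mismatch), `n_trials`, `n_correct` with
#' `0 <= n_correct <= n_trials`.
#'
#' @param x Data frame to validate.
#' @return `x` with class `matching_table`.
#' @export
validate_matching_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("participant_id", "identity", "pairing", "n_trials",
            "n_correct")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("matching table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(x$identity %in% c("self", "other"))) {
    stop("`identity` must be \"self\" or \"other\"", call. = FALSE)
  }
  if (!all(x$pairing %in% c("match", "mismatch"))) {
    stop("`pairing` must be \"match\" or \"mismatch\"", call. = FALSE)
  }
  bad <- which(!is.finite(x$n_trials) | !is.finite(x$n_correct) |
                 x$n_correct < 0 | x$n_correct > x$n_trials)
  if (length(bad)) {
    stop("invalid counts (need 0 <= n_correct <= n_trials) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!inherits(x, "matching_table")) {
    class(x) <- c("matching_table", class(x))
  }
  x
}

#' Read / write matching-task tables
#'
#' @param path CSV path.
#' @return A validated `matching_table` ([read_matching()]); the path,
#'   invisibly ([write_matching()]).
#' @export
read_matching <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_matching_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_matching
#' @param x A `matching_table`.
#' @export
write_matching <- function(x, path) {
  x <- validate_matching_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write analysis outputs and a run manifest
#'
#' Writes whichever result objects are supplied as CSV artifacts into
#' `outdir` and records a `manifest.json` listing every file written,
#' the package version, the seed and a diagnostics digest. With no
#' results a manifest with zero artifacts is still written, with a
#' warning.
#'
#' @param outdir Output directory (created if needed).
#' @param summaries A [posterior_summary()] data frame, or a named list
#'   of them (written as `summary_<name>.csv`).
#' @param comparison A `tva_loo_compare`.
#' @param power A `power_result`.
#' @param spe An `spe_result` (participant table plus group row).
#' @param config Optional list echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(outdir, summaries = NULL, comparison = NULL,
                          power = NULL, spe = NULL, config = NULL,
                          seed = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  files <- character(0)
  digest <- list()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(summaries)) {
    if (is.data.frame(summaries)) summaries <- list(posterior = summaries)
    for (nm in names(summaries)) {
      put(summaries[[nm]], sprintf("summary_%s.csv", nm))
      if ("rhat" %in% names(summaries[[nm]])) {
        digest$max_rhat <- max(digest$max_rhat %||% -Inf,
                               max(summaries[[nm]]$rhat, na.rm = TRUE))
      }
    }
  }
  if (!is.null(comparison)) put(comparison, "model_comparison.csv")
  if (!is.null(power)) put(power, "power.csv")
  if (!is.null(spe)) {
    put(spe$participant, "spe_participants.csv")
    put(data.frame(mean_spe = spe$group$mean, ci_lower = spe$group$ci_lower,
                   ci_upper = spe$group$ci_upper, n = spe$group$n),
        "spe_group.csv")
  }
  if (length(files) == 0L) {
    warning("no results supplied; writing an empty manifest", call. = FALSE)
  }
  manifest <- list(
    package = "tvatoj",
    version = as.character(utils::packageVersion("tvatoj")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    diagnostics = digest,
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
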