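#' Construct and validate a source-space epoch dataset
#'
#' A `source_dataset` bundles region-resolved source epochs for a set of
#' subjects under a shared condition design. Epoch arrays are stored per
#' (subject, region, condition) with dimensions vertices x time samples x
#' trials. The time axis must be uniform, strictly increasing, and cover a
#' pre-stimulus baseline segment as well as the post-stimulus analysis
#' window.
#'
#' @param epochs Nested list `epochs[[subject]][[region]][[condition]]`,
#'   each a numeric array `[n_vertices, n_times, n_trials]`.
#' @param time_ms Numeric vector of sample times in milliseconds.
#' @param design A [condition_design()].
#' @param validate Run [validate_source_dataset()] (default `TRUE`).
#' @return Object of class `source_dataset`.
#' @export
source_dataset <- function(epochs, time_ms, design, validate = TRUE) {
  ds <- structure(
    list(subjects = names(epochs),
         regions = names(epochs[[1L]]),
         time_ms = as.numeric(time_ms),
         sampling_step_ms = if (length(time_ms) > 1L) diff(time_ms)[1L] else NA_real_,
         design = design,
         epochs = epochs),
    class = "source_dataset")
  if (validate) validate_source_dataset(ds)
  ds
}

#' Validate the structural invariants of a source dataset
#'
#' Checks that the time axis is strictly increasing and uniform, that it
#' contains pre-stimulus samples and the 0-500 ms analysis window, that all
#' subjects hold all design conditions in every region, that vertex counts
#' are consistent per subject x region (and >= 4), and that all epoch arrays
#' share the time axis length.
#'
#' @param ds A `source_dataset`.
#' @return `ds`, invisibly; otherwise an error naming the violated invariant
#'   and the offending (subject, region, condition).
#' @export
validate_source_dataset <- function(ds) {
  t <- ds$time_ms
  if (length(t) < 2L || any(diff(t) <= 0))
    stop("invariant violated: time_axis must be strictly increasing")
  if (max(abs(diff(t) - diff(t)[1L])) > 1e-9)
    stop("invariant violated: time_axis must have a uniform step")
  if (min(t) > 0) stop("invariant violated: time_axis lacks a pre-stimulus segment")
  if (max(t) < 500) stop("invariant violated: time_axis does not cover the 0-500 ms analysis window")
  cond_labels <- ds$design$conditions$label
  for (s in ds$subjects) {
    if (!identical(sort(names(ds$epochs[[s]])), sort(ds$regions)))
      stop(sprintf("invariant violated: subject '%s' does not hold all regions", s))
    for (r in ds$regions) {
      arrs <- ds$epochs[[s]][[r]]
      missing <- setdiff(cond_labels, names(arrs))
      if (length(missing))
        stop(sprintf("invariant violated: missing condition(s) %s for (%s, %s)",
                     paste(missing, collapse = ", "), s, r))
      nv <- vapply(arrs, function(a) dim(a)[1L], integer(1L))
      nt <- vapply(arrs, function(a) dim(a)[2L], integer(1L))
      if (length(unique(nv)) != 1L)
        stop(sprintf("invariant violated: inconsistent vertex count for (%s, %s)", s, r))
      if (nv[1L] < 4L)
        stop(sprintf("invariant violated: fewer than 4 vertices in (%s, %s)", s, r))
      if (any(nt != length(t)))
        stop(sprintf("invariant violated: epoch time dimension mismatch for (%s, %s, %s)",
                     s, r, names(arrs)[which(nt != length(t))[1L]]))
    }
  }
  invisible(ds)
}

#' @export
print.source_dataset <- function(x, ...) {
  d1 <- dim(x$epochs[[1L]][[1L]][[1L]])
  cat("<source_dataset>", length(x$subjects), "subjects,",
      length(x$regions), "regions,", nrow(x$design$conditions), "conditions\n")
  cat("  time:", min(x$time_ms), "to", max(x$time_ms), "ms, step",
      x$sampling_step_ms, "ms;", "epochs e.g.",
      paste(d1, collapse = " x "), "(vertices x times x trials)\n")
  invisible(x)
}

#' Save / load a source dataset
#'
#' Datasets are serialized as a single RDS file holding the full
#' `source_dataset` structure; loading re-validates all structural
#' invariants, so metadata and arrays round-trip exactly.
#'
#' @param ds A `source_dataset`.
#' @param path File path (conventionally `.rds`).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   validated `source_dataset`.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "source_dataset"))
  saveRDS(ds, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset container not found: ", path)
  ds <- readRDS(path)
  if (!inherits(ds, "source_dataset"))
    stop("schema error: '", path, "' does not contain a source_dataset")
  required <- c("subjects", "regions", "time_ms", "sampling_step_ms",
                "design", "epochs")
  missing <- setdiff(required, names(ds))
  if (length(missing))
    stop("schema error: missing field(s) ", paste(missing, collapse = ", "),
         " in ", path)
  validate_source_dataset(ds)
  ds
}

#' Write result tables with a JSON run manifest
#'
#' Each element of `tables` (a named list of data frames) is written as
#' `<name>.csv` with stable column order; a `manifest.json` records the
#' configuration, seed, package version and the file list with content
#' hashes, so a rerun with the same config and seed is byte-identical up to
#' the timestamp.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config List of configuration values echoed into the manifest.
#' @param seed Integer seed echoed into the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
save_results <- function(tables, dir, config = list(), seed = NA_integer_) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  hashes <- list()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
    hashes[[paste0(nm, ".csv")]] <- file_checksum(p)
  }
  manifest <- list(
    package = "sourcemvpa",
    version = as.character(utils::packageVersion("sourcemvpa")),
    seed = seed,
    config = config,
    files = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}

file_checksum <- function(path) {
  unname(tools::md5sum(path))
}
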