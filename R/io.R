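#' Load a simulation configuration from file and overrides
#'
#' Reads a flat key/value configuration file (YAML or JSON dialect),
#' applies literal overrides on top, fills every remaining field with the
#' [sim_config()] default and validates the result. Unknown keys are
#' rejected with an error naming them.
#'
#' @param path configuration file path, or `NULL` for defaults only.
#' @param overrides named list of field values taking precedence over the
#'   file.
#' @return A validated [sim_config()] object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  values <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("configuration file not found: %s",
                                         path))
    values <- yaml::read_yaml(path)
    if (is.null(values)) values <- list()
  }
  for (key in names(overrides)) values[[key]] <- overrides[[key]]
  defaults <- sim_config()
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  config <- unclass(defaults)
  for (key in names(values)) config[[key]] <- values[[key]]
  do.call(sim_config, config[setdiff(names(config), character())])
}

#' Write / read a run manifest
#'
#' The manifest records everything needed to re-run a simulation exactly:
#' the fully resolved configuration, the seed, the package version,
#' wall-clock start and end times and any warnings (e.g. the equilibrium
#' phase hitting its step cap). It round-trips losslessly through JSON.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed of the run.
#' @param path output JSON path.
#' @param warnings character vector of run warnings.
#' @param started,finished POSIXct timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path, warnings = character(),
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
      config = unclass(config),
      seed = as.integer(seed),
      package = "microbehave",
      version = as.character(utils::packageVersion("microbehave")),
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
      warnings = as.list(warnings))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  manifest$warnings <- as.character(unlist(manifest$warnings))
  manifest
}

#' Write a trajectory to TSV
#'
#' Writes `<prefix>_behavior.tsv` (columns `step`, `phase`, `b1`, one row
#' per simulated step) and, when the trajectory carries recorded
#' compositions, `<prefix>_proportions.tsv` (thinned; columns `step` plus
#' one column per strain).
#'
#' @param trajectory an `mb_trajectory` from [run_addiction()] or the
#'   trajectory element of [run_two_strain()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_trajectory <- function(trajectory, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  n <- length(trajectory$b1)
  phase <- if (!is.null(trajectory$tau))
    rep(c("addiction", "withdrawal"),
        c(trajectory$tau, trajectory$horizon))
  else rep("random_walk", n)
  beh <- data.frame(step = seq_len(n), phase = phase, b1 = trajectory$b1)
  f1 <- file.path(dir, paste0(prefix, "_behavior.tsv"))
  utils::write.table(beh, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f1)
  props <- trajectory$proportions
  if (is.null(props) && !is.null(trajectory$x_affecting) &&
      length(trajectory$x_affecting))
    props <- matrix(trajectory$x_affecting, ncol = 1,
                    dimnames = list(NULL, "x_affecting"))
  if (!is.null(props) && nrow(props) > 0) {
    if (is.null(colnames(props)))
      colnames(props) <- paste0("x", seq_len(ncol(props)))
    pr <- data.frame(step = trajectory$prop_steps, props,
                     check.names = FALSE)
    f2 <- file.path(dir, paste0(prefix, "_proportions.tsv"))
    utils::write.table(pr, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}

#' Write a metrics or sweep table to CSV
#'
#' @param table data frame (replicate metrics, ensemble summary or sweep
#'   results).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
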