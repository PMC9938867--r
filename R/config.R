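# Run configuration: one structured YAML file (key/value with nested
# sections) drives scripted runs; every run can log the resolved config and
# its random seed.

#' Load a run configuration
#'
#' @param path path to a YAML configuration file.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a mapping of keys to values")
  cfg
}

#' Save a run configuration
#'
#' @param config named list of configuration values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Log a resolved configuration and seed
#'
#' Writes a one-run log record (resolved configuration plus the random seed
#' in use) to a connection, so scripted runs are reproducible.
#'
#' @param config named list of configuration values.
#' @param seed integer random seed of the run.
#' @param con connection or path to append to (default stdout).
#' @return Invisibly, the log text.
#' @export
log_run <- function(config, seed, con = stdout()) {
  txt <- c(sprintf("# run at %s, seed %d", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   as.integer(seed)),
           yaml::as.yaml(config))
  writeLines(txt, con)
  invisible(txt)
}
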