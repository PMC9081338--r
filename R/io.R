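# CSV / JSON / YAML readers and writers shared by the workflows, plus the
# round-tripping run configuration.

#' Write / read long-format trace tables
#' @param x traces (see [traces_to_df()]); `path` a CSV file.
#' @return the path (write) or a data.frame (read), invisibly for writers.
#' @export
write_traces_csv <- function(x, path) {
  utils::write.csv(traces_to_df(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param path CSV file.
#' @export
read_traces_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write / read nucleus record tables (shared schema across modules)
#' @param records data.frame of nucleus records; `path` a CSV file.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @param path CSV file.
#' @export
read_records_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_records_csv
#' @export
write_sites_csv <- write_records_csv

#' @rdname write_records_csv
#' @export
read_sites_csv <- read_records_csv

# ---- run configuration ----------------------------------------------------

.known_config_keys <- list(
  trace_study = c("n", "seed", "mixture", "kinetics", "classifier", "out_dir"),
  screen_study = c("seed", "n_compounds", "n_controls", "effects",
                   "n_plates", "site_dropout_prob", "mean_nuclei_per_site",
                   "timepoints_h", "out_dir"))

#' Write / read a run configuration (YAML, lossless round-trip)
#'
#' Unknown keys are rejected on read so that typos in a config file fail
#' loudly rather than being silently ignored.
#'
#' @param config named list with a `trace_study` and/or `screen_study`
#'   section.
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  bad_sections <- setdiff(names(config), names(.known_config_keys))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), .known_config_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  config
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
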