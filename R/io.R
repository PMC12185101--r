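# Plain-text interchange for trial tables and epoch containers.

#' Write / read a trial table as CSV
#'
#' One row per trial, columns exactly as produced by [generate_design()];
#' missing values (e.g. `prev_target_dir` on the first trial of a block) are
#' empty fields.
#'
#' @param trials trial table data frame.
#' @param path CSV file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` the table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}

#' Write / read an epoch container as plain text
#'
#' A directory with `meta.json` (epoch type, time stamps, dimensions, seed),
#' `data.csv` (trials x (sensors * time points), column-major over sensors
#' then time) and `trials.csv`.
#'
#' @param epochs a [sensor_epochs()] object.
#' @param dir directory to create/write.
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` the object.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(epochs$data)
  meta <- list(epoch_type = epochs$epoch_type, binned = epochs$binned,
               seed = epochs$seed, times_ms = epochs$times_ms,
               n_trials = dm[1], n_sensors = dm[2], n_times = dm[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(matrix(epochs$data, dm[1], dm[2] * dm[3]),
                     file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_trials(epochs$trials, file.path(dir, "trials.csv"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.csv"), sep = ","))
  dimnames(flat) <- NULL
  sensor_epochs(array(flat, dim = c(meta$n_trials, meta$n_sensors, meta$n_times)),
                meta$times_ms, read_trials(file.path(dir, "trials.csv")),
                meta$epoch_type, binned = meta$binned,
                seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}
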