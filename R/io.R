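#' Read and write membrane traces as CSV
#'
#' Format: header `time_ms,v_mV,u,I`, one row per grid point, '.' decimal
#' separator.
#'
#' @param trace a `membrane_trace`
#' @param path file path
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `membrane_trace`
#' @name trace_csv
NULL

#' @rdname trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "membrane_trace"))
  df <- data.frame(time_ms = trace$times, v_mV = trace$v, u = trace$u,
                   I = trace$I)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_ms", "v_mV", "u", "I") %in% names(df)))
  new_membrane_trace(df$time_ms, df$v_mV, df$u, df$I)
}

#' Read and write spike trains as plain text
#'
#' One timestamp (ms) per line, after a header line
#' `# duration_ms=<float>`.
#'
#' @param train a [spike_train()]
#' @param path file path
#' @name spike_train_io
NULL

#' @rdname spike_train_io
#' @export
write_spike_train <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  writeLines(c(sprintf("# duration_ms=%.6f", train$duration_ms),
               sprintf("%.6f", train$times_ms)), path)
  invisible(path)
}

#' @rdname spike_train_io
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  if (!grepl("^# duration_ms=", header)) {
    stop("missing '# duration_ms=' header in ", path, call. = FALSE)
  }
  dur <- as.numeric(sub("^# duration_ms=", "", header))
  times <- as.numeric(lines[-1])
  times <- times[!is.na(times)]
  spike_train(times, duration_ms = dur)
}

#' Read and write extracellular recordings
#'
#' CSV with header `sample_index,signal_uV` plus a JSON sidecar
#' `<path>.json` holding `{fs_hz, duration_s}`.  Ground truth is not
#' serialized.
#'
#' @param recording an [extracellular_recording()]
#' @param path CSV path (sidecar written next to it)
#' @name recording_io
NULL

#' @rdname recording_io
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "extracellular_recording"))
  df <- data.frame(sample_index = seq_along(recording$signal) - 1L,
                   signal_uV = recording$signal)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs_hz = recording$fs_hz,
                            duration_s = recording$duration_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  extracellular_recording(df$signal_uV, fs_hz = meta$fs_hz)
}

#' Read and write neuron parameters / stimulus / config as JSON
#'
#' Flat keys `a, b, c, d`, `stimulus.kind`, `stimulus.amplitude`, `dt_ms`,
#' `duration_ms` (nested objects for the stimulus segments).
#'
#' @param params,path see below
#' @name params_json
NULL

#' @rdname params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "neuron_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  neuron_params(x$a, x$b, x$c, x$d)
}

#' Serialize a fit result to JSON
#'
#' `{best_params: {a,b,c,d}, best_fitness, generations_run,
#' fitness_history: [...], config: {...}}`.
#'
#' @param fit a `fit_result`
#' @param path file path
#' @export
write_fit_result_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  cfg <- fit$config
  cfg$bounds <- apply(cfg$bounds, 1, as.list)
  jsonlite::write_json(
    list(best_params = unclass(fit$best_params),
         best_fitness = fit$best_fitness,
         generations_run = fit$generations_run,
         fitness_history = fit$fitness_history,
         config = unclass(cfg)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a possible-pattern matrix as CSV
#'
#' @param tab data.frame from [pattern_table()]
#' @param path file path
#' @export
write_pattern_matrix_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
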