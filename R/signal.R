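#' Respiration surrogate signal
#'
#' A uniformly sampled, unitless respiration surrogate trace, the 1D chest
#' surface signal a phase-gating system records (e.g. a laser distance sensor
#' sampling at 20 Hz). Amplitude carries no physical unit; the gating module
#' rescales it to millimetres when tumor excursion is assumed.
#'
#' @param samples Numeric vector of amplitude values (finite).
#' @param sampling_rate_hz Samples per second, > 0. Default 20 Hz, the rate of
#'   the clinical surrogate recordings this package emulates.
#' @param id Opaque signal identifier.
#' @param metadata Optional list: generator parameters or source-file path.
#'
#' @return An object of class `respiration_signal`: a list with elements
#'   `samples`, `sampling_rate_hz`, `duration_s`, `id`, `metadata`.
#' @export
respiration_signal <- function(samples, sampling_rate_hz = 20, id = "signal",
                               metadata = list()) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      duration_s = length(samples) / sampling_rate_hz,
      id = as.character(id),
      metadata = metadata
    ),
    class = "respiration_signal"
  )
}

#' @export
print.respiration_signal <- function(x, ...) {
  cat(sprintf(
    "<respiration_signal '%s'>: %d samples @ %g Hz (%.2f s), range [%.3f, %.3f]\n",
    x$id, length(x$samples), x$sampling_rate_hz, x$duration_s,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.respiration_signal <- function(x) length(x$samples)

#' Sample times of a signal
#'
#' Times in seconds of each sample, starting at 0.
#'
#' @param signal A [respiration_signal()].
#' @return Numeric vector, same length as `signal$samples`.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "respiration_signal"))
  (seq_along(signal$samples) - 1) / signal$sampling_rate_hz
}

#' Write a signal to CSV
#'
#' Two columns `time_s,amplitude`, values printed with 6 decimal places.
#'
#' @param signal A [respiration_signal()].
#' @param path Output file path.
#' @param config Optional list written as a JSON sidecar (`<path>.json`).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path, config = NULL) {
  stopifnot(inherits(signal, "respiration_signal"))
  df <- data.frame(
    time_s = sprintf("%.6f", signal_times(signal)),
    amplitude = sprintf("%.6f", signal$samples)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a signal from CSV
#'
#' Expects columns `time_s,amplitude` with uniform timestamps. Sampling
#' intervals deviating by more than 10% from the nominal interval are rejected
#' rather than resampled.
#'
#' @param path CSV file path.
#' @param expected_rate_hz Nominal sampling rate; timestamps are checked
#'   against its interval. Default 20.
#' @param id Signal identifier; defaults to the file name without extension.
#' @return A [respiration_signal()].
#' @export
read_signal_csv <- function(path, expected_rate_hz = 20, id = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    stop("CSV must have columns `time_s` and `amplitude`", call. = FALSE)
  }
  if (nrow(df) >= 2) {
    dt <- diff(df$time_s)
    nominal <- 1 / expected_rate_hz
    if (any(abs(dt - nominal) > 0.1 * nominal)) {
      stop(sprintf(
        "non-uniform timestamps: sampling interval deviates >10%% from %g s",
        nominal
      ), call. = FALSE)
    }
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  respiration_signal(df$amplitude, sampling_rate_hz = expected_rate_hz,
                     id = id, metadata = list(source = path))
}
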