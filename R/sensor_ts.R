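#' Continuous multichannel sensor recording
#'
#' Light container for a channels x time recording at a fixed sampling rate.
#'
#' @param data Numeric matrix, channels x time. No missing values.
#' @param rate_hz Sampling rate in samples per second (> 0).
#' @param session_id Character label for the session.
#' @return An object of class `sensor_ts`.
#' @export
sensor_ts <- function(data, rate_hz, session_id = "session") {
  data <- as.matrix(data)
  if (anyNA(data)) stop("sensor data must not contain missing values")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar")
  structure(list(data = data, rate_hz = rate_hz,
                 session_id = as.character(session_id)),
            class = "sensor_ts")
}

#' @export
print.sensor_ts <- function(x, ...) {
  cat(sprintf("<sensor_ts '%s': %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$session_id, nrow(x$data), ncol(x$data), x$rate_hz,
              ncol(x$data) / x$rate_hz))
  invisible(x)
}

n_samples <- function(ts) ncol(ts$data)
n_channels <- function(ts) nrow(ts$data)

ms_to_samples <- function(ms, rate_hz, what = "lag") {
  x <- ms * rate_hz / 1000
  if (abs(x - round(x)) > 1e-8)
    stop(sprintf("%s of %g ms is not a multiple of the sample period (%g ms)",
                 what, ms, 1000 / rate_hz))
  as.integer(round(x))
}

#' Write / read a sensor recording as delimited text
#'
#' One channel per row, samples in columns; the sampling rate and session id
#' travel in a JSON side-car file (`<path>.json`).
#'
#' @param ts A [sensor_ts()].
#' @param path Output TSV path.
#' @return `write_sensor_tsv` returns `path` invisibly; `read_sensor_tsv`
#'   returns a [sensor_ts()].
#' @export
write_sensor_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "sensor_ts"))
  utils::write.table(ts$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(rate_hz = ts$rate_hz, session_id = ts$session_id,
                            n_channels = nrow(ts$data)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sensor_tsv
#' @export
read_sensor_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  data <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  sensor_ts(data, rate_hz = meta$rate_hz, session_id = meta$session_id)
}
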