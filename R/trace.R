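# The (time, signal) series that is the common currency of simulation
# output, synthetic data and analysis input, plus its CSV serialisation.

#' Create a time-series trace
#'
#' @param time Numeric vector of times in seconds, strictly increasing,
#'   length >= 2.
#' @param signal Numeric vector of the same length (absorbance units, uM,
#'   %, or a relative signal, as labelled by `units`).
#' @param units Unit label for the signal.
#' @param meta Optional list of provenance tags.
#' @return An object of class `redox_trace`.
#' @export
redox_trace <- function(time, signal, units = "AU", meta = list()) {
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal)) {
    stop("`time` and `signal` must have equal length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a trace needs at least 2 points", call. = FALSE)
  }
  if (anyNA(time) || anyNA(signal)) {
    stop("trace contains missing values", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(list(time = time, signal = signal, units = units, meta = meta),
            class = "redox_trace")
}

#' @export
print.redox_trace <- function(x, ...) {
  cat(sprintf("<redox_trace> %d points, t = %g..%g s, signal %g..%g [%s]\n",
              length(x$time), min(x$time), max(x$time), min(x$signal),
              max(x$signal), x$units))
  invisible(x)
}

#' @export
as.data.frame.redox_trace <- function(x, ...) {
  data.frame(time_s = x$time, signal = x$signal)
}

#' Write a trace to CSV
#'
#' Plain CSV with header `time_s,signal`; values are written with 15
#' significant digits so that [read_trace()] round-trips them to better than
#' 1e-12 relative.
#'
#' @param trace A [redox_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "redox_trace"))
  lines <- c("time_s,signal",
             paste(sprintf("%.15g", trace$time),
                   sprintf("%.15g", trace$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Expects the `time_s,signal` format written by [write_trace()]; enforces
#' strictly increasing time on read.
#'
#' @param path Input file path.
#' @param units Unit label to attach.
#' @return A [redox_trace()].
#' @export
read_trace <- function(path, units = "AU") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("malformed trace CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(names(df), c("time_s", "signal"))) {
    stop("trace CSV must have header 'time_s,signal'", call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("trace CSV '", path, "' has fewer than 2 rows", call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("non-monotone (or duplicated) time in '", path, "'",
         call. = FALSE)
  }
  redox_trace(df$time_s, df$signal, units = units,
              meta = list(source = path))
}

#' Restrict a trace to a time interval
#'
#' @param trace A [redox_trace()].
#' @param from,to Interval bounds in seconds (inclusive).
#' @return A [redox_trace()] over the subinterval.
#' @export
trace_window <- function(trace, from = -Inf, to = Inf) {
  keep <- trace$time >= from & trace$time <= to
  if (sum(keep) < 2L) {
    stop("fewer than 2 trace points in [", from, ", ", to, "] s",
         call. = FALSE)
  }
  redox_trace(trace$time[keep], trace$signal[keep], units = trace$units,
              meta = trace$meta)
}
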