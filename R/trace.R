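#' Construct a time-series trace
#'
#' A trace is a tibble with columns `time_s` (strictly increasing, seconds)
#' and `value`, carrying a `channel` attribute naming the signal:
#' `"raw_fluorescence"` (arbitrary units), `"phi"` (normalized variable
#' fluorescence) or `"p_plus"` (fractional oxidized dimer). Normalized
#' channels must stay within `[-0.05, 1.05]`; small noise excursions outside
#' `[0, 1]` are tolerated.
#'
#' @param x A data frame whose first two columns (or columns named `time_s`
#'   and `value`) hold times and signal values.
#' @param channel Signal channel, one of `"raw_fluorescence"`, `"phi"`,
#'   `"p_plus"`.
#' @param min_points Minimum number of samples required (default 2; analysis
#'   functions impose their own stricter minima).
#' @return A tibble of class `rc_trace`.
#' @examples
#' as_trace(data.frame(time_s = 1:10 / 1e4, value = (1:10) / 10), "phi")
#' @export
as_trace <- function(x, channel = c("raw_fluorescence", "phi", "p_plus"),
                     min_points = 2L) {
  channel <- match.arg(channel)
  x <- as.data.frame(x)
  if (all(c("time_s", "value") %in% names(x))) {
    x <- x[c("time_s", "value")]
  } else if (ncol(x) >= 2L) {
    x <- setNames(x[1:2], c("time_s", "value"))
  } else {
    rcf_abort("A trace needs two columns: time_s and value.",
              "rcfluor_error_trace")
  }
  if (!is.numeric(x$time_s) || !is.numeric(x$value) || anyNA(x)) {
    rcf_abort("Trace columns must be numeric without NAs.",
              "rcfluor_error_trace")
  }
  if (nrow(x) < min_points) {
    rcf_abort(sprintf("Trace has %d samples; at least %d required.",
                      nrow(x), min_points), "rcfluor_error_trace")
  }
  if (any(diff(x$time_s) <= 0)) {
    rcf_abort("Trace times must be strictly increasing.",
              "rcfluor_error_trace")
  }
  if (channel %in% c("phi", "p_plus") &&
      (min(x$value) < -0.05 || max(x$value) > 1.05)) {
    rcf_abort(sprintf(
      "Channel '%s' must lie within [-0.05, 1.05]; observed [%.3g, %.3g].",
      channel, min(x$value), max(x$value)), "rcfluor_error_trace")
  }
  out <- as_tibble(x)
  attr(out, "channel") <- channel
  class(out) <- c("rc_trace", class(out))
  out
}

#' @rdname as_trace
#' @export
trace_channel <- function(x) attr(x, "channel") %||% NA_character_

#' Read / write a trace as two-column CSV
#'
#' The on-disk dialect is a single header line `time_s,value`, `.` decimal
#' separator. The channel is declared by the caller, never inferred from the
#' file.
#'
#' @param path CSV file path.
#' @inheritParams as_trace
#' @return `read_trace()` returns an `rc_trace` tibble; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path, channel = c("raw_fluorescence", "phi", "p_plus"),
                       min_points = 2L) {
  if (!file.exists(path)) {
    rcf_abort(sprintf("Trace file not found: %s", path), "rcfluor_error_io")
  }
  df <- tryCatch(read.csv(path), error = function(e) {
    rcf_abort(sprintf("Cannot parse CSV '%s': %s", path, conditionMessage(e)),
              "rcfluor_error_io")
  })
  tryCatch(as_trace(df, channel, min_points = min_points),
           rcfluor_error_trace = function(e) {
             rcf_abort(sprintf("Malformed trace in '%s': %s",
                               path, conditionMessage(e)), "rcfluor_error_io")
           })
}

#' @rdname read_trace
#' @param trace An `rc_trace` tibble (or any data frame with `time_s`,
#'   `value` columns).
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)[c("time_s", "value")]
  lines <- c("time_s,value",
             sprintf("%.12g,%.12g", df$time_s, df$value))
  writeLines(lines, path)
  invisible(path)
}

#' Average replicate traces point-by-point
#'
#' Experimental inductions are routinely recorded as a handful of replicate
#' sweeps and averaged. Replicates are aligned onto the time grid of the
#' first trace, restricted to the time window covered by every replicate,
#' by linear interpolation, then averaged per time point.
#'
#' @param traces A list of traces (see [as_trace()]) sharing a channel.
#' @return An `rc_trace` tibble on the common grid.
#' @export
average_traces <- function(traces) {
  if (!length(traces)) rcf_abort("No traces supplied.", "rcfluor_error_trace")
  ch <- trace_channel(traces[[1]])
  lo <- max(vapply(traces, function(tr) min(tr$time_s), numeric(1)))
  hi <- min(vapply(traces, function(tr) max(tr$time_s), numeric(1)))
  if (lo >= hi) {
    rcf_abort("Traces have no overlapping time window.",
              "rcfluor_error_trace")
  }
  grid <- traces[[1]]$time_s
  grid <- grid[grid >= lo & grid <= hi]
  vals <- vapply(traces,
                 function(tr) approx(tr$time_s, tr$value, xout = grid)$y,
                 numeric(length(grid)))
  as_trace(tibble(time_s = grid, value = rowMeans(vals)),
           channel = if (is.na(ch)) "raw_fluorescence" else ch)
}

#' @export
autoplot.rc_trace <- function(object, ...) {
  ch <- trace_channel(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ch %||% "value") +
    ggplot2::theme_minimal()
}
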