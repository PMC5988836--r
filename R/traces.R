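#' Construct a single-cell ratio trace
#'
#' A trace is the FRET/CFP ratio time course of one cell: a data frame with
#' columns `time_min` (strictly increasing, uniformly spaced) and `value`
#' (dimensionless ratio; `NA` marks frames with no valid pixels), plus
#' optional `cell_id` and `condition` columns.
#'
#' @param time_min Sampling times in minutes (uniform spacing, >= 4 samples).
#' @param value Ratio values (same length as `time_min`).
#' @param cell_id Optional cell identifier.
#' @param condition Optional condition label.
#' @return A validated trace `data.frame`.
#' @export
trace <- function(time_min, value, cell_id = NULL, condition = NULL) {
  out <- data.frame(time_min = as.numeric(time_min),
                    value = as.numeric(value))
  if (!is.null(cell_id)) out$cell_id <- cell_id
  if (!is.null(condition)) out$condition <- condition
  validate_trace(out)
  out
}

#' Validate a trace
#'
#' Checks the trace contract: at least 4 samples, strictly increasing and
#' uniformly spaced times (to within 1e-6 relative), numeric values.
#'
#' @param x A trace data frame (see [trace()]).
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_trace <- function(x) {
  if (!is.data.frame(x) || !all(c("time_min", "value") %in% names(x))) {
    stop("a trace needs `time_min` and `value` columns", call. = FALSE)
  }
  tt <- x$time_min
  if (length(tt) < 4L) {
    stop("a trace needs at least 4 samples", call. = FALSE)
  }
  dt <- diff(tt)
  if (any(dt <= 0)) stop("trace times must be strictly increasing",
                         call. = FALSE)
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("trace times must be uniformly spaced", call. = FALSE)
  }
  if (!is.numeric(x$value)) stop("trace values must be numeric", call. = FALSE)
  invisible(x)
}

# Sampling interval of a trace, in minutes.
trace_interval <- function(x) mean(diff(x$time_min))

#' Smooth a trace with a centred moving average
#'
#' Replaces each value by the mean of all samples within `window / 2` minutes
#' of its time point (a 6-min window at 1.5-min sampling averages 5 samples at
#' interior points). The window shrinks at the ends of the recording rather
#' than padding, and missing (`NA`) frames are excluded from the mean rather
#' than interpolated, so output length equals input length.
#'
#' @param x A trace data frame.
#' @param window Total window span in minutes (default 6). Must be at least
#'   the sampling interval.
#' @return The trace with smoothed `value`.
#' @export
moving_average <- function(x, window = 6) {
  validate_trace(x)
  dt <- trace_interval(x)
  if (!is.numeric(window) || length(window) != 1L || window < dt) {
    stop("`window` must be a single number >= the sampling interval (",
         signif(dt, 4), " min)", call. = FALSE)
  }
  half <- window / 2 + 1e-9 * window
  k <- floor(half / dt)                     # samples on each side
  v <- x$value
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - k):min(n, i + k)
    out[i] <- mean(v[j], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  x$value <- out
  x
}

#' Normalize a trace to its pre-treatment baseline
#'
#' Divides every value by the mean ratio within `baseline_window`, so the
#' baseline mean of the output is 1. Used to compare responses across cells
#' whose absolute FRET/CFP levels differ.
#'
#' @param x A trace data frame.
#' @param baseline_window Length-2 numeric `c(from, to)` in minutes; must
#'   contain at least 2 non-missing samples with positive mean.
#' @return The normalized trace.
#' @export
normalize_to_baseline <- function(x, baseline_window) {
  validate_trace(x)
  if (!is.numeric(baseline_window) || length(baseline_window) != 2L) {
    stop("`baseline_window` must be c(from, to) in minutes", call. = FALSE)
  }
  sel <- x$time_min >= baseline_window[1] & x$time_min <= baseline_window[2] &
    !is.na(x$value)
  if (sum(sel) < 2L) {
    stop("baseline window must contain at least 2 samples", call. = FALSE)
  }
  m <- mean(x$value[sel])
  if (!is.finite(m) || m <= 0) {
    stop("baseline mean must be positive", call. = FALSE)
  }
  x$value <- x$value / m
  x
}

#' Temporal autocorrelation of a trace
#'
#' Mean-subtracted sample autocorrelation, used to ask whether pulsatile
#' activity has any periodicity (a periodic signal shows secondary maxima at
#' its period; sporadic pulses do not). `r(0) = 1` and `|r(k)| <= 1`.
#'
#' @param x A trace data frame with positive variance and no missing values.
#' @param max_lag Maximum lag in frames; must be less than half the trace
#'   length.
#' @return Named numeric vector of coefficients for lags `0:max_lag` (names
#'   are lag times in minutes).
#' @export
autocorrelation <- function(x, max_lag = NULL) {
  validate_trace(x)
  v <- x$value
  if (anyNA(v)) stop("autocorrelation requires a complete trace", call. = FALSE)
  n <- length(v)
  if (is.null(max_lag)) max_lag <- floor(n / 2) - 1L
  if (max_lag >= n / 2) {
    stop("`max_lag` must be less than half the trace length", call. = FALSE)
  }
  if (stats::var(v) <= 0) {
    stop("autocorrelation of a zero-variance trace is undefined",
         call. = FALSE)
  }
  r <- drop(stats::acf(v, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)
  names(r) <- (0:max_lag) * trace_interval(x)
  r
}

#' Split a long trace table into per-cell traces
#'
#' @param x Data frame with `cell_id`, `time_min`, `value` (and optionally
#'   `condition`) columns.
#' @return Named list of single-cell trace data frames.
#' @export
split_traces <- function(x) {
  if (!all(c("cell_id", "time_min", "value") %in% names(x))) {
    stop("need `cell_id`, `time_min` and `value` columns", call. = FALSE)
  }
  out <- split(x, x$cell_id)
  lapply(out, function(d) d[order(d$time_min), , drop = FALSE])
}

#' Write / read trace tables as CSV
#'
#' Long format with columns `cell_id`, `time_min`, `value` and, when present,
#' `condition`.
#'
#' @param x Trace table.
#' @param path File path.
#' @return `read_traces` returns the trace table; `write_traces` returns
#'   `path` invisibly.
#' @export
write_traces <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a cell-by-time matrix for heat-map display
#'
#' Reshapes a long trace table into a matrix with one row per cell and one
#' column per time point (the layout used for population heat maps of ERK
#' activity).
#'
#' @param x Long trace table with `cell_id`, `time_min`, `value`.
#' @param path Optional CSV path; when given the matrix is also written.
#' @return Numeric matrix (cells x time points), invisibly when `path` is
#'   given.
#' @export
trace_matrix <- function(x, path = NULL) {
  traces <- split_traces(x)
  times <- sort(unique(x$time_min))
  m <- t(vapply(traces, function(d) {
    d$value[match(times, d$time_min)]
  }, numeric(length(times))))
  colnames(m) <- times
  if (!is.null(path)) {
    utils::write.csv(data.frame(cell_id = rownames(m), m, check.names = FALSE),
                     path, row.names = FALSE)
    return(invisible(m))
  }
  m
}
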