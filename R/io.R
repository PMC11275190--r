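#' Read a trace from a two-column CSV file
#'
#' Expects a header row and two numeric columns, time in seconds and the
#' measured value.  Sampling must be uniform: the maximum deviation of
#' successive time deltas from their mean must be below `1e-6 * dt`.
#'
#' @param path Path to the CSV file.
#' @param unit Unit of the value column, `"mV"` or `"uA"`.
#' @param label Optional label attached to the returned trace.
#'
#' @return A [trace].
#' @export
read_trace_csv <- function(path, unit = c("mV", "uA"), label = "") {
  unit <- match.arg(unit)
  if (!file.exists(path))
    ps_stop(paste0("file not found: ", path), "io_missing_file")
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2L)
    ps_stop("trace CSV must have two columns (time, value)", "trace_bad_columns")
  tcol <- df[[1]]; vcol <- df[[2]]
  if (!is.numeric(tcol) || !is.numeric(vcol) || anyNA(tcol) || anyNA(vcol))
    ps_stop("trace CSV contains non-numeric cells", "trace_nonnumeric")
  if (length(tcol) < 2L)
    ps_stop("trace CSV needs at least two rows", "trace_too_short")
  deltas <- diff(tcol)
  if (any(deltas <= 0))
    ps_stop("time column is not strictly increasing", "trace_nonmonotone")
  dt <- mean(deltas)
  if (max(abs(deltas - dt)) >= 1e-6 * dt)
    ps_stop("sampling is not uniform within tolerance (1e-6 * dt)",
            "trace_nonuniform")
  trace(vcol, dt = dt, unit = unit, t0 = tcol[1], label = label)
}

#' Write a trace to a two-column CSV file
#'
#' Writes header `time_s,value` followed by one row per sample.  Times are
#' seconds from recording start.
#'
#' @param x A [trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  lines <- c("time_s,value",
             paste(formatC(trace_times(x), format = "g", digits = 15),
                   formatC(x$values, format = "g", digits = 15), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Moment-statistics row for one exposure condition
#'
#' One row of a spike-metrics table: the condition label plus mean, standard
#' deviation, max, min, kurtosis and skewness of the summarized quantity
#' (spike amplitude in mV, or interspike period in s).
#'
#' @param condition Condition label.
#' @param mean,sd,max,min Moments in the units of the summarized quantity.
#' @param kurtosis Non-excess kurtosis (Gaussian = 3).
#' @param skewness Moment skewness g1.
#' @return A one-row `data.frame` with the seven canonical columns.
#' @export
metrics_row <- function(condition, mean, sd, max, min, kurtosis, skewness) {
  if (sd < 0) ps_stop("sd must be >= 0", "metrics_invalid")
  if (!(min <= mean && mean <= max))
    ps_stop("metrics row must satisfy min <= mean <= max", "metrics_invalid")
  data.frame(Condition = as.character(condition), Mean = mean, StdDev = sd,
             Max = max, Min = min, Kurtosis = kurtosis, Skewness = skewness,
             stringsAsFactors = FALSE)
}

metrics_columns <- c("Condition", "Mean", "StdDev", "Max", "Min",
                     "Kurtosis", "Skewness")

#' Write a metrics table to CSV
#'
#' Seven columns in the canonical order (condition, mean, SD, max, min,
#' kurtosis, skewness), with fixed decimal formatting: `digits_moments`
#' decimals for mean/SD/max/min and `digits_shape` decimals for
#' kurtosis/skewness.
#'
#' @param rows A `data.frame` of stacked [metrics_row] rows.
#' @param path Output path.
#' @param digits_moments Decimals for mean/SD/max/min (default 3).
#' @param digits_shape Decimals for kurtosis/skewness (default 2).
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(rows, path, digits_moments = 3,
                                digits_shape = 2) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    ps_stop("`rows` must be a non-empty data.frame", "metrics_invalid")
  if (!all(metrics_columns %in% names(rows)))
    ps_stop("`rows` is missing canonical metrics columns", "metrics_invalid")
  rows <- rows[, metrics_columns]
  fmt <- function(v, d) formatC(v, format = "f", digits = d)
  body <- paste(rows$Condition,
                fmt(rows$Mean, digits_moments), fmt(rows$StdDev, digits_moments),
                fmt(rows$Max, digits_moments), fmt(rows$Min, digits_moments),
                fmt(rows$Kurtosis, digits_shape), fmt(rows$Skewness, digits_shape),
                sep = ",")
  writeLines(c(paste(metrics_columns, collapse = ","), body), path)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table]
#' @param path Path to the CSV file.
#' @return A `data.frame` with the seven canonical columns.
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!identical(names(df), metrics_columns))
    ps_stop("metrics CSV does not have the canonical column set",
            "metrics_invalid")
  df
}

#' Export a metrics table as JSON
#' @param rows A metrics `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
metrics_to_json <- function(rows, path) {
  jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
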