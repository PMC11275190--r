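#' Uniformly sampled recording trace
#'
#' Container for a uniformly sampled time series: a voltage recording
#' (millivolts) or a chronoamperometric current recording (microamperes).
#' Time is measured in seconds from the start of the recording.
#'
#' @param values Numeric vector of samples (non-empty, finite).
#' @param dt Sampling interval in seconds (> 0).
#' @param unit Measurement unit, `"mV"` (voltage) or `"uA"` (current).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param label Free-text label, typically the exposure condition.
#'
#' @return An object of class `trace`: a list with elements `values`, `dt`,
#'   `t0`, `unit`, `label`.
#' @export
#'
#' @examples
#' tr <- trace(sin(2 * pi * (0:99) / 50), dt = 1, unit = "mV")
#' trace_times(tr)[1:5]
trace <- function(values, dt, unit = c("mV", "uA"), t0 = 0, label = "") {
  unit <- match.arg(unit)
  if (!is.numeric(values) || length(values) == 0L)
    ps_stop("`values` must be a non-empty numeric vector", "trace_invalid")
  if (anyNA(values) || any(!is.finite(values)))
    ps_stop("`values` must be finite", "trace_invalid")
  if (!is_num1(dt) || dt <= 0)
    ps_stop("`dt` must be a single positive number", "trace_invalid")
  structure(
    list(values = as.numeric(values), dt = as.numeric(dt),
         t0 = as.numeric(t0), unit = unit, label = as.character(label)[1]),
    class = "trace")
}

#' @rdname trace
#' @param x A `trace` object.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt = %g s, unit = %s%s\n",
              length(x$values), x$dt, x$unit,
              if (nzchar(x$label)) paste0(", label = '", x$label, "'") else ""))
  cat(sprintf("  range [%.4g, %.4g], duration %g s\n",
              min(x$values), max(x$values),
              (length(x$values) - 1) * x$dt))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)
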