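#' Least-squares B-spline baseline fit
#'
#' Fits a B-spline of the given degree with uniformly spaced interior knots
#' to a trace by (optionally masked) least squares and returns the fitted
#' baseline together with the residual trace.  Knots are clamped at the
#' boundaries (standard B-spline basis with repeated end knots).  The fit is
#' additive by construction: `baseline + residual` reproduces the input to
#' machine precision.
#'
#' @param x A [trace].
#' @param knot_spacing Interior knot spacing in seconds; must be at least
#'   `2 * dt` (tighter knots would chase the spikes themselves).
#' @param degree Spline degree (default 3, cubic).
#' @param exclude Optional logical vector (length of the trace) marking
#'   samples to leave out of the fit (e.g. spike windows); the baseline is
#'   still evaluated everywhere.
#' @return An object of class `baseline_fit`: list with `baseline` (numeric
#'   vector), `residual` (a [trace]), `knots` (interior knot positions, s),
#'   `coefficients`, `degree`.
#' @export
#'
#' @examples
#' tr <- trace(rep(2, 100), dt = 1, unit = "mV")
#' bf <- fit_baseline(tr, knot_spacing = 20)
#' max(abs(bf$residual$values))  # ~0
fit_baseline <- function(x, knot_spacing, degree = 3, exclude = NULL) {
  stopifnot(inherits(x, "trace"))
  if (!is_num1(knot_spacing) || knot_spacing < 2 * x$dt)
    ps_stop("knot_spacing must be >= 2 * dt", "baseline_invalid")
  if (!is_count(degree)) ps_stop("degree must be a positive integer",
                                 "baseline_invalid")
  n <- length(x$values)
  tt <- trace_times(x)
  if (n < (degree + 2))
    ps_stop("trace too short for the requested spline degree",
            "baseline_invalid")
  a <- tt[1]; b <- tt[n]
  interior <- if (b - a > knot_spacing)
    seq(a + knot_spacing, b - knot_spacing / 2, by = knot_spacing)
  else numeric(0)
  B <- splines::bs(tt, knots = interior, degree = degree,
                   intercept = TRUE, Boundary.knots = c(a, b))
  keep <- if (is.null(exclude)) rep(TRUE, n) else !exclude
  if (sum(keep) < ncol(B))
    ps_stop("too few unmasked samples for the spline basis",
            "baseline_invalid")
  # normal equations on the kept samples; basis is well-conditioned at these
  # knot densities
  Bk <- B[keep, , drop = FALSE]
  coef <- solve(crossprod(Bk), crossprod(Bk, x$values[keep]))
  baseline <- as.numeric(B %*% coef)
  res <- x
  res$values <- x$values - baseline
  structure(list(baseline = baseline, residual = res,
                 knots = interior, coefficients = as.numeric(coef),
                 degree = degree),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> degree %d, %d interior knots, residual RMS %.4g\n",
              x$degree, length(x$knots), sqrt(mean(x$residual$values^2))))
  invisible(x)
}

# First-pass ISI estimate used for the default knot spacing: running-median
# detrend (robust to spikes) followed by a MAD-threshold peak scan.
estimate_median_isi <- function(x, window_s = 301) {
  k <- min(length(x$values), max(3, round(window_s / x$dt)))
  if (k %% 2 == 0) k <- k + 1
  resid <- x$values - stats::runmed(x$values, k)
  rt <- x; rt$values <- resid
  ev <- detect_spikes(rt)
  if (length(ev$times) < 3) return(NA_real_)
  stats::median(diff(ev$times))
}

#' Detrend a trace with a spike-aware B-spline baseline
#'
#' Two-pass drift removal: a first least-squares B-spline fit gives a
#' provisional residual on which spikes are detected; the baseline is then
#' refit with the detected spike windows masked out, so spike mass is not
#' absorbed into the baseline.  The default knot spacing is 10 times the
#' median interspike interval from a first-pass peak scan, keeping knots
#' sparse relative to spike spacing.
#'
#' @param x A [trace] (voltage).
#' @param knot_spacing Interior knot spacing, s; `NULL` (default) uses
#'   `10 * median ISI` from the first-pass scan.
#' @param degree Spline degree (default 3).
#' @param refine Mask detected spikes and refit (default `TRUE`).
#' @param ... Detection parameters passed to [detect_spikes].
#' @return A `baseline_fit` whose `residual` is the detrended trace.
#' @export
detrend_trace <- function(x, knot_spacing = NULL, degree = 3,
                          refine = TRUE, ...) {
  stopifnot(inherits(x, "trace"))
  if (is.null(knot_spacing)) {
    med_isi <- estimate_median_isi(x)
    duration <- (length(x$values) - 1) * x$dt
    knot_spacing <- if (is.na(med_isi)) duration / 8 else 10 * med_isi
    knot_spacing <- max(knot_spacing, 2 * x$dt)
  }
  fit <- fit_baseline(x, knot_spacing, degree)
  if (!refine) return(fit)
  ev <- detect_spikes(fit$residual, ...)
  if (length(ev$times) == 0) return(fit)
  # mask the pulse support around each detected peak (seconds; covers the
  # default biexponential pulse down to ~1% of peak height)
  tt <- trace_times(x)
  mask <- rep(FALSE, length(tt))
  for (tp in ev$times)
    mask[tt >= tp - 20 & tt <= tp + 100] <- TRUE
  if (sum(!mask) < (degree + 2) * (length(fit$knots) + 2)) return(fit)
  fit_baseline(x, knot_spacing, degree, exclude = mask)
}
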