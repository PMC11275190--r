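#' Detect spikes on a detrended voltage trace
#'
#' Finds local maxima exceeding an absolute threshold with at least the
#' requested topographic prominence (height above the higher of the two
#' flanking minima, walking out to the nearest higher sample on each side).
#' Maxima closer together than the refractory interval are merged, keeping
#' the larger.  Spike amplitude is the residual value at the peak sample.
#'
#' Defaults follow robust-noise conventions: threshold and prominence both
#' `5 * MAD` of the residual, refractory 30 s (well below the smallest
#' published interspike interval).  Prominence shares the 5 MAD bar because
#' noise-induced local maxima on the decay shoulders of large spikes sit
#' beyond any admissible refractory and a laxer prominence bar admits them.
#'
#' @param x A detrended voltage [trace].
#' @param threshold Absolute detection threshold, mV; `NULL` for `5 * MAD`.
#' @param min_prominence Minimum prominence, mV; `NULL` for `5 * MAD`.
#' @param refractory Merge window, s (default 30).
#' @return A [spike_events] object.
#' @export
detect_spikes <- function(x, threshold = NULL, min_prominence = NULL,
                          refractory = 30) {
  stopifnot(inherits(x, "trace"))
  v <- x$values
  n <- length(v)
  mad_v <- stats::mad(v)
  if (is.null(threshold)) threshold <- 5 * mad_v
  if (is.null(min_prominence)) min_prominence <- 5 * mad_v
  if (threshold < 0 || refractory < 0)
    ps_stop("threshold and refractory must be non-negative", "detect_invalid")
  if (n < 3) return(spike_events(numeric(0), numeric(0)))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > threshold]
  if (length(cand) == 0) return(spike_events(numeric(0), numeric(0)))
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(spike_events(numeric(0), numeric(0)))
  tt <- trace_times(x)
  # refractory merge: keep the larger of peaks closer than `refractory`
  keep_i <- cand[1]
  out <- integer(0)
  for (i in cand[-1]) {
    if (tt[i] - tt[keep_i] < refractory) {
      if (v[i] > v[keep_i]) keep_i <- i
    } else {
      out <- c(out, keep_i)
      keep_i <- i
    }
  }
  out <- c(out, keep_i)
  spike_events(tt[out], v[out])
}

# topographic prominence of peak at index i: walk out each side to the
# nearest strictly higher sample (or the trace end), track the minimum;
# prominence = peak - max(left minimum, right minimum)
peak_prominence <- function(v, i) {
  pk <- v[i]
  lmin <- pk
  j <- i - 1L
  while (j >= 1L && v[j] <= pk) {
    if (v[j] < lmin) lmin <- v[j]
    j <- j - 1L
  }
  rmin <- pk
  j <- i + 1L
  while (j <= length(v) && v[j] <= pk) {
    if (v[j] < rmin) rmin <- v[j]
    j <- j + 1L
  }
  pk - max(lmin, rmin)
}

#' Sample skewness (moment estimator g1)
#'
#' `g1 = m3 / m2^(3/2)` with central sample moments `m_k`.
#' @param x Numeric vector.
#' @return Skewness, dimensionless.
#' @export
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

#' Sample kurtosis (non-excess, m4/m2^2; Gaussian = 3)
#' @param x Numeric vector.
#' @return Kurtosis, dimensionless.
#' @export
sample_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^4) / m2^2
}

moment_row <- function(condition, x) {
  metrics_row(condition, mean = mean(x), sd = stats::sd(x),
              max = max(x), min = min(x),
              kurtosis = sample_kurtosis(x), skewness = sample_skewness(x))
}

#' Summarize a spike train: amplitude and interval moment statistics
#'
#' Computes the canonical per-condition metrics rows for spike amplitudes
#' (mV) and interspike intervals (s, successive differences of peak times).
#' Conventions: SD is the sample (n-1) estimator; skewness is the moment
#' estimator `g1 = m3/m2^1.5`; kurtosis is non-excess `m4/m2^2` (a Gaussian
#' scores 3).  The ISI standard error is `SD / sqrt(n_intervals)`.
#'
#' @param events A [spike_events] object with at least 3 events.
#' @param condition Condition label for the metrics rows.
#' @return An object of class `spike_summary`: list with `amplitude` and
#'   `isi` metrics rows, `n_spikes`, and `sem_isi` (s).
#' @export
summarize_spikes <- function(events, condition = "") {
  stopifnot(inherits(events, "spike_events"))
  n <- length(events$times)
  if (n < 3)
    ps_stop("need at least 3 spikes to summarize a train",
            "insufficient_spikes")
  isis <- diff(events$times)
  structure(
    list(amplitude = moment_row(condition, events$amplitudes),
         isi = moment_row(condition, isis),
         n_spikes = n,
         sem_isi = stats::sd(isis) / sqrt(length(isis))),
    class = "spike_summary")
}

#' @export
print.spike_summary <- function(x, ...) {
  cat(sprintf("<spike_summary> '%s': %d spikes\n", x$amplitude$Condition,
              x$n_spikes))
  cat(sprintf("  amplitude %.3f +/- %.3f mV [%.3f, %.3f]\n",
              x$amplitude$Mean, x$amplitude$StdDev, x$amplitude$Min,
              x$amplitude$Max))
  cat(sprintf("  ISI %.1f +/- %.1f s (SEM %.1f) [%.1f, %.1f]\n",
              x$isi$Mean, x$isi$StdDev, x$sem_isi, x$isi$Min, x$isi$Max))
  invisible(x)
}

#' Run the full per-condition recovery pipeline on synthetic data
#'
#' Generates a synthetic recording for the condition, removes the baseline
#' with the spike-aware B-spline detrend, detects spikes and summarizes the
#' train.  This is the generate -> detrend -> detect -> summarize round trip
#' used to validate that the analysis recovers the calibration targets.
#'
#' @param spec A [condition_spec].
#' @param n_spikes Number of generated spikes (default 500).
#' @param seed Integer seed (default `spec$seed`).
#' @param ... Passed to [detrend_trace] / [detect_spikes].
#' @return List with `summary` (a `spike_summary`), `events` (detected),
#'   `generated` (the generator output) and `fit` (the baseline fit).
#' @export
recover_condition <- function(spec, n_spikes = 500, seed = spec$seed, ...) {
  gen <- generate_voltage_trace(spec, n_spikes = n_spikes, seed = seed)
  fit <- detrend_trace(gen$trace, ...)
  ev <- detect_spikes(fit$residual, ...)
  list(summary = summarize_spikes(ev, condition = spec$label),
       events = ev, generated = gen, fit = fit)
}
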