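#' Binary temporal code from a current trace
#'
#' Thresholds a chronoamperometric current trace into a 0/1 activity
#' sequence: bit `i` is 1 iff the current strictly exceeds the threshold
#' (default 1e-4 uA); a sample exactly at the threshold codes 0.
#'
#' @param x A [trace] with unit `"uA"`.
#' @param threshold Activity threshold, uA (default `1e-4`).
#' @return An object of class `binary_code`: list with `bits` (integer 0/1
#'   vector, one per sample), `threshold`, `label`.
#' @export
binarize_current <- function(x, threshold = 1e-4) {
  stopifnot(inherits(x, "trace"))
  if (!identical(x$unit, "uA"))
    ps_stop("binarize_current requires a current trace (unit 'uA')",
            "unit_mismatch")
  structure(list(bits = as.integer(x$values > threshold),
                 threshold = threshold, label = x$label),
            class = "binary_code")
}

#' @export
print.binary_code <- function(x, ...) {
  cat(sprintf("<binary_code> %d bits, %d active, threshold %g uA%s\n",
              length(x$bits), sum(x$bits), x$threshold,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Randomly subsample active time points for a neuron population
#'
#' Picks a uniform random subset of the active (bit = 1) sample indices
#' whose size is inversely related to the number of artificial neurons:
#' `floor(n_active / n_neurons)`, with a minimum of 1 whenever any sample
#' is active.
#'
#' @param code A `binary_code`.
#' @param n_neurons Number of artificial neurons (>= 1; default 30).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Sorted integer vector of selected sample indices (possibly
#'   empty).
#' @export
subsample_active <- function(code, n_neurons = 30, seed = NULL) {
  stopifnot(inherits(code, "binary_code"))
  if (!is_count(n_neurons))
    ps_stop("n_neurons must be a positive integer", "neuro_invalid")
  active <- which(code$bits == 1L)
  if (length(active) == 0L) return(integer(0))
  m <- max(1L, floor(length(active) / n_neurons))
  with_seed_maybe(seed, sort(active[sample.int(length(active), m)]))
}

#' Initialize a random synaptic weight matrix
#'
#' `n x n` weights drawn i.i.d. uniform on `[-1, 1)` via `2*u - 1` with
#' `u ~ U[0, 1)`, the reading under which all weights lie in `[-1, 1]`.
#'
#' @param n Neuron count (default 30).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `weight_matrix`: list with `W` (`n x n`
#'   matrix), `n`, `seed`.
#' @export
init_weights <- function(n = 30, seed = NULL) {
  if (!is_count(n)) ps_stop("n must be a positive integer", "neuro_invalid")
  W <- with_seed_maybe(seed,
    matrix(2 * stats::runif(n * n) - 1, nrow = n, ncol = n))
  structure(list(W = W, n = as.integer(n),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d x %d, entries in [%.3f, %.3f]\n",
              x$n, x$n, min(x$W), max(x$W)))
  invisible(x)
}

#' Cumulative charge from a current trace
#'
#' Recovers the charge `Q(t)` underlying `I(t) = dQ/dt` by trapezoidal
#' integration of the current from the start of the trace; `Q(t0) = 0`.
#' Microamperes integrated over seconds give microcoulombs.
#'
#' @param x A [trace] with unit `"uA"`.
#' @return Numeric vector of cumulative charge in uC, one value per sample.
#' @export
cumulative_charge <- function(x) {
  stopifnot(inherits(x, "trace"))
  if (!identical(x$unit, "uA"))
    ps_stop("cumulative_charge requires a current trace (unit 'uA')",
            "unit_mismatch")
  as.numeric(pracma::cumtrapz(trace_times(x), x$values))
}

#' Tukey boxplot statistics of a current distribution
#'
#' Mean, median, linear-interpolation (type-7) quartiles, whiskers at the
#' most extreme samples within 1.5 IQR of the quartiles, and the outliers
#' beyond them.
#'
#' @param x A non-empty [trace].
#' @return List with `mean`, `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
current_distribution_stats <- function(x) {
  stopifnot(inherits(x, "trace"))
  v <- x$values
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v >= lo_fence & v <= hi_fence
  list(mean = mean(v), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(v[inside]), whisker_high = max(v[inside]),
       outliers = sort(v[!inside]))
}

#' Export a weight matrix as CSV
#' @param w A `weight_matrix`.
#' @param path Output path (`n` rows x `n` columns, no header).
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(w, path) {
  stopifnot(inherits(w, "weight_matrix"))
  utils::write.table(w$W, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
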