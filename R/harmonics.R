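#' Estimate the base angular frequency of a periodic trace
#'
#' Locates the dominant peak of the magnitude spectrum (DC excluded) and
#' refines it by parabolic interpolation around the discrete maximum.  The
#' input is declared aperiodic — error class
#' `"harmonics_no_periodicity"` — when the peak magnitude is below 3 times
#' the median spectral magnitude.
#'
#' @param x A [trace] spanning at least ~3 periods of the putative rhythm.
#' @return Base angular frequency `omega` in rad/s.
#' @export
estimate_base_frequency <- function(x) {
  stopifnot(inherits(x, "trace"))
  v <- x$values - mean(x$values)
  n <- length(v)
  if (n < 8) ps_stop("trace too short for spectral analysis",
                     "harmonics_invalid")
  mag <- Mod(stats::fft(v))[2:(floor(n / 2) + 1)]
  p <- which.max(mag)
  if (mag[p] < 3 * stats::median(mag))
    ps_stop("no dominant spectral peak (input looks aperiodic)",
            "harmonics_no_periodicity")
  delta <- 0
  if (p > 1 && p < length(mag)) {
    denom <- mag[p - 1] - 2 * mag[p] + mag[p + 1]
    if (denom < 0) delta <- 0.5 * (mag[p - 1] - mag[p + 1]) / denom
  }
  f <- (p + delta) / (n * x$dt)
  2 * pi * f
}

#' Harmonic decomposition by least squares
#'
#' Projects the (mean-removed) trace onto `{sin(k w t), cos(k w t)}` for
#' `k = 1..K` and reports each harmonic in sine-phase form
#' `A_k sin(k w t + phi_k)` with `A_k >= 0` and `phi_k` in `(-pi, pi]`.
#' Least-squares projection is used rather than raw DFT bins so the base
#' frequency need not align with the DFT grid.
#'
#' @param x A [trace].
#' @param omega Base angular frequency, rad/s; `NULL` calls
#'   [estimate_base_frequency].
#' @param K Highest harmonic index; `K*omega/(2*pi)` must stay below the
#'   Nyquist frequency `1/(2*dt)`.
#' @return A `data.frame` with columns `k`, `amplitude`, `phase`, `omega`;
#'   attributes `residual_power` and `mean_square` (of the zero-mean input).
#' @export
harmonic_decompose <- function(x, omega = NULL, K = 16) {
  stopifnot(inherits(x, "trace"))
  if (is.null(omega)) omega <- estimate_base_frequency(x)
  if (!is_num1(omega) || omega <= 0)
    ps_stop("omega must be a positive number", "harmonics_invalid")
  if (!is_count(K)) ps_stop("K must be a positive integer", "harmonics_invalid")
  if (K * omega / (2 * pi) >= 1 / (2 * x$dt))
    ps_stop("K * omega exceeds the Nyquist frequency", "harmonics_invalid")
  tt <- trace_times(x)
  v <- x$values - mean(x$values)
  D <- matrix(0, length(v), 2 * K)
  for (k in seq_len(K)) {
    D[, 2 * k - 1] <- sin(k * omega * tt)
    D[, 2 * k] <- cos(k * omega * tt)
  }
  coef <- stats::lm.fit(D, v)$coefficients
  coef[is.na(coef)] <- 0
  a <- coef[seq(1, 2 * K, by = 2)]  # sin coefficients
  b <- coef[seq(2, 2 * K, by = 2)]  # cos coefficients
  A <- sqrt(a^2 + b^2)
  # a*sin + b*cos = A*sin(theta + phi) with phi = atan2(b, a)
  phi <- atan2(b, a)
  phi[phi <= -pi] <- phi[phi <= -pi] + 2 * pi
  phi[A == 0] <- 0
  out <- data.frame(k = seq_len(K), amplitude = unname(A),
                    phase = unname(phi), omega = omega)
  fitted <- as.numeric(D %*% coef)
  attr(out, "residual_power") <- mean((v - fitted)^2)
  attr(out, "mean_square") <- mean(v^2)
  out
}

#' Reconstruct a signal from harmonic components
#'
#' Evaluates `sum_k A_k sin(k w t + phi_k)` at the requested times.
#'
#' @param components A `data.frame` as returned by [harmonic_decompose]
#'   (columns `k`, `amplitude`, `phase`, `omega`; one shared `omega`).
#' @param times Numeric vector of evaluation times, s.
#' @return Numeric vector of reconstructed values.
#' @export
harmonic_reconstruct <- function(components, times) {
  if (nrow(components) == 0) return(numeric(length(times)))
  omega <- unique(components$omega)
  if (length(omega) != 1)
    ps_stop("components must share one base frequency", "harmonics_invalid")
  out <- numeric(length(times))
  for (i in seq_len(nrow(components)))
    out <- out + components$amplitude[i] *
      sin(components$k[i] * omega * times + components$phase[i])
  out
}
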