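# Independent oracles and shared fixtures, built in code.

# Brute-force LZ76 parser working directly from the definition: each phrase
# is the shortest prefix of the remainder that does not occur as a substring
# of the text up to (and including) the phrase minus its last symbol.
lz76_brute <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    repeat {
      phrase <- substr(s, i, j)
      history <- substr(s, 1, j - 1)
      if (!grepl(phrase, history, fixed = TRUE)) break
      if (j == n) break
      j <- j + 1L
    }
    count <- count + 1L
    i <- j + 1L
  }
  count
}

# Sort-based type-7 quantile oracle (linear interpolation between order
# statistics), independent of stats::quantile.
quantile7_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Truncated-normal mean/SD by numerical integration (independent of the
# closed-form expressions in the package).
truncnorm_moments_numint <- function(mu, sigma, a, b) {
  Z <- stats::integrate(function(x) dnorm(x, mu, sigma), a, b,
                        rel.tol = 1e-12)$value
  m <- stats::integrate(function(x) x * dnorm(x, mu, sigma), a, b,
                        rel.tol = 1e-12)$value / Z
  v <- stats::integrate(function(x) (x - m)^2 * dnorm(x, mu, sigma), a, b,
                        rel.tol = 1e-12)$value / Z
  c(mean = m, sd = sqrt(v))
}

# Small, fast condition spec for structural tests: short intervals so
# rendered traces stay small.  ISI targets are feasible for the truncated
# normal on the stated support.
test_spec <- function(...) {
  args <- list(label = "test",
               amp_mean = 1, amp_sd = 0.2, amp_skew = 1,
               amp_min = 0.3, amp_max = 2.5,
               isi_mean = 300, isi_sd = 60, isi_min = 150, isi_max = 600,
               drift_amplitude = 0.3, drift_period = 30000,
               noise_sd = 0.002, seed = 99L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(condition_spec, args)
}
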