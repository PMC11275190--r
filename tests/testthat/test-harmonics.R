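test_that("the base frequency of a single tone is located within 0.5%", {
  tt <- 0:1999
  tr <- trace(sin(2 * pi * 0.01 * tt), dt = 1, unit = "mV")
  w <- estimate_base_frequency(tr)
  expect_equal(w, 2 * pi * 0.01, tolerance = 0.005)
})

test_that("spectrally flat input raises a no-periodicity error", {
  withr::with_seed(41, {
    tr <- trace(rnorm(500), dt = 1, unit = "mV")
  })
  expect_error(estimate_base_frequency(tr),
               class = "harmonics_no_periodicity")
})

test_that("with two tones the stronger one wins", {
  tt <- 0:3999
  v <- 0.4 * sin(2 * pi * 0.005 * tt) + 1.0 * sin(2 * pi * 0.02 * tt)
  tr <- trace(v, dt = 1, unit = "mV")
  expect_equal(estimate_base_frequency(tr), 2 * pi * 0.02, tolerance = 0.005)
})

test_that("a single harmonic is recovered exactly in sine-phase form", {
  w <- 2 * pi / 500
  tt <- 0:4999
  tr <- trace(2 * sin(w * tt + 0.5), dt = 1, unit = "mV")
  comp <- harmonic_decompose(tr, omega = w, K = 6)
  expect_equal(comp$amplitude[1], 2, tolerance = 5e-4)
  expect_equal(comp$phase[1], 0.5, tolerance = 1e-3)
  expect_true(all(comp$amplitude[-1] < 1e-6))
  # zero signal: all amplitudes vanish
  z <- trace(rep(0, 1000), dt = 1, unit = "mV")
  compz <- harmonic_decompose(z, omega = w, K = 4)
  expect_true(all(compz$amplitude == 0))
})

test_that("synthesis -> analysis round trips a multi-harmonic signal", {
  w <- 2 * pi / 800
  tt <- 0:4799  # six exact periods, so the sampled signal has zero mean
  v <- 1.0 * sin(1 * w * tt + 0.3) + 0.5 * sin(2 * w * tt - 1.1) +
    0.25 * sin(4 * w * tt + 2.0)
  tr <- trace(v, dt = 1, unit = "mV")
  comp <- harmonic_decompose(tr, omega = w, K = 8)
  expect_equal(comp$amplitude[c(1, 2, 4)], c(1.0, 0.5, 0.25),
               tolerance = 0.01)
  expect_equal(comp$phase[c(1, 2, 4)], c(0.3, -1.1, 2.0), tolerance = 0.01)
  rec <- harmonic_reconstruct(comp, tt)
  expect_lt(sqrt(mean((rec - (v - mean(v)))^2)), 1e-6)
  # empty component list reconstructs silence
  expect_equal(harmonic_reconstruct(comp[0, ], 0:10), rep(0, 11))
})

test_that("retained harmonic power respects the Parseval bound", {
  withr::with_seed(73, {
    for (rep_i in 1:5) {
      w <- 2 * pi / stats::runif(1, 300, 900)
      tt <- 0:2999
      K <- 6
      v <- rep(0, length(tt))
      for (k in 1:K)
        v <- v + stats::runif(1, 0, 1) * sin(k * w * tt + stats::runif(1, -pi, pi))
      v <- v + rnorm(length(tt), 0, 0.3)
      tr <- trace(v, dt = 1, unit = "mV")
      comp <- harmonic_decompose(tr, omega = w, K = K)
      expect_lte(sum(comp$amplitude^2) / 2,
                 mean((v - mean(v))^2) * (1 + 1e-6))
    }
  })
})

test_that("harmonic preconditions are enforced", {
  tr <- trace(sin(2 * pi * 0.01 * (0:999)), dt = 1, unit = "mV")
  expect_error(harmonic_decompose(tr, omega = 2 * pi * 0.04, K = 20),
               class = "harmonics_invalid")  # K past Nyquist
  comp <- data.frame(k = 1:2, amplitude = c(1, 1), phase = c(0, 0),
                     omega = c(0.1, 0.2))
  expect_error(harmonic_reconstruct(comp, 0:10), class = "harmonics_invalid")
})
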