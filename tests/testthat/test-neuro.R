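test_that("current binarization applies a strict threshold", {
  tr <- trace(c(5e-5, 2e-4, 9e-5, 3e-4), dt = 1, unit = "uA")
  code <- binarize_current(tr)  # default threshold 1e-4 uA
  expect_equal(code$bits, c(0L, 1L, 0L, 1L))
  # strict inequality at the boundary: a value equal to the threshold is 0
  tr2 <- trace(c(1e-4, 2e-4), dt = 1, unit = "uA")
  expect_equal(binarize_current(tr2)$bits, c(0L, 1L))
  tr3 <- trace(rep(0, 5), dt = 1, unit = "uA")
  expect_equal(binarize_current(tr3)$bits, rep(0L, 5))
  # idempotent under re-thresholding of the (0/1) code values
  rebits <- as.integer(as.numeric(code$bits) > code$threshold)
  expect_equal(rebits, code$bits)
  vt <- trace(c(1, 2), dt = 1, unit = "mV")
  expect_error(binarize_current(vt), class = "unit_mismatch")
})

test_that("active-sample subsets scale inversely with the neuron count", {
  bits <- rep(0L, 500)
  bits[1:100 * 5] <- 1L  # 100 active samples
  code <- structure(list(bits = bits, threshold = 1e-4, label = ""),
                    class = "binary_code")
  s30 <- subsample_active(code, 30, seed = 9)
  expect_length(s30, 3)  # floor(100/30)
  expect_true(all(code$bits[s30] == 1L))
  expect_identical(s30, subsample_active(code, 30, seed = 9))
  # one neuron: every active index
  expect_length(subsample_active(code, 1, seed = 9), 100)
  # minimum subset size of 1 once anything is active
  few <- structure(list(bits = c(0L, 1L, 0L), threshold = 1e-4, label = ""),
                   class = "binary_code")
  expect_length(subsample_active(few, 30, seed = 9), 1)
  none <- structure(list(bits = rep(0L, 10), threshold = 1e-4, label = ""),
                    class = "binary_code")
  expect_length(subsample_active(none, 30, seed = 9), 0)
})

test_that("synaptic weights are uniform on [-1, 1) with variance 1/3", {
  w <- init_weights(30, seed = 4)
  expect_equal(dim(w$W), c(30, 30))
  expect_true(all(w$W >= -1 & w$W < 1))
  expect_identical(w$W, init_weights(30, seed = 4)$W)
  big <- init_weights(1000, seed = 5)$W  # 1e6 entries
  expect_lt(abs(mean(big)), 0.01)
  expect_equal(stats::var(as.vector(big)), 1 / 3, tolerance = 0.01)
  expect_error(init_weights(0), class = "neuro_invalid")
})

test_that("cumulative charge integrates current as dQ/dt inverse", {
  tr <- trace(rep(1, 11), dt = 1, unit = "uA")  # 1 uA over 10 s
  q <- cumulative_charge(tr)
  expect_equal(q[1], 0)
  expect_equal(q[11], 10)
  z <- trace(rep(0, 20), dt = 1, unit = "uA")
  expect_true(all(cumulative_charge(z) == 0))
  # central finite differences of Q recover I at interior points
  withr::with_seed(8, {
    v <- 2 + sin((0:200) / 10) + rnorm(201, 0, 0.01)
  })
  tr <- trace(v, dt = 1, unit = "uA")
  q <- cumulative_charge(tr)
  i_rec <- (q[3:201] - q[1:199]) / 2
  expect_equal(i_rec, v[2:200], tolerance = 0.01)
  expect_error(cumulative_charge(trace(1:5, dt = 1, unit = "mV")),
               class = "unit_mismatch")
})

test_that("current distribution statistics match a sort-based oracle", {
  tr <- trace(1:5, dt = 1, unit = "uA")
  s <- current_distribution_stats(tr)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  const <- current_distribution_stats(trace(rep(7, 10), dt = 1, unit = "uA"))
  expect_equal(const$iqr, 0)
  expect_length(const$outliers, 0)
  withr::with_seed(12, {
    for (rep_i in 1:5) {
      v <- c(rnorm(200), rnorm(5, 0, 10))  # heavy tail to force outliers
      tr <- trace(v, dt = 1, unit = "uA")
      s <- current_distribution_stats(tr)
      q1 <- quantile7_oracle(v, 0.25)
      q3 <- quantile7_oracle(v, 0.75)
      expect_equal(s$q1, q1)
      expect_equal(s$q3, q3)
      expect_equal(s$median, quantile7_oracle(v, 0.5))
      fence_lo <- q1 - 1.5 * (q3 - q1)
      fence_hi <- q3 + 1.5 * (q3 - q1)
      expect_equal(s$whisker_low, min(v[v >= fence_lo]))
      expect_equal(s$whisker_high, max(v[v <= fence_hi]))
      expect_equal(s$outliers, sort(v[v < fence_lo | v > fence_hi]))
    }
  })
})

test_that("weight matrices round-trip through CSV export", {
  w <- init_weights(10, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weight_matrix(w, path)
  back <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, w$W, tolerance = 1e-12)
})
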